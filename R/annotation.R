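#' Read gene intervals from BED or GFF3
#'
#' Loads a local annotation file into the internal 1-based inclusive
#' interval convention. BED input (0-based, half-open) is converted on
#' read; GFF3 is taken as-is (1-based inclusive), keeping `gene` features
#' (falling back to all features if none are typed `gene`). When the
#' rtracklayer package is available it does the parsing; otherwise a
#' minimal reader for 3-6 column BED and tab-delimited GFF3 is used.
#'
#' @param path file path; format inferred from the extension (`.bed` vs
#'   `.gff`/`.gff3`) unless `format` is given.
#' @param format `"bed"` or `"gff3"`.
#' @return data.frame of class `gene_intervals`: `gene`, `chr`, `start`,
#'   `end`, `strand`.
#' @export
read_gene_intervals <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "bed") "bed" else if (ext %in% c("gff", "gff3")) "gff3"
      else stopf("cannot infer annotation format from '%s'", path)
  }
  format <- match.arg(format, c("bed", "gff3"))
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
    df <- as.data.frame(gr)
    if (format == "gff3" && "type" %in% names(df) && any(df$type == "gene"))
      df <- df[df$type == "gene", , drop = FALSE]
    name <- df$Name %||% df$name %||% df$gene_id %||% df$ID
    if (is.null(name)) name <- sprintf("feature%d", seq_len(nrow(df)))
    out <- data.frame(gene = as.character(name), chr = as.character(df$seqnames),
                      start = df$start, end = df$end,
                      strand = as.character(df$strand), stringsAsFactors = FALSE)
  } else if (format == "bed") {
    df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    out <- data.frame(
      gene = if (ncol(df) >= 4) as.character(df[[4]])
             else sprintf("feature%d", seq_len(nrow(df))),
      chr = as.character(df[[1]]),
      start = df[[2]] + 1L,  # BED is 0-based half-open
      end = df[[3]],
      strand = if (ncol(df) >= 6) as.character(df[[6]]) else "*",
      stringsAsFactors = FALSE)
  } else {
    df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                     quote = "", stringsAsFactors = FALSE)
    if (ncol(df) < 9) stopf("malformed GFF3: expected 9 columns")
    if (any(df[[3]] == "gene")) df <- df[df[[3]] == "gene", , drop = FALSE]
    attrs <- df[[9]]
    name <- sub(".*Name=([^;]+).*", "\\1", attrs)
    noname <- !grepl("Name=", attrs)
    name[noname] <- sub(".*ID=([^;]+).*", "\\1", attrs[noname])
    out <- data.frame(gene = name, chr = as.character(df[[1]]),
                      start = as.integer(df[[4]]), end = as.integer(df[[5]]),
                      strand = as.character(df[[7]]), stringsAsFactors = FALSE)
  }
  if (any(out$start > out$end)) stopf("interval with start > end in %s", path)
  class(out) <- c("gene_intervals", "data.frame")
  out
}

#' Nearest gene to a SNP position
#'
#' If the SNP lies inside one or more intervals, an overlapping gene is
#' returned with distance 0 (reported `"within"`); otherwise the interval
#' minimising the distance to its nearer edge. Ties go to the smaller
#' interval start.
#'
#' @param chr,pos SNP chromosome and bp position (1-based).
#' @param genes a [read_gene_intervals()] data.frame.
#' @return List of class `candidate_gene`: `gene`, `distance` (bp, 0 when
#'   within), `within` (logical). When the chromosome has no genes, `gene`
#'   is `NA` and `distance` `Inf` ("none found"), not an error.
#' @export
nearest_gene <- function(chr, pos, genes) {
  g <- genes[as.character(genes$chr) == as.character(chr), , drop = FALSE]
  if (nrow(g) == 0)
    return(structure(list(gene = NA_character_, distance = Inf, within = FALSE),
                     class = "candidate_gene"))
  inside <- g$start <= pos & pos <= g$end
  dist <- ifelse(inside, 0, pmin(abs(pos - g$start), abs(pos - g$end)))
  ord <- order(dist, g$start)
  k <- ord[1]
  structure(list(gene = g$gene[k], distance = unname(dist[k]),
                 within = unname(inside[k])), class = "candidate_gene")
}

#' @export
print.candidate_gene <- function(x, ...) {
  if (is.na(x$gene)) cat("no gene found on chromosome\n")
  else cat(sprintf("%s (%s)\n", x$gene,
                   if (x$within) "within" else sprintf("%d bp", x$distance)))
  invisible(x)
}

#' Pairwise LD (r-squared) in a genomic region
#'
#' Squared Pearson correlation of allele dosages over animals with both
#' calls non-missing (the composite, unphased estimator). Pairs involving a
#' monomorphic SNP are reported as `NA`.
#'
#' @param genotypes a [genotype_matrix].
#' @param chr chromosome of the region.
#' @param from,to bp bounds (inclusive); default spans the chromosome.
#' @return Symmetric matrix of class `ld_matrix` with unit diagonal and SNP
#'   ids as dimnames.
#' @export
ld_r2 <- function(genotypes, chr, from = -Inf, to = Inf) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  map <- genotypes$map
  sel <- which(as.character(map$chr) == as.character(chr) &
                 map$pos >= from & map$pos <= to)
  if (length(sel) < 2) stopf("fewer than 2 SNPs in region %s:%s-%s", chr, from, to)
  dos <- genotypes$dosages[, sel, drop = FALSE]
  if (nrow(dos) < 2) stopf("need at least 2 genotyped animals")
  r <- suppressWarnings(cor(dos, use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- 1
  dimnames(r2) <- list(map$snp[sel], map$snp[sel])
  class(r2) <- c("ld_matrix", class(r2))
  r2
}
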