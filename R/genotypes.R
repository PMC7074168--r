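#' Genotype matrix container
#'
#' Bundles an animals-by-SNPs allele-dosage matrix with its marker map.
#' Dosages count copies of the A1 allele and take values 0, 1, 2 or `NA`
#' (missing call). The map must be sorted by (chromosome, position).
#'
#' @param dosages integer/numeric matrix, animals in rows, SNPs in columns.
#'   Row names (or `ids`) identify animals.
#' @param map data.frame with columns `snp`, `chr`, `pos` (bp, 1-based) and
#'   optionally `cM`, `a1`, `a2`.
#' @param ids animal identifiers; defaults to `rownames(dosages)`.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `map`, `ids`.
#' @export
genotype_matrix <- function(dosages, map, ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(ids)) stopf("animal ids are required (rownames or `ids`)")
  ids <- as.character(ids)
  if (length(ids) != nrow(dosages))
    stopf("length(ids) [%d] != nrow(dosages) [%d]", length(ids), nrow(dosages))
  if (anyDuplicated(ids)) stopf("duplicate animal ids in genotype matrix")
  req <- c("snp", "chr", "pos")
  if (!all(req %in% names(map)))
    stopf("map must have columns %s", paste(req, collapse = ", "))
  map <- as.data.frame(map)
  if (nrow(map) != ncol(dosages))
    stopf("map rows [%d] != SNP columns [%d]", nrow(map), ncol(dosages))
  ord <- order(map$chr, map$pos)
  if (!identical(ord, seq_len(nrow(map))))
    stopf("map must be sorted by (chr, pos)")
  bad <- dosages[!is.na(dosages) & !(dosages %in% 0:2)]
  if (length(bad)) stopf("dosages must be 0, 1, 2 or NA")
  rownames(dosages) <- ids
  colnames(dosages) <- map$snp
  structure(list(dosages = dosages, map = map, ids = ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d animals x %d SNPs on %d chromosome(s)\n",
              length(x$ids), nrow(x$map), length(unique(x$map$chr))))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix to a set of animals
#'
#' @param g a [genotype_matrix].
#' @param keep_ids animal ids to retain (row order follows `keep_ids`).
#' @return A [genotype_matrix] over the requested animals.
#' @export
subset_animals <- function(g, keep_ids) {
  stopifnot(inherits(g, "genotype_matrix"))
  keep_ids <- as.character(keep_ids)
  missing <- setdiff(keep_ids, g$ids)
  if (length(missing))
    stopf("unknown animal ids: %s", paste(head(missing, 5), collapse = ", "))
  genotype_matrix(g$dosages[keep_ids, , drop = FALSE], g$map, keep_ids)
}
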