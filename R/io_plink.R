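#' Write genotypes in PLINK format
#'
#' Writes PED/MAP (text) or BED/BIM/FAM (binary, SNP-major, magic bytes
#' `0x6c 0x1b 0x01`). Dosages count the A1 allele; missing calls become
#' `0 0` in PED and the `01` code in BED.
#'
#' @param genotypes a [genotype_matrix].
#' @param prefix output path prefix (files `prefix.ped`/`.map` or
#'   `.bed`/`.bim`/`.fam`).
#' @param format `"ped"` (default) or `"bed"`.
#' @param ped optional [pedigree] supplying sire/dam/sex for the FAM/PED
#'   columns.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, prefix, format = c("ped", "bed"), ped = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  map <- genotypes$map
  a1 <- map$a1 %||% rep("A", nrow(map))
  a2 <- map$a2 %||% rep("B", nrow(map))
  cm <- map$cM %||% rep(0, nrow(map))
  fam <- plink_fam_frame(genotypes$ids, ped)
  if (format == "ped") {
    write.table(data.frame(map$chr, map$snp, cm, map$pos),
                paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    dos <- genotypes$dosages
    n <- nrow(dos); M <- ncol(dos)
    al <- matrix("0", n, 2L * M)
    for (j in seq_len(M)) {
      x <- dos[, j]
      first <- ifelse(is.na(x), "0", ifelse(x >= 1, a1[j], a2[j]))
      second <- ifelse(is.na(x), "0", ifelse(x == 2, a1[j], a2[j]))
      al[, 2L * j - 1L] <- first
      al[, 2L * j] <- second
    }
    out <- cbind(fam, al)
    write.table(out, paste0(prefix, ".ped"), quote = FALSE, sep = " ",
                row.names = FALSE, col.names = FALSE)
  } else {
    write.table(data.frame(map$chr, map$snp, cm, map$pos, a1, a2),
                paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
                row.names = FALSE, col.names = FALSE)
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    dos <- genotypes$dosages
    n <- nrow(dos)
    # 2-bit codes per individual: dosage(A1) 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
    code <- matrix(3L, n, ncol(dos))
    code[dos == 2] <- 0L; code[dos == 1] <- 2L; code[is.na(dos)] <- 1L
    nbytes <- ceiling(n / 4)
    pad <- nbytes * 4L - n
    for (j in seq_len(ncol(dos))) {
      cj <- c(code[, j], rep(0L, pad))
      m <- matrix(cj, nrow = 4L)
      bytes <- m[1, ] + m[2, ] * 4L + m[3, ] * 16L + m[4, ] * 64L
      writeBin(as.raw(bytes), con)
    }
  }
  invisible(prefix)
}

plink_fam_frame <- function(ids, ped) {
  if (!is.null(ped)) {
    k <- match(ids, ped$id)
    data.frame(fid = "0", iid = ids,
               pat = ifelse(is.na(k), "0", ped$sire[k]),
               mat = ifelse(is.na(k), "0", ped$dam[k]),
               sex = if (!is.null(ped$sex))
                 ifelse(is.na(k), 0L, ifelse(ped$sex[k] == "M", 1L, 2L)) else 0L,
               pheno = -9, stringsAsFactors = FALSE)
  } else {
    data.frame(fid = "0", iid = ids, pat = "0", mat = "0", sex = 0L,
               pheno = -9, stringsAsFactors = FALSE)
  }
}

#' Read genotypes from PLINK files
#'
#' Accepts a PED/MAP pair or a BED/BIM/FAM triplet (auto-detected from the
#' files present). Dosages are coded as the count of the A1 allele (BIM A1,
#' or the more frequent first-listed allele for PED input when the map
#' carries no alleles); missing calls are preserved; SNP order follows the
#' map file.
#'
#' @param prefix path prefix of the fileset.
#' @return A [genotype_matrix].
#' @export
read_plink <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) read_plink_bed(prefix)
  else if (file.exists(paste0(prefix, ".ped"))) read_plink_ped(prefix)
  else stopf("no PLINK fileset at prefix '%s'", prefix)
}

read_plink_ped <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  if (!file.exists(map_path)) stopf("missing %s", map_path)
  map <- read.table(map_path, stringsAsFactors = FALSE)
  names(map) <- c("chr", "snp", "cM", "pos")[seq_len(ncol(map))]
  M <- nrow(map)
  lines <- readLines(paste0(prefix, ".ped"))
  fields <- strsplit(trimws(lines), "[ \t]+")
  n <- length(fields)
  len <- lengths(fields)
  if (any(len != 6 + 2 * M))
    stopf("PED/MAP disagree: line %d has %d fields, expected %d",
          which(len != 6 + 2 * M)[1], len[len != 6 + 2 * M][1], 6 + 2 * M)
  ids <- vapply(fields, `[[`, character(1), 2L)
  allele <- matrix(unlist(lapply(fields, function(f) f[-(1:6)])), nrow = n,
                   byrow = TRUE)
  dos <- matrix(NA_integer_, n, M)
  a1 <- character(M); a2 <- character(M)
  for (j in seq_len(M)) {
    x1 <- allele[, 2L * j - 1L]; x2 <- allele[, 2L * j]
    obs <- c(x1, x2); obs <- obs[obs != "0"]
    # PED carries no allele labels: A1 = minor allele (PLINK convention),
    # ties broken lexicographically
    tab <- table(obs)
    al <- names(tab)[order(tab, names(tab))]
    a1[j] <- al[1] %||% "A"
    a2[j] <- if (length(al) > 1) al[length(al)] else (if (a1[j] == "A") "B" else "A")
    miss <- x1 == "0" | x2 == "0"
    d <- (x1 == a1[j]) + (x2 == a1[j])
    d[miss] <- NA_integer_
    dos[, j] <- d
  }
  map$a1 <- a1; map$a2 <- a2
  genotype_matrix(dos, map, ids = ids)
}

read_plink_bed <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  names(bim) <- c("chr", "snp", "cM", "pos", "a1", "a2")
  fam <- read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  ids <- as.character(fam[[2]])
  n <- length(ids); M <- nrow(bim)
  nbytes <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3 + nbytes * M + 1)
  if (length(raw) < 3 || !identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stopf("bad BED magic bytes at offset 0-2 in %s.bed (not SNP-major PLINK)", prefix)
  if (length(raw) != 3 + nbytes * M)
    stopf("truncated BED: %d data bytes, expected %d (byte offset %d)",
          length(raw) - 3L, nbytes * M, length(raw))
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit codes, individual-fastest within SNP
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L, (body %/% 16L) %% 4L,
                 body %/% 64L)
  codes <- matrix(as.vector(codes), nrow = nbytes * 4L)[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_integer_, n, M)
  dos[codes == 0L] <- 2L
  dos[codes == 2L] <- 1L
  dos[codes == 3L] <- 0L
  genotype_matrix(dos, bim, ids = ids)
}

#' Read a pedigree CSV
#'
#' Columns `id`, `sire`, `dam` (0 or empty = unknown); extra columns `sex`,
#' `generation` are carried through.
#'
#' @param path CSV file path.
#' @return A [pedigree].
#' @export
read_pedigree_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("id", "sire", "dam")
  if (!all(req %in% names(df)))
    stopf("pedigree CSV must have columns id, sire, dam")
  df$sire[df$sire == ""] <- "0"; df$dam[df$dam == ""] <- "0"
  pedigree(df$id, df$sire, df$dam, sex = df$sex,
           generation = if (!is.null(df$generation)) as.integer(df$generation))
}

#' Write a pedigree CSV
#' @param ped a [pedigree].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree_csv <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a symmetric matrix as indexed triplets
#'
#' Plain-text `(i, j, value)` TSV (upper triangle including the diagonal)
#' for inspection of relationship matrices.
#'
#' @param m matrix (dense or sparse) with dimnames.
#' @param path output path.
#' @param zero_tol entries with `|value| <= zero_tol` are omitted.
#' @return `path`, invisibly.
#' @export
write_matrix_triplets <- function(m, path, zero_tol = 0) {
  tm <- as(as(as(m, "generalMatrix"), "CsparseMatrix"), "TsparseMatrix")
  i <- tm@i + 1L; j <- tm@j + 1L; x <- tm@x
  keep <- i <= j & abs(x) > zero_tol
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  df <- data.frame(i = ids[i[keep]], j = ids[j[keep]], value = x[keep])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
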