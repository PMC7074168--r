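#' Pedigree container
#'
#' An ordered set of animal/sire/dam records. Unknown parents are coded `0`
#' (or `NA`, converted to `0`). Records must be ordered parents-first: every
#' known parent appears earlier than its offspring, which also rules out an
#' animal being its own ancestor.
#'
#' @param id,sire,dam animal identifiers (coerced to character; `0`/`NA` =
#'   unknown parent).
#' @param sex optional factor/character (`"M"`/`"F"`), informational.
#' @param generation optional integer generation number (founders = 0).
#' @return A data.frame of class `pedigree` with columns `id`, `sire`, `dam`
#'   and any of `sex`, `generation` supplied.
#' @export
pedigree <- function(id, sire, dam, sex = NULL, generation = NULL) {
  id <- as.character(id)
  sire <- as.character(sire); dam <- as.character(dam)
  sire[is.na(sire)] <- "0"; dam[is.na(dam)] <- "0"
  n <- length(id)
  if (length(sire) != n || length(dam) != n)
    stopf("id, sire, dam must have equal length")
  if (anyDuplicated(id)) stopf("duplicate animal ids in pedigree")
  if (any(id == "0")) stopf("'0' is reserved for unknown parents")
  pos <- seq_len(n); names(pos) <- id
  for (col in list(sire, dam)) {
    known <- col != "0"
    absent <- setdiff(col[known], id)
    if (length(absent))
      stopf("parent(s) not in pedigree: %s", paste(head(absent, 5), collapse = ", "))
    late <- which(known & pos[col] >= pos)
    if (length(late))
      stopf("pedigree not ordered parents-first at animal '%s'", id[late[1]])
  }
  out <- data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
  if (!is.null(sex)) out$sex <- as.character(sex)
  if (!is.null(generation)) out$generation <- as.integer(generation)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(x$sire == "0" & x$dam == "0")
  cat(sprintf("pedigree: %d animals (%d founders)\n", nrow(x), nf))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# integer parent indices (0 = unknown) in pedigree order
parent_index <- function(ped) {
  pos <- seq_len(nrow(ped)); names(pos) <- ped$id
  s <- ifelse(ped$sire == "0", 0L, pos[ped$sire])
  d <- ifelse(ped$dam == "0", 0L, pos[ped$dam])
  cbind(sire = as.integer(s), dam = as.integer(d))
}

#' Restrict a pedigree to a set of animals and their ancestors
#'
#' Keeps the given animals plus every ancestor, preserving the original
#' parents-first ordering.
#'
#' @param ped a [pedigree].
#' @param ids animals whose ancestry to keep.
#' @return A [pedigree] over the reduced animal set.
#' @export
prune_pedigree <- function(ped, ids) {
  stopifnot(inherits(ped, "pedigree"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, ped$id)
  if (length(unknown))
    stopf("ids not in pedigree: %s", paste(head(unknown, 5), collapse = ", "))
  keep <- logical(nrow(ped)); names(keep) <- ped$id
  keep[ids] <- TRUE
  pi <- parent_index(ped)
  for (i in rev(seq_len(nrow(ped)))) {  # reverse pass propagates to ancestors
    if (keep[i]) {
      if (pi[i, 1] > 0) keep[pi[i, 1]] <- TRUE
      if (pi[i, 2] > 0) keep[pi[i, 2]] <- TRUE
    }
  }
  out <- ped[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes F for every animal without forming the full relationship matrix,
#' using the L-D-L' decomposition of the numerator relationship matrix.
#'
#' @param ped a [pedigree].
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding_coefficients <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  pi <- parent_index(ped)
  n <- nrow(ped)
  F <- numeric(n)
  dii <- numeric(n)  # Mendelian sampling variance scale
  # point[j], L-row workspace per animal (Meuwissen & Luo 1992)
  for (i in seq_len(n)) {
    s <- pi[i, 1]; d <- pi[i, 2]
    dii[i] <- 0.5 - 0.25 * ((if (s > 0) F[s] else -1) + (if (d > 0) F[d] else -1))
    if (s == 0 || d == 0) { F[i] <- 0; next }
    # a_ii = sum_j L_ij^2 d_jj over ancestors, traversed in decreasing index
    # order so every contribution to L_ij arrives before j is consumed
    Fi <- -1
    Lvec <- numeric(n); Lvec[i] <- 1
    anc <- i
    while (length(anc)) {
      j <- max(anc)
      anc <- anc[anc != j]
      lj <- Lvec[j]
      sj <- pi[j, 1]; dj <- pi[j, 2]
      if (sj > 0) { if (Lvec[sj] == 0) anc <- c(anc, sj); Lvec[sj] <- Lvec[sj] + 0.5 * lj }
      if (dj > 0) { if (Lvec[dj] == 0) anc <- c(anc, dj); Lvec[dj] <- Lvec[dj] + 0.5 * lj }
      Fi <- Fi + lj * lj * dii[j]
      Lvec[j] <- 0  # consumed
    }
    F[i] <- Fi
    dii[i] <- 0.5 - 0.25 * (F[s] + F[d])
  }
  names(F) <- ped$id
  F
}
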