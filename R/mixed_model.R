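#' Trait summary statistics
#'
#' N, mean, sample SD (n-1), min, max and the coefficient of variation
#' `CV% = SD/mean * 100`.
#'
#' @param values numeric trait vector; `NA`s are dropped.
#' @return List of class `trait_summary`.
#' @export
summarize_trait <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2) stopf("need at least 2 non-missing values")
  m <- mean(x)
  if (m == 0) stopf("CV undefined: trait mean is zero")
  structure(list(n = length(x), mean = m, sd = sd(x), min = min(x),
                 max = max(x), cv_percent = cv_percent(m, sd(x))),
            class = "trait_summary")
}

#' Coefficient of variation in percent
#'
#' @param mean,sd trait mean and standard deviation (mean must be nonzero).
#' @return `sd / mean * 100`.
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean == 0)) stopf("CV undefined: mean is zero")
  sd / mean * 100
}

#' @export
print.trait_summary <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.3f, SD = %.3f, range [%.3f, %.3f], CV = %.2f%%\n",
              x$n, x$mean, x$sd, x$min, x$max, x$cv_percent))
  invisible(x)
}

#' Single-trait animal-model specification
#'
#' Names the analyzed trait, the categorical fixed effects and any numeric
#' covariates; the additive animal effect over the pedigree is implicit.
#'
#' @param trait column name of the analyzed trait in the phenotype table.
#' @param fixed_factors categorical fixed-effect columns (e.g. sex, birth
#'   year, use type, farm).
#' @param covariates numeric covariate columns (e.g. age in days).
#' @return List of class `model_spec`.
#' @export
model_spec <- function(trait, fixed_factors = character(0),
                       covariates = character(0)) {
  structure(list(trait = trait, fixed_factors = fixed_factors,
                 covariates = covariates), class = "model_spec")
}

# full-rank fixed-effects design with drop-first reference coding;
# rank-deficient columns (confounded levels) are dropped by pivoted QR
fixed_design <- function(spec, data) {
  miss <- setdiff(c(spec$trait, spec$fixed_factors, spec$covariates), names(data))
  if (length(miss)) stopf("phenotype table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  terms <- c(sprintf("factor(%s)", spec$fixed_factors), spec$covariates)
  fml <- stats::as.formula(paste("~", paste(c("1", terms), collapse = " + ")))
  X <- stats::model.matrix(fml, data = data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the coefficient matrix and right-hand side of the single-trait
#' animal model `y = Wb + Za + e`, `a ~ N(0, H sigma_a^2)`,
#' `e ~ N(0, I sigma_e^2)`:
#' `[[W'W, W'Z], [Z'W, Z'Z + H^-1 (sigma_e^2/sigma_a^2)]] [b; a] = [W'y; Z'y]`.
#' Rank deficiency of the fixed design is handled by reference coding plus
#' pivoted-QR column dropping.
#'
#' @param spec a [model_spec()].
#' @param phenotypes data.frame with `id`, the trait and the model columns;
#'   rows with missing trait are dropped.
#' @param H_inv (sparse) relationship inverse over all pedigree animals,
#'   with animal ids as dimnames ([build_H_inverse()] or
#'   [build_A_inverse()]).
#' @param vc [variance_components()] supplying the variance ratio.
#' @param genotyped_ids optional ids of genotyped animals, carried through
#'   to the solution for GEBV extraction.
#' @return List of class `mme_system`.
#' @export
assemble_mme <- function(spec, phenotypes, H_inv, vc, genotyped_ids = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  ids <- rownames(H_inv)
  if (is.null(ids)) stopf("H_inv must carry animal ids as dimnames")
  phen <- phenotypes[!is.na(phenotypes[[spec$trait]]), , drop = FALSE]
  absent <- setdiff(as.character(phen$id), ids)
  if (length(absent))
    stopf("phenotyped animal(s) absent from pedigree: %s",
          paste(head(absent, 5), collapse = ", "))
  y <- phen[[spec$trait]]
  X <- fixed_design(spec, phen)
  n_rec <- length(y); q <- length(ids)
  Z <- Matrix::sparseMatrix(i = seq_len(n_rec),
                            j = match(as.character(phen$id), ids),
                            x = 1, dims = c(n_rec, q))
  ratio <- vc$sigma_e2 / vc$sigma_a2
  Hs <- as(as(H_inv, "generalMatrix"), "CsparseMatrix")
  Xs <- as(X, "CsparseMatrix")
  C <- rbind(cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z)),
             cbind(Matrix::crossprod(Z, Xs),
                   Matrix::crossprod(Z) + ratio * Hs))
  rhs <- c(as.numeric(Matrix::crossprod(Xs, y)),
           as.numeric(Matrix::crossprod(Z, y)))
  structure(list(C = Matrix::forceSymmetric(C), rhs = rhs, X = X, Z = Z,
                 y = y, ids = ids, record_ids = as.character(phen$id),
                 ratio = ratio, vc = vc,
                 genotyped_ids = as.character(genotyped_ids %||% character(0)),
                 effect_names = colnames(X)),
            class = "mme_system")
}

#' Solve the mixed-model equations
#'
#' Sparse Cholesky solve of the assembled system, with a relative residual
#' check.
#'
#' @param system an [assemble_mme()] result.
#' @param tol maximum allowed relative residual norm (default 1e-10).
#' @return List of class `mme_solution`: fixed-effect estimates `b`,
#'   additive predictions `a` for all pedigree animals, `a_g` for the
#'   genotyped subset (if ids were supplied), and solver diagnostics.
#' @export
solve_mme <- function(system, tol = 1e-10) {
  stopifnot(inherits(system, "mme_system"))
  p <- ncol(system$X)
  sol <- as.numeric(Matrix::solve(system$C, system$rhs))
  res <- as.numeric(system$C %*% sol) - system$rhs
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(system$rhs^2)), .Machine$double.eps)
  if (!is.finite(rel) || rel > tol)
    stopf("MME solve did not reach tolerance (relative residual %.3g)", rel)
  b <- stats::setNames(sol[seq_len(p)], system$effect_names)
  a <- stats::setNames(sol[-seq_len(p)], system$ids)
  a_g <- if (length(system$genotyped_ids)) a[system$genotyped_ids] else NULL
  structure(list(b = b, a = a, a_g = a_g,
                 diagnostics = list(relative_residual = rel, method = "sparse Cholesky")),
            class = "mme_solution")
}

#' Variance components of the animal model
#'
#' @param sigma_a2 additive genetic variance (trait units squared).
#' @param sigma_e2 residual variance.
#' @param se optional named numeric standard errors (`sigma_a2`, `sigma_e2`,
#'   `h2`).
#' @return List of class `variance_components` with derived
#'   `sigma_p2 = sigma_a2 + sigma_e2` and `h2 = sigma_a2 / sigma_p2`.
#' @export
variance_components <- function(sigma_a2, sigma_e2, se = NULL) {
  if (sigma_a2 <= 0 || sigma_e2 <= 0) stopf("variances must be positive")
  structure(list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
                 sigma_p2 = sigma_a2 + sigma_e2,
                 h2 = sigma_a2 / (sigma_a2 + sigma_e2), se = se),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("sigma_a2 = %.4g, sigma_e2 = %.4g, sigma_p2 = %.4g, h2 = %.3f",
              x$sigma_a2, x$sigma_e2, x$sigma_p2, x$h2))
  if (!is.null(x$se) && is.finite(x$se["h2"] %||% NA))
    cat(sprintf(" (SE %.3f)", x$se["h2"]))
  cat("\n")
  invisible(x)
}

#' Narrow-sense heritability from variance components
#'
#' @param vc a [variance_components()] object (or list with `sigma_a2`,
#'   `sigma_e2`).
#' @return `sigma_a2 / (sigma_a2 + sigma_e2)`.
#' @export
heritability <- function(vc) vc$sigma_a2 / (vc$sigma_a2 + vc$sigma_e2)

#' REML variance components for the single-trait animal model
#'
#' Expectation-maximisation REML on Henderson's mixed-model equations, with
#' optional average-information (AI) acceleration after a few EM warm-up
#' rounds. Each round factorises the coefficient matrix, solves for
#' `(b, a)`, and obtains the trace `tr(H^-1 C^aa)` from the inverse
#' coefficient matrix. The EM updates are
#' `sigma_a^2 <- (a' H^-1 a + sigma_e^2 tr(H^-1 C^aa)) / q` and
#' `sigma_e^2 <- y'e / (n - rank(W))`; AI steps use the average-information
#' matrix with step-halving toward the EM update whenever a step would leave
#' the parameter space.
#'
#' @param spec a [model_spec()].
#' @param phenotypes phenotype data.frame (see [assemble_mme()]).
#' @param H_inv relationship inverse over all pedigree animals.
#' @param start starting [variance_components()]; default splits the
#'   phenotypic variance at h2 = 0.5.
#' @param max_iter maximum iterations (default 100).
#' @param tol relative-change convergence tolerance on
#'   `(sigma_a2, sigma_e2)` (default 1e-8).
#' @param method `"ai"` (EM warm-up then AI acceleration, the default) or
#'   `"em"` (plain EM).
#' @param n_em_warmup EM rounds before the first AI step (default 3).
#' @return A [variance_components()] object with attributes `iterations`,
#'   `converged` and `loglik_path`; under `method = "ai"` the standard
#'   errors of the components and of h2 (delta method) are filled in, under
#'   plain EM they are `NA`.
#' @export
reml_estimate <- function(spec, phenotypes, H_inv, start = NULL,
                          max_iter = 100L, tol = 1e-8,
                          method = c("ai", "em"), n_em_warmup = 3L) {
  method <- match.arg(method)
  phen <- phenotypes[!is.na(phenotypes[[spec$trait]]), , drop = FALSE]
  vy <- var(phen[[spec$trait]])
  if (is.null(start)) start <- variance_components(0.5 * vy, 0.5 * vy)
  if (start$sigma_a2 <= 0 || start$sigma_e2 <= 0)
    stopf("starting variances must be positive")
  theta <- c(start$sigma_a2, start$sigma_e2)
  Hs <- as(as(as(H_inv, "generalMatrix"), "CsparseMatrix"), "TsparseMatrix")
  q <- nrow(H_inv)
  state <- NULL
  AI <- NULL
  iter_used <- max_iter
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    state <- reml_inner(spec, phen, H_inv, Hs, theta)
    em <- state$em
    if (method == "em" || it <= n_em_warmup) {
      theta_new <- em
    } else {
      AI <- state$AI
      step <- tryCatch(solve(AI, state$grad), error = function(e) NULL)
      theta_new <- if (is.null(step)) em else theta + step
      # step-halving toward the EM update keeps the iterate admissible
      half <- 0
      while (any(theta_new <= 0) && half < 30) {
        theta_new <- (theta_new + em) / 2
        half <- half + 1
      }
      if (any(theta_new <= 0)) theta_new <- em
    }
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), .Machine$double.eps))
    theta <- theta_new
    if (rel < tol) { converged <- TRUE; iter_used <- it; break }
  }
  if (!converged && method == "em")
    warnf("EM-REML reached max_iter = %d without meeting tol = %g", max_iter, tol)
  se <- c(sigma_a2 = NA_real_, sigma_e2 = NA_real_, h2 = NA_real_)
  if (method == "ai") {
    state <- reml_inner(spec, phen, H_inv, Hs, theta)
    V <- tryCatch(solve(state$AI), error = function(e) NULL)
    if (!is.null(V)) {
      g <- c(theta[2], -theta[1]) / sum(theta)^2  # d h2 / d(theta)
      se <- c(sigma_a2 = sqrt(max(V[1, 1], 0)),
              sigma_e2 = sqrt(max(V[2, 2], 0)),
              h2 = sqrt(max(drop(t(g) %*% V %*% g), 0)))
    }
  }
  out <- variance_components(theta[1], theta[2], se = se)
  attr(out, "iterations") <- iter_used
  attr(out, "converged") <- converged
  attr(out, "method") <- method
  out
}

# one REML round: solve the MME at theta = (sigma_a2, sigma_e2), return the
# EM update, the REML gradient and the average-information matrix
reml_inner <- function(spec, phen, H_inv, Hs, theta) {
  vc <- variance_components(theta[1], theta[2])
  sys <- assemble_mme(spec, phen, H_inv, vc)
  p <- ncol(sys$X); q <- length(sys$ids); n <- length(sys$y)
  Ch <- Matrix::Cholesky(sys$C, LDL = FALSE, perm = TRUE, super = FALSE)
  sol <- as.numeric(Matrix::solve(Ch, sys$rhs))
  b <- sol[seq_len(p)]; a <- sol[-seq_len(p)]
  e <- sys$y - as.numeric(sys$X %*% b) - as.numeric(sys$Z %*% a)
  # tr(H^-1 C^aa): a-block of the inverse coefficient matrix against the
  # sparsity pattern of H^-1, via the Takahashi selected inverse
  tr_aa <- selected_inverse_trace(Ch, Hs, offset = p)
  aHa <- as.numeric(t(a) %*% (H_inv %*% a))
  em <- c((aHa + theta[2] * tr_aa) / q,
          sum(sys$y * e) / (n - p))
  # gradient of the REML log-likelihood (MME identities:
  # tr(P ZHZ') = (q - ratio * tr_aa)/sigma_a2,
  # tr(P) = (n - p - q + ratio * tr_aa)/sigma_e2, Py = e/sigma_e2)
  ratio <- theta[2] / theta[1]
  yPVaPy <- aHa / theta[1]^2
  g_a <- -0.5 * ((q - ratio * tr_aa) / theta[1] - yPVaPy)
  g_e <- -0.5 * ((n - p - q + ratio * tr_aa) / theta[2] - sum(e^2) / theta[2]^2)
  # average information from working vectors f_a = Z a / sigma_a2, f_e = Py
  f_a <- as.numeric(sys$Z %*% a) / theta[1]
  f_e <- e / theta[2]
  Pf <- function(f) {
    rhs <- c(as.numeric(Matrix::crossprod(sys$X, f)),
             as.numeric(Matrix::crossprod(sys$Z, f)))
    s <- as.numeric(Matrix::solve(Ch, rhs))
    (f - as.numeric(sys$X %*% s[seq_len(p)]) -
        as.numeric(sys$Z %*% s[-seq_len(p)])) / theta[2]
  }
  Pfa <- Pf(f_a); Pfe <- Pf(f_e)
  AI <- 0.5 * matrix(c(sum(f_a * Pfa), sum(f_a * Pfe),
                       sum(f_a * Pfe), sum(f_e * Pfe)), 2, 2)
  list(em = em, grad = c(g_a, g_e), AI = AI, sol = sol, e = e, tr_aa = tr_aa)
}
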