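# EMMA-style single-kinship REML machinery shared by the univariate and
# bivariate scan engines. All scans work in the eigenspace of K so that each
# marker test costs O(n).

#' Eigendecomposition of a kinship matrix for mixed-model scans
#'
#' @param K Kinship matrix (bent to PSD internally if needed).
#' @return List with `U` (eigenvectors), `lambda` (eigenvalues, floored at
#'   1e-10).
#' @keywords internal
kinship_eigen <- function(K) {
  K <- bend_psd(K)
  e <- eigen(K, symmetric = TRUE)
  list(U = e$vectors, lambda = pmax(e$values, 1e-10))
}

# Restricted log-likelihood of y ~ X b + u + e with var(u) = s2g K,
# var(e) = s2e I, profiled over s2g at fixed delta = s2e / s2g.
# Inputs are rotated: yr = U'y, Xr = U'X.
.reml_loglik <- function(log10_delta, yr, Xr, lambda) {
  delta <- 10^log10_delta
  n <- length(yr)
  p <- ncol(Xr)
  w <- 1 / (lambda + delta)
  Xw <- Xr * sqrt(w)
  yw <- yr * sqrt(w)
  XtX <- crossprod(Xw)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xw, yw)))
  r <- yw - Xw %*% beta
  rss <- sum(r^2)
  if (rss <= 0) return(-Inf)
  s2g <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * s2g) +
                  sum(log(lambda + delta)) +
                  2 * sum(log(diag(ch))) +
                  (n - p))
  ll
}

#' REML fit of the null mixed model for a genome scan
#'
#' Fits `y = X b + u + e` with `var(u) = s2g K`, `var(e) = s2e I` by REML,
#' using a single eigendecomposition of `K` and a one-dimensional search over
#' `log(delta)` (`delta = s2e / s2g`): a 100-point log10 grid on
#' `[1e-5, 1e5]` followed by local refinement with [stats::optimize()].
#' The returned rotation enables O(markers) downstream scans.
#'
#' @param y Accession-level trait vector (finite, non-constant).
#' @param covariates Matrix of structure covariates (e.g. PCoA axes), or
#'   `NULL`. An intercept is always added.
#' @param K Kinship matrix, or a precomputed [kinship_eigen()] list.
#' @return List of class `mm_null_fit`: `sigma2_g`, `sigma2_e`, `delta`,
#'   `pseudo_h2` (`1/(1+delta)`), `loglik`, `eig`, rotated `yr`/`Xr`, and the
#'   fixed-effect design `X`.
#' @export
fit_null_mixed_model <- function(y, covariates = NULL, K = NULL) {
  if (any(!is.finite(y))) stop("y contains non-finite values")
  if (stats::sd(y) == 0) stop("y is constant")
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  eig <- if (is.list(K) && !is.null(K$lambda)) K else kinship_eigen(K)
  yr <- drop(crossprod(eig$U, y))
  Xr <- crossprod(eig$U, X)

  grid <- seq(-5, 5, length.out = 100)
  ll <- vapply(grid, .reml_loglik, numeric(1), yr = yr, Xr = Xr,
               lambda = eig$lambda)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(.reml_loglik, c(lo, hi), maximum = TRUE, yr = yr,
                         Xr = Xr, lambda = eig$lambda, tol = 1e-8)
  delta <- 10^opt$maximum
  w <- 1 / (eig$lambda + delta)
  Xw <- Xr * sqrt(w); yw <- yr * sqrt(w)
  qr_ <- qr(Xw)
  rss <- sum(qr.resid(qr_, yw)^2)
  s2g <- rss / (n - ncol(X))
  structure(list(sigma2_g = s2g, sigma2_e = s2g * delta, delta = delta,
                 pseudo_h2 = 1 / (1 + delta), loglik = opt$objective,
                 eig = eig, yr = yr, Xr = Xr, X = X, n = n),
            class = "mm_null_fit")
}

# Whitened base design/response given a null fit and extra fixed columns
# (cofactor dosages), all in rotated coordinates.
.whiten <- function(fit, cofactor_mat = NULL) {
  w <- sqrt(1 / (fit$eig$lambda + fit$delta))
  Xr <- fit$Xr
  if (!is.null(cofactor_mat)) {
    Xr <- cbind(Xr, crossprod(fit$eig$U, cofactor_mat))
  }
  list(Xw = Xr * w, yw = fit$yr * w, w = w)
}

#' Single-marker mixed-model scan
#'
#' Tests each marker of the panel added singly to the fixed effects
#' (covariates plus current cofactors), by generalized least squares under
#' the variance components of `fit` (estimated with the same cofactors in
#' the fixed effects). The test is a partial F-test with residual degrees of
#' freedom `n - n_fixed`. Cofactor markers themselves are reported with
#' their drop-one partial F p-values in the current multi-locus model.
#'
#' @param panel Imputed [genotype_panel()] whose accessions align with `y`.
#' @param fit A [fit_null_mixed_model()] fit whose fixed effects already
#'   include `covariates` (and nothing else).
#' @param cofactors Character vector of cofactor marker ids (possibly
#'   empty).
#' @return Data frame of class `assoc_result`: `marker_id`, `chrom`, `pos`,
#'   `beta` (trait units per minor allele), `f_stat`, `p_value`,
#'   `is_cofactor`. Markers collinear with the fixed effects get `NA`
#'   p-values.
#' @export
scan_markers <- function(panel, fit, cofactors = character(0)) {
  G <- panel$dosages
  map <- panel$map
  co_idx <- match(cofactors, map$marker_id)
  if (any(is.na(co_idx))) stop("unknown cofactor marker id")
  co_mat <- if (length(co_idx)) G[, co_idx, drop = FALSE] else NULL

  wh <- .whiten(fit, co_mat)
  n <- fit$n
  p0 <- ncol(wh$Xw)
  qr0 <- qr(wh$Xw)
  y0 <- qr.resid(qr0, wh$yw)
  rss0 <- sum(y0^2)

  # minor-allele coding so beta is per minor allele
  freq <- colMeans(G) / 2
  flip <- freq > 0.5
  Gm <- G
  if (any(flip)) Gm[, flip] <- 2 - Gm[, flip]

  Gr <- crossprod(fit$eig$U, Gm) * wh$w       # whitened markers
  Gres <- qr.resid(qr0, Gr)                   # residualized on fixed effects
  gty <- colSums(Gres * y0)
  gtg <- colSums(Gres^2)
  tol <- 1e-8 * max(colSums(Gr^2), 1)
  ok <- gtg > tol
  beta <- ifelse(ok, gty / gtg, NA_real_)
  rss1 <- rss0 - ifelse(ok, gty^2 / gtg, 0)
  df2 <- n - p0 - 1
  fst <- ifelse(ok, (rss0 - rss1) / (rss1 / df2), NA_real_)
  pval <- ifelse(ok, stats::pf(fst, 1, df2, lower.tail = FALSE), NA_real_)

  out <- data.frame(marker_id = map$marker_id, chrom = map$chrom,
                    pos = map$pos, beta = beta, f_stat = fst, p_value = pval,
                    is_cofactor = FALSE)

  if (length(co_idx)) {
    # drop-one partial F for each cofactor in the current model
    fit_lm <- stats::lm.fit(wh$Xw, wh$yw)
    rss_full <- sum(fit_lm$residuals^2)
    df_full <- n - p0
    co_cols <- seq.int(ncol(fit$Xr) + 1L, p0)
    for (k in seq_along(co_idx)) {
      Xd <- wh$Xw[, -co_cols[k], drop = FALSE]
      rss_d <- sum(qr.resid(qr(Xd), wh$yw)^2)
      fk <- (rss_d - rss_full) / (rss_full / df_full)
      j <- co_idx[k]
      out$f_stat[j] <- fk
      out$p_value[j] <- stats::pf(fk, 1, df_full, lower.tail = FALSE)
      out$beta[j] <- fit_lm$coefficients[co_cols[k]] * (if (flip[j]) -1 else 1)
      out$is_cofactor[j] <- TRUE
    }
  }
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Multi-locus mixed-model forward selection
#'
#' Forward stepwise inclusion of markers as fixed cofactors in the
#' kinship-corrected mixed model. At each step the most significant marker
#' (smallest scan p-value; ties broken by lower chromosome then position) is
#' added and the variance components re-estimated. The path stops after
#' `max_cofactors` steps or when the pseudo-heritability drops below 0.01.
#' The optimal model is the largest model along the path whose cofactors all
#' have drop-one p-values below `p_threshold`; with no qualifying model the
#' null model (step 0) is optimal.
#'
#' @inheritParams scan_markers
#' @param y Accession-level trait vector aligned to the panel.
#' @param covariates Structure covariates (PCoA axes) or `NULL`.
#' @param K Kinship matrix or [kinship_eigen()] list.
#' @param max_cofactors Maximum number of cofactors (default 5).
#' @param p_threshold Raw p-value bound each retained cofactor must satisfy
#'   (default 1e-4).
#' @return List of class `mlmm_fit`: `path` (list of per-step records with
#'   `cofactors`, `scan`, `sigma2_g`, `sigma2_e`, `pseudo_h2`,
#'   `cofactor_p`), `optimal_step` (0-based), `optimal_cofactors`,
#'   `p_threshold`.
#' @export
mlmm_select <- function(panel, y, covariates = NULL, K = NULL,
                        max_cofactors = 5, p_threshold = 1e-4) {
  eig <- if (is.list(K) && !is.null(K$lambda)) K else kinship_eigen(K)
  cofactors <- character(0)
  path <- list()
  for (s in 0:max_cofactors) {
    co_mat <- if (length(cofactors))
      panel$dosages[, match(cofactors, panel$map$marker_id), drop = FALSE]
    else NULL
    fit <- fit_null_mixed_model(y, cbind(covariates, co_mat), eig)
    scan <- scan_markers(panel, fit_strip_cofactors(fit, covariates, y, eig,
                                                    ncol2(covariates)),
                         cofactors)
    co_p <- scan$p_value[scan$is_cofactor]
    names(co_p) <- scan$marker_id[scan$is_cofactor]
    path[[s + 1L]] <- list(step = s, cofactors = cofactors, scan = scan,
                           sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
                           pseudo_h2 = fit$pseudo_h2, cofactor_p = co_p)
    if (s == max_cofactors || fit$pseudo_h2 < 0.01) break
    cand <- scan[!scan$is_cofactor & !is.na(scan$p_value), , drop = FALSE]
    if (nrow(cand) == 0L) break
    ord <- order(cand$p_value, cand$chrom, cand$pos)
    cofactors <- c(cofactors, cand$marker_id[ord[1L]])
  }
  qualifying <- vapply(path, function(st) {
    length(st$cofactor_p) == 0L ||
      all(!is.na(st$cofactor_p) & st$cofactor_p < p_threshold)
  }, logical(1))
  opt <- max(which(qualifying)) - 1L
  structure(list(path = path, optimal_step = opt,
                 optimal_cofactors = path[[opt + 1L]]$cofactors,
                 p_threshold = p_threshold),
            class = "mlmm_fit")
}

# scan_markers needs a fit whose Xr covers covariates only; when cofactors
# are present their columns are passed separately so drop-one tests can
# address them. Rebuild a covariate-only fit reusing the variance components
# already estimated with the cofactors included.
fit_strip_cofactors <- function(fit, covariates, y, eig, p_cov) {
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  fit$X <- X
  fit$Xr <- crossprod(eig$U, X)
  fit
}

ncol2 <- function(x) if (is.null(x)) 0L else ncol(x)

#' @exportS3Method base::print
print.mlmm_fit <- function(x, ...) {
  cat("mlmm_fit:", length(x$path) - 1L, "forward step(s); optimal step",
      x$optimal_step, "\n")
  if (length(x$optimal_cofactors)) {
    cat("  cofactors:", paste(x$optimal_cofactors, collapse = ", "), "\n")
  } else cat("  no significant cofactors (null model)\n")
  invisible(x)
}

#' Fraction of phenotypic variance explained by selected markers
#'
#' The variance of the fitted fixed marker component divided by the total
#' variance of the covariate-adjusted phenotype, clamped to `[0, 1]`.
#' Marker effects are estimated jointly by GLS under the mixed model.
#'
#' @inheritParams mlmm_select
#' @param markers Character vector of marker ids (the optimal model's
#'   cofactors); empty gives 0.
#' @return Numeric fraction in `[0, 1]`.
#' @export
global_pve <- function(panel, y, markers, covariates = NULL, K = NULL) {
  if (length(markers) == 0L) return(0)
  idx <- match(markers, panel$map$marker_id)
  if (any(is.na(idx))) stop("unknown marker id")
  G <- panel$dosages[, idx, drop = FALSE]
  eig <- if (is.list(K) && !is.null(K$lambda)) K else kinship_eigen(K)
  fit <- fit_null_mixed_model(y, cbind(covariates, G), eig)
  wh <- .whiten(fit)
  cf <- stats::lm.fit(wh$Xw, wh$yw)$coefficients
  p_cov <- 1L + ncol2(covariates)
  bG <- cf[seq.int(p_cov + 1L, p_cov + length(idx))]
  fitted_mark <- G %*% bG
  # covariate-adjusted phenotype on the raw scale
  X0 <- cbind(rep(1, length(y)), covariates)
  y_adj <- stats::lm.fit(X0, y)$residuals
  pve <- stats::var(drop(fitted_mark)) / stats::var(y_adj)
  min(max(pve, 0), 1)
}
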