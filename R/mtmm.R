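# Bivariate multi-trait mixed model for one trait measured under two
# watering regimes (C, D). The stacked 2n model has genetic covariance
# Vg (x) K with Vg the 2x2 regime covariance, and independent per-regime
# residuals (the two regimes are measured on different plants, so the
# residual cross-covariance is structurally zero).

.mtmm_neg2reml <- function(theta, yCr, yDr, Xr, lambda) {
  if (any(!is.finite(theta)) || any(abs(theta[-3]) > 40)) return(1e10)
  s2gC <- exp(theta[1]); s2gD <- exp(theta[2])
  rho <- tanh(theta[3])
  s2eC <- exp(theta[4]); s2eD <- exp(theta[5])
  gcd <- rho * sqrt(s2gC * s2gD)

  a <- lambda * s2gC + s2eC          # B[1,1] per eigen-index
  b <- lambda * s2gD + s2eD          # B[2,2]
  cc <- lambda * gcd                 # B[1,2]
  det <- a * b - cc^2
  if (any(det <= 0)) return(1e10)
  wcc <- b / det; wdd <- a / det; wcd <- -cc / det

  p <- ncol(Xr)
  A11 <- crossprod(Xr * wcc, Xr)
  A22 <- crossprod(Xr * wdd, Xr)
  A12 <- crossprod(Xr * wcd, Xr)
  A <- rbind(cbind(A11, A12), cbind(A12, A22))
  b1 <- crossprod(Xr, wcc * yCr + wcd * yDr)
  b2 <- crossprod(Xr, wcd * yCr + wdd * yDr)
  bv <- rbind(b1, b2)
  q <- sum(wcc * yCr^2 + 2 * wcd * yCr * yDr + wdd * yDr^2)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  z <- forwardsolve(t(ch), bv)
  quad <- q - sum(z^2)
  if (quad <= 0) return(1e10)
  sum(log(det)) + 2 * sum(log(diag(ch))) + quad
}

#' REML fit of the null bivariate (two-regime) mixed model
#'
#' Estimates the five variance parameters of the stacked model for a trait
#' measured under control and drought: per-regime genetic variances, their
#' cross-regime genetic correlation, and per-regime residual variances.
#' Genetic covariance is `Vg (x) K`; residuals are independent between
#' regimes. Optimization is numerical (BFGS on log-variance / atanh-rho
#' scale) after a single eigendecomposition of `K`, started from the
#' univariate per-regime REML fits.
#'
#' When the two trait vectors are numerically identical the bivariate REML
#' is unbounded (the difference subspace carries exactly zero variance), so
#' the fit collapses exactly to the univariate mixed model on the shared
#' trait with `rho_g = 1`; downstream tests then reduce accordingly.
#'
#' @param y_C,y_D Accession-level trait vectors under control and drought,
#'   aligned to `K`.
#' @param covariates Structure covariates (shared by both regimes) or
#'   `NULL`.
#' @param K Kinship matrix or [kinship_eigen()] list.
#' @return List of class `mtmm_fit`: `sigma2_g_C`, `sigma2_g_D`, `rho_g`,
#'   `sigma2_e_C`, `sigma2_e_D`, `degenerate`, `convergence`, plus internal
#'   rotated data for [mtmm_tests()].
#' @export
fit_mtmm_null <- function(y_C, y_D, covariates = NULL, K = NULL) {
  stopifnot(length(y_C) == length(y_D))
  n <- length(y_C)
  eig <- if (is.list(K) && !is.null(K$lambda)) K else kinship_eigen(K)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  Xr <- crossprod(eig$U, X)
  yCr <- drop(crossprod(eig$U, y_C))
  yDr <- drop(crossprod(eig$U, y_D))

  if (stats::var(y_C - y_D) < 1e-12 * (stats::var(y_C) + stats::var(y_D))) {
    uni <- fit_null_mixed_model(y_C, covariates, eig)
    out <- list(sigma2_g_C = uni$sigma2_g, sigma2_g_D = uni$sigma2_g,
                rho_g = 1, sigma2_e_C = uni$sigma2_e,
                sigma2_e_D = uni$sigma2_e, degenerate = TRUE,
                convergence = 0L, uni_fit = uni, eig = eig, Xr = Xr,
                yCr = yCr, yDr = yDr, n = n, covariates = covariates)
    class(out) <- "mtmm_fit"
    return(out)
  }

  fC <- fit_null_mixed_model(y_C, covariates, eig)
  fD <- fit_null_mixed_model(y_D, covariates, eig)
  theta0 <- c(log(max(fC$sigma2_g, 1e-6)), log(max(fD$sigma2_g, 1e-6)),
              atanh(0.5), log(max(fC$sigma2_e, 1e-6)),
              log(max(fD$sigma2_e, 1e-6)))
  opt <- stats::optim(theta0, .mtmm_neg2reml, method = "BFGS",
                      yCr = yCr, yDr = yDr, Xr = Xr, lambda = eig$lambda,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$value >= 1e10) {
    stop("MTMM REML did not converge; parameter trace: ",
         paste(signif(opt$par, 4), collapse = ", "))
  }
  th <- opt$par
  out <- list(sigma2_g_C = exp(th[1]), sigma2_g_D = exp(th[2]),
              rho_g = tanh(th[3]), sigma2_e_C = exp(th[4]),
              sigma2_e_D = exp(th[5]), degenerate = FALSE,
              convergence = opt$convergence, eig = eig, Xr = Xr,
              yCr = yCr, yDr = yDr, n = n, covariates = covariates)
  class(out) <- "mtmm_fit"
  out
}

#' @exportS3Method base::print
print.mtmm_fit <- function(x, ...) {
  cat("mtmm_fit: s2g_C =", signif(x$sigma2_g_C, 4),
      " s2g_D =", signif(x$sigma2_g_D, 4),
      " rho_g =", signif(x$rho_g, 4), "\n",
      "          s2e_C =", signif(x$sigma2_e_C, 4),
      " s2e_D =", signif(x$sigma2_e_D, 4),
      if (x$degenerate) " (degenerate: identical traits)" else "", "\n")
  invisible(x)
}

# 2x2 block whitener per eigen-index from the fitted variance components.
.mtmm_whitener <- function(vc) {
  lambda <- vc$eig$lambda
  gcd <- vc$rho_g * sqrt(vc$sigma2_g_C * vc$sigma2_g_D)
  a <- lambda * vc$sigma2_g_C + vc$sigma2_e_C
  b <- lambda * vc$sigma2_g_D + vc$sigma2_e_D
  cc <- lambda * gcd
  det <- a * b - cc^2
  wcc <- b / det; wdd <- a / det; wcd <- -cc / det
  sa <- sqrt(wcc)
  cr <- wcd / sa
  sb <- sqrt(pmax(wdd - wcd^2 / wcc, 1e-12))
  list(sa = sa, cr = cr, sb = sb)
}

.whiten_pair <- function(wh, FC, FD) {
  rbind(wh$sa * FC + wh$cr * FD, wh$sb * FD)
}

#' Per-marker global and G x W tests under the bivariate model
#'
#' Two-step testing: the variance components of `vc` (estimated once under
#' the no-SNP model) are fixed, and three nested fixed-effect models are
#' compared by GLS for each marker: null (no SNP), common (one effect shared
#' by both regimes) and full (separate per-regime effects). The global test
#' (common vs null, 1 df) flags markers with a shared effect; the G x W test
#' (full vs common, 1 df) flags markers whose effect depends on the regime.
#' F statistics use residual df `2n - n_fixed`. Per-marker PVE is the
#' explained-variance fraction of the added term in the whitened model.
#'
#' When `vc` is degenerate (identical traits), the global test reduces
#' exactly to the univariate scan on the shared trait and `p_gxw` is 1.
#'
#' @param panel Imputed [genotype_panel()] aligned to the trait vectors.
#' @param vc A [fit_mtmm_null()] fit.
#' @return Data frame of class `mtmm_result`: `marker_id`, `chrom`, `pos`,
#'   `beta_common`, `beta_C`, `beta_D`, `p_global`, `p_gxw`, `pve_global`,
#'   `pve_gxw`. Monomorphic markers get `NA` results.
#' @export
mtmm_tests <- function(panel, vc) {
  map <- panel$map
  G <- panel$dosages
  freq <- colMeans(G) / 2
  flip <- freq > 0.5
  Gm <- G
  if (any(flip)) Gm[, flip] <- 2 - Gm[, flip]
  mono <- apply(G, 2, stats::sd) == 0

  if (isTRUE(vc$degenerate)) {
    scan <- scan_markers(panel, vc$uni_fit)
    df2 <- vc$n - ncol(vc$uni_fit$X) - 1
    pve <- scan$f_stat / (scan$f_stat + df2)
    out <- data.frame(marker_id = map$marker_id, chrom = map$chrom,
                      pos = map$pos, beta_common = scan$beta,
                      beta_C = scan$beta, beta_D = scan$beta,
                      p_global = scan$p_value,
                      p_gxw = ifelse(is.na(scan$p_value), NA_real_, 1),
                      pve_global = pve, pve_gxw = 0)
    out[mono, -(1:3)] <- NA
    class(out) <- c("mtmm_result", "data.frame")
    return(out)
  }

  wh <- .mtmm_whitener(vc)
  n <- vc$n
  p_cov <- ncol(vc$Xr)
  zero <- matrix(0, n, p_cov)
  Xw <- cbind(.whiten_pair(wh, vc$Xr, zero), .whiten_pair(wh, zero, vc$Xr))
  yw <- drop(.whiten_pair(wh, matrix(vc$yCr), matrix(vc$yDr)))
  qr0 <- qr(Xw)
  y0 <- qr.resid(qr0, yw)
  rss0 <- sum(y0^2)

  Gr <- crossprod(vc$eig$U, Gm)
  Cw <- .whiten_pair(wh, Gr, Gr)            # common-effect columns
  Dw <- .whiten_pair(wh, Gr, -Gr)           # interaction columns
  Cres <- qr.resid(qr0, Cw)
  Dres <- qr.resid(qr0, Dw)

  cty <- colSums(Cres * y0)
  ctc <- colSums(Cres^2)
  okc <- ctc > 1e-10 & !mono
  bc <- ifelse(okc, cty / ctc, NA_real_)
  rss_common <- rss0 - ifelse(okc, cty^2 / ctc, 0)
  df_g <- 2 * n - (2 * p_cov + 1)
  Fg <- (rss0 - rss_common) / (rss_common / df_g)
  p_global <- ifelse(okc, stats::pf(Fg, 1, df_g, lower.tail = FALSE),
                     NA_real_)
  pve_global <- ifelse(okc, (rss0 - rss_common) / rss0, NA_real_)

  # residualize the interaction column on [X0, common col]; Dres2 is then
  # orthogonal to the common fit, so its inner product with y0 is the test
  # numerator for the full-vs-common comparison
  ctd <- colSums(Cres * Dres)
  Dres2 <- Dres - sweep(Cres, 2, ifelse(okc, ctd / ctc, 0), `*`)
  dty <- colSums(Dres2 * y0)
  dtd <- colSums(Dres2^2)
  okd <- okc & dtd > 1e-10
  bd <- ifelse(okd, dty / dtd, NA_real_)
  rss_full <- rss_common - ifelse(okd, dty^2 / dtd, 0)
  df_i <- 2 * n - (2 * p_cov + 2)
  Fi <- (rss_common - rss_full) / (rss_full / df_i)
  p_gxw <- ifelse(okd, stats::pf(Fi, 1, df_i, lower.tail = FALSE), NA_real_)
  pve_gxw <- ifelse(okd, (rss_common - rss_full) / rss_common, NA_real_)

  out <- data.frame(marker_id = map$marker_id, chrom = map$chrom,
                    pos = map$pos, beta_common = bc,
                    beta_C = bc + bd, beta_D = bc - bd,
                    p_global = p_global, p_gxw = p_gxw,
                    pve_global = pve_global, pve_gxw = pve_gxw)
  class(out) <- c("mtmm_result", "data.frame")
  out
}

#' Merge significant markers in mutual LD into unique QTLs
#'
#' Single-linkage grouping of same-chromosome significant markers whose
#' pairwise r-squared exceeds the critical LD threshold; markers in the same
#' group are considered one QTL, represented by the most significant member
#' (ties broken by lower chromosome, then position).
#'
#' @param results Data frame with columns `marker_id` and `p_value` for the
#'   significant markers (from either test).
#' @param panel Imputed [genotype_panel()] containing those markers.
#' @param threshold Critical LD threshold (r-squared).
#' @return Data frame with one row per QTL group: `marker_id`
#'   (representative), `p_value`, `n_members`, `members`
#'   (comma-separated ids).
#' @export
merge_ld_significant <- function(results, panel, threshold) {
  if (nrow(results) == 0L) {
    return(data.frame(marker_id = character(0), p_value = numeric(0),
                      n_members = integer(0), members = character(0)))
  }
  idx <- match(results$marker_id, panel$map$marker_id)
  if (any(is.na(idx))) stop("marker(s) absent from panel")
  chrom <- panel$map$chrom[idx]
  pos <- panel$map$pos[idx]
  m <- nrow(results)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i || chrom[i] != chrom[j]) next
      r2 <- ld_r2(panel$dosages[, idx[i]], panel$dosages[, idx[j]])
      if (!is.na(r2) && r2 > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(m), find, integer(1))
  out <- do.call(rbind, lapply(split(seq_len(m), root), function(members) {
    ord <- order(results$p_value[members], chrom[members], pos[members])
    rep_i <- members[ord[1L]]
    data.frame(marker_id = results$marker_id[rep_i],
               p_value = results$p_value[rep_i],
               n_members = length(members),
               members = paste(results$marker_id[members], collapse = ","))
  }))
  rownames(out) <- NULL
  out[order(out$p_value), , drop = FALSE]
}
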