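#' Filter a genotype panel on missingness and minor allele frequency
#'
#' Filtering proceeds in a fixed order: (1) accessions whose fraction of
#' missing calls exceeds `max_missing_per_accession` are dropped; (2) markers
#' whose missing fraction (computed on the remaining accessions) exceeds
#' `max_missing_per_marker` are dropped; (3) markers whose minor allele
#' frequency, computed on non-missing calls, falls below `min_maf` are
#' dropped. Defaults match common association-panel practice for array
#' genotypes: 25% per accession, 10% per marker, MAF 0.04.
#'
#' @param panel A [genotype_panel()], possibly with missing calls.
#' @param max_missing_per_accession Maximum tolerated missing fraction per
#'   accession (default 0.25).
#' @param max_missing_per_marker Maximum tolerated missing fraction per
#'   marker (default 0.10).
#' @param min_maf Minimum minor allele frequency (default 0.04). Markers with
#'   MAF strictly below this are removed.
#' @return The filtered [genotype_panel()]. Counts of dropped accessions and
#'   markers are attached as attribute `"filter_log"`.
#' @export
filter_markers <- function(panel, max_missing_per_accession = 0.25,
                           max_missing_per_marker = 0.10, min_maf = 0.04) {
  d <- panel$dosages
  acc_miss <- rowMeans(is.na(d))
  keep_acc <- acc_miss <= max_missing_per_accession
  d <- d[keep_acc, , drop = FALSE]

  mrk_miss <- colMeans(is.na(d))
  keep_m1 <- mrk_miss <= max_missing_per_marker
  d1 <- d[, keep_m1, drop = FALSE]

  freq <- colMeans(d1, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  keep_m2 <- !is.na(maf) & maf >= min_maf
  keep_markers <- which(keep_m1)[keep_m2]
  if (length(keep_markers) == 0L) {
    stop("all markers removed by filtering; empty panel")
  }
  out <- genotype_panel(panel$dosages[keep_acc, keep_markers, drop = FALSE],
                        panel$map[keep_markers, , drop = FALSE],
                        accession_ids = panel$accession_ids[keep_acc],
                        groups = panel$groups[keep_acc])
  attr(out, "filter_log") <- list(
    accessions_dropped = sum(!keep_acc),
    markers_dropped_missing = sum(!keep_m1),
    markers_dropped_maf = sum(!keep_m2),
    accessions_kept = nrow(out$dosages),
    markers_kept = ncol(out$dosages))
  out
}

#' Impute missing dosages by the marker mean
#'
#' Each missing call is replaced by the marker's mean dosage over non-missing
#' calls, i.e. twice the observed alternate-allele frequency. This is the
#' standard frequency imputation consistent with downstream linear models.
#'
#' @param panel A filtered [genotype_panel()].
#' @return A [genotype_panel()] with no missing values (dosages become real).
#' @export
impute_missing <- function(panel) {
  d <- panel$dosages
  nm <- colSums(!is.na(d))
  if (any(nm == 0L)) {
    stop("marker(s) with zero non-missing calls: ",
         paste(panel$map$marker_id[nm == 0L], collapse = ", "))
  }
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2L]]
  out <- panel
  out$dosages <- d
  out
}

#' Identity-by-state kinship matrix
#'
#' Allele-sharing similarity between accessions:
#' `K[i, j] = mean over markers of (1 - |x_i - x_j| / 2)`, computed on
#' imputed dosages. The diagonal is exactly 1; entries lie in `[0, 1]` and the
#' matrix is invariant to flipping the allele coding of any marker.
#'
#' @param panel An imputed [genotype_panel()] (no missing values).
#' @return A symmetric accessions x accessions matrix of class `matrix`, with
#'   accession ids as dimnames.
#' @export
compute_kinship <- function(panel) {
  d <- panel$dosages
  if (ncol(d) == 0L) stop("panel has zero markers")
  if (anyNA(d)) stop("panel contains missing values; impute first")
  man <- as.matrix(stats::dist(d, method = "manhattan"))
  K <- 1 - man / (2 * ncol(d))
  diag(K) <- 1
  dimnames(K) <- list(panel$accession_ids, panel$accession_ids)
  K
}

#' Bend a symmetric matrix to positive semi-definiteness
#'
#' IBS similarity matrices can be slightly indefinite; REML requires a PSD
#' genetic covariance. Eigenvalues below `floor` are raised to `floor` and
#' the matrix reconstructed.
#'
#' @param K Symmetric matrix.
#' @param floor Minimum eigenvalue (default `1e-6`).
#' @return A PSD matrix of the same dimension.
#' @export
bend_psd <- function(K, floor = 1e-6) {
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) >= floor) return(K)
  v <- pmax(e$values, floor)
  Kb <- e$vectors %*% (v * t(e$vectors))
  dimnames(Kb) <- dimnames(K)
  (Kb + t(Kb)) / 2
}

#' Principal co-ordinate analysis of a kinship matrix
#'
#' Classical metric multidimensional scaling of the dissimilarity
#' `D = 1 - K` (double centering of `-D^2/2` and eigendecomposition).
#' Axis coordinates are centered at zero and ordered by decreasing
#' eigenvalue; they serve as population-structure covariates in the mixed
#' models.
#'
#' @param K Kinship (similarity) matrix from [compute_kinship()].
#' @param n_axes Number of axes to return (default 3).
#' @return A list of class `pcoa_coords` with `coords` (accessions x axes
#'   matrix) and `eigenvalues` (all eigenvalues of the centered matrix).
#' @export
compute_pcoa <- function(K, n_axes = 3) {
  D <- stats::as.dist(1 - K)
  n <- attr(D, "Size")
  k_req <- min(n_axes, n - 1)
  fit <- suppressWarnings(stats::cmdscale(D, k = k_req, eig = TRUE))
  pos <- sum(fit$eig > sqrt(.Machine$double.eps))
  k_avail <- min(k_req, max(pos, 1L))
  if (k_avail < n_axes) {
    warning("only ", k_avail, " informative axes available (", n_axes,
            " requested)")
  }
  coords <- fit$points[, seq_len(k_avail), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  rownames(coords) <- rownames(K)
  structure(list(coords = coords, eigenvalues = fit$eig),
            class = "pcoa_coords")
}

#' Composite linkage disequilibrium between two markers
#'
#' The squared Pearson correlation of dosage vectors. For near-completely
#' homozygous material this composite estimator is numerically close to the
#' haplotype-frequency r-squared.
#'
#' @param x,y Equal-length imputed dosage vectors.
#' @return r-squared in `[0, 1]`, or `NA` when either vector has zero
#'   variance (undefined; excluded from percentile computations upstream).
#' @export
ld_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("dosage vectors differ in length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Critical LD threshold from unlinked marker pairs
#'
#' Samples pairs of markers on different chromosomes (without replacement of
#' pairs), computes their r-squared and returns the requested percentile of
#' the resulting null distribution. The 95th percentile of unlinked r-squared
#' is the conventional critical threshold beyond which LD is considered to
#' reflect linkage.
#'
#' @param panel Imputed [genotype_panel()] spanning at least 2 chromosomes.
#' @param n_pairs Number of inter-chromosome pairs to sample
#'   (default 100000); if fewer distinct pairs exist, all are used.
#' @param percentile Percentile of the unlinked r-squared distribution
#'   (default 0.95).
#' @param seed Optional integer seed for the pair sampling.
#' @return The threshold (numeric scalar). The sampled r-squared values are
#'   attached as attribute `"r2"`.
#' @export
critical_ld_threshold <- function(panel, n_pairs = 1e5, percentile = 0.95,
                                  seed = NULL) {
  chrom <- panel$map$chrom
  if (length(unique(chrom)) < 2L) stop("need markers on >= 2 chromosomes")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  m <- length(chrom)
  tab <- table(chrom)
  total_pairs <- (m * (m - 1) / 2) - sum(tab * (tab - 1) / 2)
  n_target <- min(n_pairs, total_pairs)

  seen <- new.env(hash = TRUE)
  ii <- integer(0); jj <- integer(0)
  while (length(ii) < n_target) {
    k <- max(1000L, ceiling((n_target - length(ii)) * 1.6))
    a <- sample.int(m, k, replace = TRUE)
    b <- sample.int(m, k, replace = TRUE)
    ok <- chrom[a] != chrom[b]
    a <- a[ok]; b <- b[ok]
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi)
    for (t in seq_along(key)) {
      if (length(ii) >= n_target) break
      if (is.null(seen[[key[t]]])) {
        seen[[key[t]]] <- TRUE
        ii <- c(ii, lo[t]); jj <- c(jj, hi[t])
      }
    }
  }
  d <- scale(panel$dosages)          # zero-variance markers give NaN columns
  r <- colSums(d[, ii, drop = FALSE] * d[, jj, drop = FALSE]) /
    (nrow(d) - 1)
  r2 <- r^2
  r2 <- r2[is.finite(r2)]
  thr <- unname(stats::quantile(r2, percentile))
  attr(thr, "r2") <- r2
  thr
}
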