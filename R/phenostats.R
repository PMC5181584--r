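#' Sample skewness
#' @param x Numeric vector.
#' @return Third standardized moment.
#' @keywords internal
sample_skewness <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(NA_real_)
  mean(x^3) / m2^1.5
}

#' Box-Cox transformation chosen by minimum skewness
#'
#' Applies the power transformation `(y^lambda - 1)/lambda` (natural log for
#' `lambda = 0`) over a grid of lambda values and retains the one giving the
#' least skewed distribution (smallest absolute sample skewness). Non-positive
#' data are shifted to be strictly positive first; the shift is recorded.
#'
#' @param values Numeric vector (finite).
#' @param lambda_grid Candidate lambda values (default -2 to 2 by 0.25).
#' @return A list of class `boxcox_fit`: `values` (transformed), `lambda`,
#'   `shift`, `skewness` (of the chosen transform).
#' @export
boxcox_transform <- function(values, lambda_grid = seq(-2, 2, by = 0.25)) {
  if (any(!is.finite(values))) stop("values must be finite")
  if (stats::sd(values) == 0) stop("constant vector: transformation undefined")
  shift <- 0
  if (min(values) <= 0) {
    shift <- -min(values) + 1e-6 * diff(range(values)) + .Machine$double.eps
    if (shift == 0) shift <- 1
  }
  y <- values + shift
  best <- NULL
  for (lam in lambda_grid) {
    z <- if (abs(lam) < 1e-12) log(y) else (y^lam - 1) / lam
    sk <- abs(sample_skewness(z))
    if (is.na(sk)) next
    if (is.null(best) || sk < best$skew) {
      best <- list(values = z, lambda = lam, skew = sk)
    }
  }
  if (is.null(best)) stop("no valid transformation found")
  structure(list(values = best$values, lambda = best$lambda, shift = shift,
                 skewness = best$skew), class = "boxcox_fit")
}

.pheno_subset <- function(table, trait, location) {
  d <- table[table$trait == trait & table$location == location, , drop = FALSE]
  if (nrow(d) == 0L) stop("no data for trait '", trait, "' at location '",
                          location, "'")
  d
}

#' Sequential ANOVA dissection of a trait
#'
#' Fits the fixed-effects model
#' `Y = mu + Gr + Gr(G) + W + Gr x W + Gr(G) x W + e`
#' (genetic group, accession nested in group, watering regime and their
#' interactions) with Type I sequential sums of squares in exactly that term
#' order, and reports each term's share of the total sum of squares and its
#' F-test p-value against the residual.
#'
#' @param table Phenotype data frame with columns `accession_id`, `group`,
#'   `location`, `regime` (`"C"`/`"D"`), `replicate`, `trait`, `value`.
#' @param trait Trait name to analyse.
#' @param location Location to analyse (locations are analysed separately).
#' @return Data frame of class `anova_partition` with columns `term`, `df`,
#'   `sum_sq`, `fraction`, `p_value`. Fractions sum to 1 and dfs to N - 1.
#' @export
anova_partition <- function(table, trait, location) {
  d <- .pheno_subset(table, trait, location)
  if (length(unique(d$regime)) < 2L) stop("missing regime cell for '", trait,
                                          "': need both C and D")
  d$group <- factor(d$group)
  d$accession_id <- factor(d$accession_id)
  d$regime <- factor(d$regime)
  f <- value ~ group + group:accession_id + regime + group:regime +
    group:accession_id:regime
  fit <- stats::lm(stats::terms(f, keep.order = TRUE), data = d)
  an <- stats::anova(fit)
  labels <- c("group" = "Gr", "group:accession_id" = "Gr(G)", "regime" = "W",
              "group:regime" = "GrxW", "group:accession_id:regime" = "Gr(G)xW",
              "Residuals" = "residual")
  out <- data.frame(term = unname(labels[rownames(an)]),
                    df = an$Df, sum_sq = an$`Sum Sq`,
                    fraction = an$`Sum Sq` / sum(an$`Sum Sq`),
                    p_value = an$`Pr(>F)`)
  class(out) <- c("anova_partition", "data.frame")
  out
}

#' Broad-sense heritability from replicate-level data
#'
#' REML fit of `value ~ group + (1 | accession)` within one watering regime;
#' the genetic variance is the accession variance component and
#' `H2 = s2G / (s2G + s2e / n)` with `n` the mean number of replicates per
#' accession for the trait.
#'
#' @inheritParams anova_partition
#' @param regime `"C"` or `"D"`.
#' @return List of class `heritability_fit`: `sigma2_G`, `sigma2_e`, `n`
#'   (mean replicates), `sigma2_total`, `H2`.
#' @export
heritability <- function(table, trait, location, regime) {
  d <- .pheno_subset(table, trait, location)
  d <- d[d$regime == regime, , drop = FALSE]
  if (nrow(d) == 0L) stop("no data in regime ", regime)
  reps <- table(d$accession_id)
  if (max(reps) < 2L) stop("single replicate everywhere: residual variance ",
                           "is inestimable")
  d$group <- factor(d$group)
  fml <- if (nlevels(d$group) > 1L) value ~ group + (1 | accession_id)
         else value ~ 1 + (1 | accession_id)
  fit <- suppressMessages(lme4::lmer(fml, data = d, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2G <- vc$vcov[vc$grp == "accession_id"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  n <- mean(reps)
  H2 <- s2G / (s2G + s2e / n)
  structure(list(sigma2_G = s2G, sigma2_e = s2e, n = n,
                 sigma2_total = s2G + s2e / n, H2 = H2),
            class = "heritability_fit")
}

#' Phenotypic plasticity index per accession
#'
#' `Delta = (D - C) / C` computed on raw accession means, where `C` and `D`
#' are the accession's mean trait values under the control and drought
#' regimes.
#'
#' @inheritParams anova_partition
#' @return Data frame with columns `accession_id`, `mean_C`, `mean_D`,
#'   `delta`. Accessions with `mean_C == 0` get `NA` with a warning.
#' @export
plasticity <- function(table, trait, location) {
  d <- .pheno_subset(table, trait, location)
  mC <- tapply(d$value[d$regime == "C"], d$accession_id[d$regime == "C"], mean)
  mD <- tapply(d$value[d$regime == "D"], d$accession_id[d$regime == "D"], mean)
  acc <- intersect(names(mC), names(mD))
  mC <- mC[acc]; mD <- mD[acc]
  delta <- (mD - mC) / mC
  zero <- mC == 0
  if (any(zero)) {
    warning(sum(zero), " accession(s) with zero control mean: plasticity NA")
    delta[zero] <- NA_real_
  }
  data.frame(accession_id = acc, mean_C = unname(mC), mean_D = unname(mD),
             delta = unname(delta))
}

#' Partition G x W interaction into re-ranking and scale change
#'
#' With genotypic standard deviations `s_C`, `s_D` of the accession means in
#' each regime and their cross-regime correlation `r`, the interaction is
#' decomposed as scale part `(s_C - s_D)^2` and re-ranking part
#' `2 s_C s_D (1 - r)`; fractions are normalized by their sum.
#'
#' @inheritParams anova_partition
#' @return List: `fraction_reranking`, `fraction_scale`, `degenerate`
#'   (TRUE when the interaction is exactly zero, in which case both fractions
#'   are reported as 0).
#' @export
interaction_partition <- function(table, trait, location) {
  p <- plasticity(table, trait, location)
  if (nrow(p) < 3L) stop("need >= 3 accessions with both regime means")
  sC <- stats::sd(p$mean_C)
  sD <- stats::sd(p$mean_D)
  r <- stats::cor(p$mean_C, p$mean_D)
  scale_part <- (sC - sD)^2
  rerank_part <- 2 * sC * sD * (1 - r)
  tot <- scale_part + rerank_part
  # an interaction this far below the genotypic variances is numerically zero
  if (tot <= 1e-10 * (sC^2 + sD^2)) {
    return(list(fraction_reranking = 0, fraction_scale = 0, degenerate = TRUE))
  }
  list(fraction_reranking = rerank_part / tot,
       fraction_scale = scale_part / tot,
       degenerate = FALSE)
}

#' Derive yield from fruit weight and fruit number
#'
#' Adds a `"Yield"` trait per accession, location and regime, computed as
#' (mean fruit weight) x (mean fruit number per plant), in grams per plant.
#'
#' @param table Phenotype data frame (see [anova_partition()]).
#' @param fw_trait,nb_trait Names of the fruit-weight and fruit-number
#'   traits (defaults `"FW"` and `"Nbfruits"`).
#' @return The input table with `"Yield"` records appended (replicate 1).
#'   Accession/regime cells missing either component are skipped with a
#'   warning.
#' @export
derive_yield <- function(table, fw_trait = "FW", nb_trait = "Nbfruits") {
  key <- c("accession_id", "group", "location", "regime")
  fw <- table[table$trait == fw_trait, , drop = FALSE]
  nb <- table[table$trait == nb_trait, , drop = FALSE]
  agg_fw <- stats::aggregate(value ~ accession_id + group + location + regime,
                             data = fw, FUN = mean)
  agg_nb <- stats::aggregate(value ~ accession_id + group + location + regime,
                             data = nb, FUN = mean)
  merged <- merge(agg_fw, agg_nb, by = key, suffixes = c("_fw", "_nb"))
  n_fw_cells <- nrow(agg_fw)
  if (nrow(merged) < n_fw_cells) {
    warning(n_fw_cells - nrow(merged),
            " accession/regime cell(s) missing a component trait: skipped")
  }
  if (nrow(merged) == 0L) {
    warning("no complete cells: no yield records derived")
    return(table)
  }
  yield <- data.frame(accession_id = merged$accession_id,
                      group = merged$group, location = merged$location,
                      regime = merged$regime, replicate = 1L,
                      trait = "Yield",
                      value = merged$value_fw * merged$value_nb)
  rbind(table, yield)
}

#' Cross-regime rank correlations of heritability and genetic variance
#'
#' Spearman correlations, across traits, between the control and drought
#' values of the broad-sense heritability and of the genetic variance.
#'
#' @param results Data frame with columns `trait`, `regime` (`"C"`/`"D"`),
#'   `H2`, `sigma2_G`, one row per trait x regime.
#' @return List: `spearman_H2`, `spearman_varG`.
#' @export
cross_regime_correlations <- function(results) {
  wc <- results[results$regime == "C", ]
  wd <- results[results$regime == "D", ]
  traits <- intersect(wc$trait, wd$trait)
  if (length(traits) < 3L) stop("need >= 3 traits with both regimes")
  wc <- wc[match(traits, wc$trait), ]
  wd <- wd[match(traits, wd$trait), ]
  list(spearman_H2 = stats::cor(wc$H2, wd$H2, method = "spearman"),
       spearman_varG = stats::cor(wc$sigma2_G, wd$sigma2_G,
                                  method = "spearman"))
}

#' Tukey HSD comparisons of group x regime cell means
#'
#' Intended as the follow-up when the group-by-regime interaction is
#' significant: all pairwise comparisons of the `group:regime` cell means
#' with Tukey's honest significant difference adjustment.
#'
#' @inheritParams anova_partition
#' @return Data frame with columns `pair`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `testable` (FALSE for pairs involving a cell with < 2 observations).
#' @export
tukey_posthoc <- function(table, trait, location) {
  d <- .pheno_subset(table, trait, location)
  d$cell <- interaction(factor(d$group), factor(d$regime), sep = ":")
  fit <- stats::aov(value ~ cell, data = d)
  tk <- stats::TukeyHSD(fit)$cell
  cnt <- table(d$cell)
  small <- names(cnt)[cnt < 2L]
  pairs <- rownames(tk)
  involved <- vapply(pairs, function(p) {
    any(strsplit(p, "-", fixed = TRUE)[[1]] %in% small)
  }, logical(1))
  data.frame(pair = pairs, diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             testable = !involved, row.names = NULL)
}

#' Accession means of a trait in one regime
#'
#' Convenience accessor producing the accession-level mean vector used as
#' the response in the mapping models, aligned to a panel's accession order.
#'
#' @inheritParams heritability
#' @param panel Optional [genotype_panel()]; when given, means are returned
#'   aligned to `panel$accession_ids` (NA for absent accessions).
#' @return Named numeric vector of accession means.
#' @export
accession_means <- function(table, trait, location, regime, panel = NULL) {
  d <- .pheno_subset(table, trait, location)
  d <- d[d$regime == regime, , drop = FALSE]
  m <- tapply(d$value, d$accession_id, mean)
  if (!is.null(panel)) {
    m <- m[panel$accession_ids]
    names(m) <- panel$accession_ids
  }
  m
}
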