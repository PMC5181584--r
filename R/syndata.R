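# Structured-panel simulator with known QTL architecture. The generator
# emulates the study design the package targets: a small highly homozygous
# diploid panel (default 141 accessions in 3 genetic groups of 10/110/21),
# 12 chromosomes of array SNPs with distance-decaying LD, two watering
# regimes with 2 replicate plants per accession, a polygenic background with
# high (but imperfect) cross-regime genetic correlation, and planted QTLs of
# four classes (constitutive, regime-specific, differential, antagonist).

#' Simulation configuration
#'
#' @param n_accessions Panel size (default 141).
#' @param group_sizes Genetic group sizes summing to `n_accessions`
#'   (default 10/110/21, labelled SP, SLC, mixture).
#' @param n_chromosomes Number of chromosomes (default 12).
#' @param markers_per_chromosome Markers per chromosome (default 508, i.e.
#'   ~6100 genome-wide).
#' @param chromosome_length Chromosome length in base pairs (default 65 Mb).
#' @param fst Divergence of group allele frequencies in `[0, 1]`
#'   (Balding-Nichols; default 0.20).
#' @param ld_block_length Correlation length of within-chromosome LD in base
#'   pairs (default 2 Mb): the latent haplotype process decorrelates as
#'   `exp(-distance / ld_block_length)`.
#' @param inbreeding Per-locus probability of forced homozygosity in
#'   `[0, 1]` (default 0.95; the panel emulates near-inbred lines, which
#'   keeps dosage r-squared close to haplotype r-squared).
#' @param qtl List of planted QTLs, each a list with `chrom`, `pos`,
#'   `class` (one of `"constitutive"`, `"control_specific"`,
#'   `"drought_specific"`, `"differential"`, `"antagonist"`) and `pve`
#'   (target per-regime fraction of accession-mean variance).
#' @param polygenic_h2 Broad-sense heritability of the trait at the
#'   replicate design, per regime (default 0.6, the middle of the 0.30-0.92
#'   range such panels show).
#' @param genetic_correlation Cross-regime correlation of the polygenic
#'   values in `[-1, 1]` (default 0.9: high, but low enough that genotype
#'   re-ranking dominates the interaction).
#' @param replicates Plants per accession per regime (default 2).
#' @param missing_rate Fraction of genotype calls set missing (default 0,
#'   so QC filters can be exercised when requested).
#' @param baseline Trait baseline mean in trait units (default 20; the
#'   genetic and residual scale is 1, giving a realistic coefficient of
#'   variation and keeping the plasticity denominator away from zero).
#' @param regime_shift Relative shift of the drought trait mean
#'   (default -0.1).
#' @param differential_ratio Effect-intensity ratio (drought / control) for
#'   the `differential` class (default 3; fixed design choice).
#' @param seed Integer seed; the same configuration and seed give
#'   bit-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 141, group_sizes = c(10, 110, 21),
                       n_chromosomes = 12, markers_per_chromosome = 508,
                       chromosome_length = 65e6, fst = 0.20,
                       ld_block_length = 2e6, inbreeding = 0.95,
                       qtl = list(), polygenic_h2 = 0.6,
                       genetic_correlation = 0.9, replicates = 2,
                       missing_rate = 0, baseline = 20, regime_shift = -0.1,
                       differential_ratio = 3, seed = 1) {
  if (sum(group_sizes) != n_accessions) {
    stop("group_sizes must sum to n_accessions (", sum(group_sizes), " != ",
         n_accessions, ")")
  }
  for (f in c(fst, inbreeding, polygenic_h2, missing_rate)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  if (abs(genetic_correlation) > 1) stop("genetic_correlation must be in [-1, 1]")
  classes <- c("constitutive", "control_specific", "drought_specific",
               "differential", "antagonist")
  for (q in qtl) {
    if (!all(c("chrom", "pos", "class", "pve") %in% names(q))) {
      stop("each qtl needs chrom, pos, class, pve")
    }
    if (!q$class %in% classes) stop("unknown qtl class: ", q$class)
    if (q$pve <= 0 || q$pve >= 1) stop("qtl pve must be in (0, 1)")
  }
  structure(list(n_accessions = n_accessions, group_sizes = group_sizes,
                 n_chromosomes = n_chromosomes,
                 markers_per_chromosome = markers_per_chromosome,
                 chromosome_length = chromosome_length, fst = fst,
                 ld_block_length = ld_block_length, inbreeding = inbreeding,
                 qtl = qtl, polygenic_h2 = polygenic_h2,
                 genetic_correlation = genetic_correlation,
                 replicates = replicates, missing_rate = missing_rate,
                 baseline = baseline, regime_shift = regime_shift,
                 differential_ratio = differential_ratio,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.group_labels <- function(group_sizes) {
  nm <- if (length(group_sizes) == 3L) c("SP", "SLC", "mixture") else
    paste0("group", seq_along(group_sizes))
  rep(nm, times = group_sizes)
}

#' Simulate a structured genotype panel
#'
#' Group allele frequencies diverge from ancestral frequencies by a
#' Balding-Nichols scheme with the configured `fst`. Within-chromosome LD
#' comes from a latent Gaussian process along each haplotype whose
#' correlation decays as `exp(-distance / ld_block_length)`; markers on
#' different chromosomes are independent. Each locus is forced homozygous
#' with probability `inbreeding`, otherwise two haplotypes are summed
#' (Hardy-Weinberg).
#'
#' @param config A [sim_config()].
#' @return A [genotype_panel()] with dosages in `{0, 1, 2}` (plus `NA` when
#'   `missing_rate > 0`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_accessions
  groups <- .group_labels(config$group_sizes)
  g_idx <- as.integer(factor(groups, levels = unique(groups)))
  n_groups <- length(config$group_sizes)

  dos_list <- vector("list", config$n_chromosomes)
  map_list <- vector("list", config$n_chromosomes)
  for (ch in seq_len(config$n_chromosomes)) {
    m <- config$markers_per_chromosome
    pos <- sort(sample.int(config$chromosome_length, m))
    p0 <- stats::runif(m, 0.1, 0.9)
    if (config$fst > 0) {
      sh <- (1 - config$fst) / config$fst
      pg <- matrix(stats::rbeta(n_groups * m, rep(p0, each = n_groups) * sh,
                                rep(1 - p0, each = n_groups) * sh),
                   nrow = n_groups)
    } else {
      pg <- matrix(rep(p0, each = n_groups), nrow = n_groups)
    }
    pg <- pmin(pmax(pg, 0.005), 0.995)
    thr <- stats::qnorm(pg)                      # n_groups x m thresholds

    r <- exp(-diff(pos) / config$ld_block_length)
    Z1 <- matrix(0, n, m); Z2 <- matrix(0, n, m)
    Z1[, 1] <- stats::rnorm(n); Z2[, 1] <- stats::rnorm(n)
    for (j in 2:m) {
      Z1[, j] <- r[j - 1] * Z1[, j - 1] + sqrt(1 - r[j - 1]^2) * stats::rnorm(n)
      Z2[, j] <- r[j - 1] * Z2[, j - 1] + sqrt(1 - r[j - 1]^2) * stats::rnorm(n)
    }
    thr_acc <- thr[g_idx, , drop = FALSE]        # n x m
    H1 <- (Z1 < thr_acc) + 0
    H2 <- (Z2 < thr_acc) + 0
    inb <- matrix(stats::runif(n * m) < config$inbreeding, n, m)
    D <- ifelse(inb, 2 * H1, H1 + H2)
    dos_list[[ch]] <- D
    map_list[[ch]] <- data.frame(chrom = ch, pos = pos)
  }
  dos <- do.call(cbind, dos_list)
  map <- do.call(rbind, map_list)
  if (config$missing_rate > 0) {
    nmiss <- round(config$missing_rate * length(dos))
    dos[sample.int(length(dos), nmiss)] <- NA
  }
  genotype_panel(dos, map,
                 accession_ids = sprintf("acc%03d", seq_len(n)),
                 groups = groups)
}

# Snap a requested QTL position to the nearest simulated marker.
.snap_qtl <- function(panel, chrom, pos) {
  idx <- which(panel$map$chrom == chrom)
  if (!length(idx)) stop("no markers on chromosome ", chrom)
  idx[which.min(abs(panel$map$pos[idx] - pos))]
}

#' Simulate bi-regime phenotypes with known QTL architecture
#'
#' For each watering regime the accession value is the sum of the planted
#' marker effects, a polygenic term drawn with covariance proportional to
#' the realized kinship of the panel (cross-regime correlation as
#' configured), and a baseline with a relative drought shift; replicate
#' noise is scaled so the realized broad-sense heritability matches
#' `polygenic_h2`. Marker effects are calibrated against the realized
#' genotypic variances (two rescaling passes) so the realized per-marker
#' PVE matches its target. Effect sign is drawn at random per QTL; class
#' patterns are: constitutive (equal effects), control/drought-specific
#' (effect in one regime only), antagonist (opposite signs, equal
#' magnitude), differential (same sign, drought effect
#' `differential_ratio` times larger — so its drought-regime realized PVE
#' exceeds the target, which is recorded in the truth table).
#'
#' @param panel Panel from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @param trait_name Trait label in the output table (default `"trait1"`).
#' @param location Location label (default `"Avi"`).
#' @return List with `phenotypes` (replicate-level data frame with columns
#'   `accession_id`, `group`, `location`, `regime`, `replicate`, `trait`,
#'   `value`) and `truth` (data frame of class `sim_truth`: `marker_id`,
#'   `class`, `effect_C`, `effect_D`, `pve_C`, `pve_D` realized).
#' @export
simulate_phenotypes <- function(panel, config, trait_name = "trait1",
                                location = "Avi") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  work <- if (anyNA(panel$dosages)) impute_missing(panel) else panel
  n <- nrow(work$dosages)
  h2 <- config$polygenic_h2
  pves <- vapply(config$qtl, `[[`, numeric(1), "pve")
  if (sum(pves) >= max(h2, .Machine$double.eps) && length(pves)) {
    stop("sum of QTL pve targets (", signif(sum(pves), 3),
         ") exceeds the heritability budget polygenic_h2 = ", h2)
  }
  sigma2_poly <- h2 - sum(pves)
  sigma2_e <- config$replicates * (1 - h2)

  # polygenic background with kinship covariance and cross-regime correlation
  if (sigma2_poly > 0) {
    K <- bend_psd(compute_kinship(work))
    L <- t(chol(K))
    zC <- stats::rnorm(n)
    zD <- config$genetic_correlation * zC +
      sqrt(1 - config$genetic_correlation^2) * stats::rnorm(n)
    gC <- drop(L %*% zC); gD <- drop(L %*% zD)
    # calibrate the within-group polygenic variance: the between-group part
    # of a kinship-structured draw is absorbed by the fixed group effect in
    # the heritability model, so scaling the raw variance would undershoot
    # the realized H2
    grp <- factor(work$groups)
    wvar <- function(g) stats::var(stats::resid(stats::lm(g ~ grp)))
    gC <- gC * sqrt(sigma2_poly / wvar(gC))
    gD <- gD * sqrt(sigma2_poly / wvar(gD))
  } else {
    gC <- gD <- numeric(n)
  }

  # planted marker effects, calibrated against realized genotypic variance
  qidx <- integer(0); qclass <- character(0)
  effC <- numeric(0); effD <- numeric(0)
  for (q in config$qtl) {
    j <- .snap_qtl(work, q$chrom, q$pos)
    v <- stats::var(work$dosages[, j])
    if (v == 0) stop("QTL marker ", work$map$marker_id[j], " is monomorphic")
    s <- sample(c(-1, 1), 1)
    a <- s * sqrt(q$pve / v)
    pat <- switch(q$class,
                  constitutive = c(a, a),
                  control_specific = c(a, 0),
                  drought_specific = c(0, a),
                  differential = c(a, config$differential_ratio * a),
                  antagonist = c(a, -a))
    qidx <- c(qidx, j); qclass <- c(qclass, q$class)
    effC <- c(effC, pat[1]); effD <- c(effD, pat[2])
  }

  compose <- function(eC, eD) {
    AC <- gC; AD <- gD
    for (k in seq_along(qidx)) {
      g <- work$dosages[, qidx[k]]
      AC <- AC + eC[k] * g
      AD <- AD + eD[k] * g
    }
    list(AC = AC, AD = AD)
  }
  # second calibration pass: rescale each nonzero base effect so its realized
  # share of the regime's accession-mean variance hits the target
  if (length(qidx)) {
    A <- compose(effC, effD)
    VC <- stats::var(A$AC) + sigma2_e / config$replicates
    VD <- stats::var(A$AD) + sigma2_e / config$replicates
    for (k in seq_along(qidx)) {
      v <- stats::var(work$dosages[, qidx[k]])
      tgt <- config$qtl[[k]]$pve
      if (qclass[k] %in% c("constitutive", "control_specific", "antagonist",
                           "differential")) {
        sc <- sqrt(tgt * VC / (effC[k]^2 * v))
        effC[k] <- effC[k] * sc
        effD[k] <- switch(qclass[k],
                          constitutive = effC[k],
                          control_specific = 0,
                          antagonist = -effC[k],
                          differential = config$differential_ratio * effC[k])
      } else {                               # drought_specific
        sc <- sqrt(tgt * VD / (effD[k]^2 * v))
        effD[k] <- effD[k] * sc
      }
    }
  }
  A <- compose(effC, effD)
  muC <- config$baseline
  muD <- config$baseline * (1 + config$regime_shift)
  AC <- muC + A$AC
  AD <- muD + A$AD

  reps <- config$replicates
  make_rows <- function(acc_val, regime) {
    data.frame(
      accession_id = rep(work$accession_ids, each = reps),
      group = rep(work$groups, each = reps),
      location = location, regime = regime,
      replicate = rep(seq_len(reps), times = n),
      trait = trait_name,
      value = rep(acc_val, each = reps) +
        stats::rnorm(n * reps, sd = sqrt(sigma2_e)))
  }
  pheno <- rbind(make_rows(AC, "C"), make_rows(AD, "D"))

  VC <- stats::var(AC) + sigma2_e / reps
  VD <- stats::var(AD) + sigma2_e / reps
  truth <- data.frame(
    marker_id = work$map$marker_id[qidx], class = qclass,
    effect_C = effC, effect_D = effD,
    pve_C = vapply(seq_along(qidx), function(k)
      effC[k]^2 * stats::var(work$dosages[, qidx[k]]) / VC, numeric(1)),
    pve_D = vapply(seq_along(qidx), function(k)
      effD[k]^2 * stats::var(work$dosages[, qidx[k]]) / VD, numeric(1)))
  class(truth) <- c("sim_truth", "data.frame")
  list(phenotypes = pheno, truth = truth)
}
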