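test_that("Box-Cox picks lambda near 1 for symmetric data and near 0 for lognormal", {
  set.seed(1)
  bc <- boxcox_transform(rnorm(500, mean = 10))
  expect_lte(abs(bc$lambda - 1), 0.5)
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    if (abs(boxcox_transform(rlnorm(500))$lambda) < 0.25) hits <- hits + 1
  }
  expect_gte(hits, 6)
  expect_error(boxcox_transform(rep(3, 10)), "constant")
  expect_error(boxcox_transform(c(1, 2, NA)), "finite")
  # non-positive data are shifted, and the shift is recorded
  sh <- boxcox_transform(c(-2, 0, 1, 3, 8))
  expect_gt(sh$shift, 2)
})

test_that("sequential ANOVA sums of squares match balanced-design projections", {
  d <- balanced_pheno(seed = 42, effects = list(group = c(0, 2),
                                                regime = c(0, 1)))
  an <- anova_partition(d, "t", "Avi")
  expect_equal(an$term, c("Gr", "Gr(G)", "W", "GrxW", "Gr(G)xW", "residual"))
  expect_equal(sum(an$fraction), 1, tolerance = 1e-10)
  expect_equal(sum(an$df), nrow(d) - 1)
  # independent oracle: balanced-case mean decomposition
  g <- factor(d$group); a <- factor(d$accession_id); w <- factor(d$regime)
  y <- d$value; mu <- mean(y)
  m_g <- tapply(y, g, mean); m_a <- tapply(y, a, mean)
  m_w <- tapply(y, w, mean)
  m_gw <- tapply(y, interaction(g, w), mean)
  m_aw <- tapply(y, interaction(a, w), mean)
  ss_gr <- sum(table(g) * (m_g - mu)^2)
  ss_acc <- sum(table(a) * (m_a[a] - m_g[g] - 0)[!duplicated(a)] * 0) # placeholder
  ss_acc <- sum(tapply(y, a, length) * (m_a - m_g[substr(names(m_a), 2, 2)])^2)
  grp_of_acc <- tapply(as.character(d$group), d$accession_id, `[`, 1)
  ss_acc <- sum(tapply(y, a, length) * (m_a - m_g[grp_of_acc[names(m_a)]])^2)
  ss_w <- sum(table(w) * (m_w - mu)^2)
  gw <- interaction(g, w)
  ss_gw <- sum(table(gw) * (m_gw - m_g[sub("[.].*", "", names(m_gw))] -
                              m_w[sub(".*[.]", "", names(m_gw))] + mu)^2)
  expect_equal(an$sum_sq[an$term == "Gr"], unname(ss_gr), tolerance = 1e-8)
  expect_equal(an$sum_sq[an$term == "Gr(G)"], unname(ss_acc), tolerance = 1e-8)
  expect_equal(an$sum_sq[an$term == "W"], unname(ss_w), tolerance = 1e-8)
  expect_equal(an$sum_sq[an$term == "GrxW"], unname(ss_gw), tolerance = 1e-8)
})

test_that("a null watering-regime effect yields a small, non-significant W term", {
  nonsig <- 0
  for (s in 1:10) {
    d <- balanced_pheno(seed = 100 + s, acc_per_group = 6)
    an <- anova_partition(d, "t", "Avi")
    if (an$p_value[an$term == "W"] > 0.05) nonsig <- nonsig + 1
    expect_lt(an$fraction[an$term == "W"], 0.15)
  }
  expect_gte(nonsig, 8)
})

test_that("constant data give zero sums of squares for every model term", {
  d <- balanced_pheno(seed = 1)
  d$value <- 5
  an <- suppressWarnings(anova_partition(d, "t", "Avi"))
  expect_equal(an$sum_sq, rep(0, 6), tolerance = 1e-20)
})

test_that("heritability reproduces the closed form on an exactly balanced design", {
  # accession means with variance 4 and within-accession variance 2:
  # MS_b = 8, MS_w = 2 -> s2G = 3, s2e = 2, H2 = 3 / (3 + 2/2) = 0.75
  a <- sqrt(3)
  means <- c(-a, -a, a, a)
  d <- data.frame(accession_id = rep(paste0("A", 1:4), each = 2),
                  group = "SLC", location = "Avi", regime = "C",
                  replicate = rep(1:2, 4), trait = "t",
                  value = rep(means, each = 2) + c(-1, 1))
  h <- heritability(d, "t", "Avi", "C")
  expect_equal(h$sigma2_G, 3, tolerance = 1e-6)
  expect_equal(h$sigma2_e, 2, tolerance = 1e-6)
  expect_equal(h$H2, 0.75, tolerance = 1e-6)
  expect_error(heritability(d[d$replicate == 1, ], "t", "Avi", "C"),
               "inestimable")
})

test_that("heritability recovers the simulated value and rejects pure noise", {
  errs <- c()
  for (s in 1:5) {
    sim <- small_sim(seed = s, mpc = 10, n_chrom = 6)
    ph <- simulate_phenotypes(sim$panel, sim$cfg)
    h <- heritability(ph$phenotypes, "trait1", "Avi", "C")
    errs <- c(errs, h$H2 - 0.6)
  }
  expect_lt(abs(mean(errs)), 0.08)
  # with 2 replicates the null sampling spread of H2-hat is wide; a purely
  # non-genetic trait should still give mostly small estimates
  h2_null <- vapply(1:10, function(s) {
    sim <- small_sim(seed = 50 + s, mpc = 10, n_chrom = 4, polygenic_h2 = 0)
    ph <- simulate_phenotypes(sim$panel, sim$cfg)
    heritability(ph$phenotypes, "trait1", "Avi", "C")$H2
  }, numeric(1))
  expect_gte(sum(h2_null < 0.15), 6)
  expect_lt(mean(h2_null), 0.2)
})

test_that("plasticity is (D - C) / C on accession means and scale invariant", {
  d <- pheno_from_means(c(A = 10, B = 5, C = 4), c(A = 12, B = 5, C = 3.2))
  p <- plasticity(d, "t", "Avi")
  expect_equal(p$delta[p$accession_id == "A"], 0.2)
  expect_equal(p$delta[p$accession_id == "B"], 0)
  expect_equal(p$delta[p$accession_id == "C"], -0.2)
  d2 <- d; d2$value <- d2$value * 7.3
  expect_equal(plasticity(d2, "t", "Avi")$delta, p$delta)
  d3 <- pheno_from_means(c(A = 0, B = 5), c(A = 1, B = 6))
  expect_warning(p3 <- plasticity(d3, "t", "Avi"), "zero control mean")
  expect_true(is.na(p3$delta[p3$accession_id == "A"]))
})

test_that("interaction partitioning reproduces its limiting cases", {
  u <- scale(c(1, 2, 3, 4, 5))[, 1]
  v <- scale(stats::resid(lm(c(2, 1, 4, 3, 5) ~ u)))[, 1]
  names(u) <- names(v) <- paste0("A", 1:5)
  u <- u + 10                 # keep control means away from zero
  # equal SDs, r = 1: zero interaction, flagged degenerate
  ip <- interaction_partition(pheno_from_means(u, u + 3), "t", "Avi")
  expect_true(ip$degenerate)
  expect_equal(ip$fraction_reranking + ip$fraction_scale, 0)
  # equal SDs, r = 0.5: pure re-ranking
  D <- 0.5 * u + sqrt(0.75) * v
  ip2 <- interaction_partition(pheno_from_means(u, D / sd(D) * sd(u)),
                               "t", "Avi")
  expect_equal(ip2$fraction_reranking, 1, tolerance = 1e-10)
  # r = 1, sC = 2 sD: pure scale change
  ip3 <- interaction_partition(pheno_from_means(2 * u, u), "t", "Avi")
  expect_equal(ip3$fraction_scale, 1, tolerance = 1e-10)
  expect_error(interaction_partition(pheno_from_means(u[1:2], u[1:2] + 1),
                                     "t", "Avi"), "3 accessions")
})

test_that("yield is mean fruit weight times mean fruit number", {
  d <- rbind(
    pheno_from_means(c(A = 10, B = 8), c(A = 9, B = 7), trait = "FW"),
    pheno_from_means(c(A = 20, B = 0), c(A = 15, B = 2), trait = "Nbfruits"))
  y <- derive_yield(d)
  yy <- y[y$trait == "Yield", ]
  expect_equal(yy$value[yy$accession_id == "A" & yy$regime == "C"], 200)
  expect_equal(yy$value[yy$accession_id == "B" & yy$regime == "C"], 0)
  # accession missing FW is skipped with a warning
  d2 <- rbind(d, pheno_from_means(c(Z = 5), c(Z = 5), trait = "Nbfruits"))
  d2 <- d2[!(d2$trait == "FW" & d2$accession_id == "Z"), ]
  expect_silent(y2 <- derive_yield(d2))
  expect_false("Z" %in% y2$accession_id[y2$trait == "Yield"])
})

test_that("cross-regime Spearman correlations match the rank formula", {
  res <- data.frame(trait = rep(paste0("t", 1:5), 2),
                    regime = rep(c("C", "D"), each = 5),
                    H2 = c(0.3, 0.5, 0.7, 0.6, 0.9,
                           0.35, 0.45, 0.75, 0.55, 0.88),
                    sigma2_G = c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1))
  cc <- cross_regime_correlations(res)
  rk <- function(x, y) 1 - 6 * sum((rank(x) - rank(y))^2) /
    (length(x) * (length(x)^2 - 1))
  expect_equal(cc$spearman_H2, rk(res$H2[1:5], res$H2[6:10]))
  expect_equal(cc$spearman_varG, -1)
  ident <- res; ident$sigma2_G <- rep(1:5, 2)
  expect_equal(cross_regime_correlations(ident)$spearman_varG, 1)
  expect_error(cross_regime_correlations(res[c(1, 2, 6, 7), ]), "3 traits")
})

test_that("Tukey post-hoc flags shifted cells and is exact for equal cells", {
  # equal cell means with symmetric within-cell spread: all diffs exactly 0
  d <- balanced_pheno(seed = 3)
  d$value <- ifelse(d$replicate == 1, -1, 1)  # every cell mean is exactly 0
  tk <- tukey_posthoc(d, "t", "Avi")
  expect_equal(nrow(tk), choose(4, 2))
  expect_equal(tk$diff, rep(0, 6))
  expect_true(all(tk$p_adj > 0.999))
  # one cell shifted by 10 SD: its pairs significant
  d2 <- balanced_pheno(seed = 4, acc_per_group = 6)
  shift <- d2$group == "G1" & d2$regime == "D"
  d2$value[shift] <- d2$value[shift] + 10
  tk2 <- tukey_posthoc(d2, "t", "Avi")
  involved <- grepl("G1:D", tk2$pair)
  expect_true(all(tk2$p_adj[involved] < 1e-6))
})
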