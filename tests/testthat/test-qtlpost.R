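# Interval definition, gene counting, effect estimation, classification and
# cross-population overlap.

# a chromosome where markers 1,2,4 are in strong LD with the peak (3) while
# marker 5 in between is unlinked ("last marker" rule must jump the gap)
interval_panel <- function() {
  set.seed(9)
  n <- 80
  peak <- sample(c(0, 2), n, replace = TRUE)
  near <- function(x, k) { i <- sample(n, k); x[i] <- 2 - x[i]; x }
  m1 <- near(peak, 5); m2 <- near(peak, 3); m4 <- near(peak, 4)
  un1 <- sample(c(0, 2), n, replace = TRUE)
  un2 <- sample(c(0, 2), n, replace = TRUE)
  # order along the chromosome: m1(1Mb) un1(2Mb) m2(3Mb) peak(4Mb) un2(5Mb) m4(6Mb) un3(9Mb)
  un3 <- sample(c(0, 2), n, replace = TRUE)
  toy_panel(cbind(m1, un1, m2, peak, un2, m4, un3),
            pos = c(1e6, 2e6, 3e6, 4e6, 5e6, 6e6, 9e6))
}

test_that("LD intervals follow the last-linked-marker rule and allow gaps", {
  p <- interval_panel()
  peak_id <- p$map$marker_id[4]
  iv <- ld_interval(p, peak_id, 0.28)
  expect_equal(unname(iv), c(1e6, 6e6))   # jumps over unlinked un1 and un2
  # no linked neighbors: degenerate interval at the peak position
  iv2 <- ld_interval(p, p$map$marker_id[7], 0.99)
  expect_equal(unname(iv2), c(9e6, 9e6))
  # monotone in the threshold: lower threshold never shrinks the interval
  widths <- vapply(c(0.9, 0.6, 0.3, 0.1, 0.05), function(t) {
    iv <- ld_interval(p, peak_id, t); iv[2] - iv[1]
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
})

test_that("LD intervals cover a simulated high-LD block", {
  cover <- 0
  for (s in 1:10) {
    cfg <- sim_config(markers_per_chromosome = 30, n_chromosomes = 2,
                      ld_block_length = 8e6, seed = 800 + s)
    panel <- simulate_genotypes(cfg)
    j <- 15
    iv <- ld_interval(panel, panel$map$marker_id[j], 0.28)
    r2 <- vapply(which(panel$map$chrom == 1), function(k)
      ld_r2(panel$dosages[, j], panel$dosages[, k]), numeric(1))
    linked <- which(panel$map$chrom == 1)[!is.na(r2) & r2 >= 0.28]
    if (iv[1] <= min(panel$map$pos[linked]) &&
        iv[2] >= max(panel$map$pos[linked])) cover <- cover + 1
  }
  expect_equal(cover, 10)
})

test_that("gene counts use inclusive overlap on a toy GFF3", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\ttoy\tgene\t100\t200\t.\t+\t.\tID=g1",
    "1\ttoy\tgene\t300\t400\t.\t+\t.\tID=g2",
    "1\ttoy\tgene\t500\t650\t.\t-\t.\tID=g3",
    "1\ttoy\tgene\t900\t950\t.\t+\t.\tID=g4",
    "2\ttoy\tgene\t100\t200\t.\t+\t.\tID=g5",
    "1\ttoy\tmRNA\t100\t200\t.\t+\t.\tID=t1;Parent=g1"), gff)
  ann <- read_gene_annotation(gff)
  expect_equal(length(ann), 5L)
  expect_equal(count_genes(c(150, 520), 1, ann), 3L)   # g1, g2, g3
  expect_equal(count_genes(c(651, 899), 1, ann), 0L)   # empty gap
  expect_equal(count_genes(c(660, 900), 1, ann), 1L)   # abutting g4 counts
  expect_equal(count_genes(c(150, 520), 2, ann), 1L)   # chromosome-aware
  # malformed lines are skipped with a warning
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\ttoy\tgene\t100\t200\t.\t+\t.\tID=g1",
               "garbage line without tabs",
               "1\ttoy\tgene\tXXX\t400"), bad)
  expect_warning(ann2 <- read_gene_annotation(bad), "malformed")
  expect_equal(length(ann2), 1L)
})

test_that("allelic effects are (minor mean - major mean) / 2", {
  # 8 accessions: 3 minor carriers with phenotype mean 10, 5 majors mean 6
  g <- c(2, 2, 2, 0, 0, 0, 0, 0)
  p <- toy_panel(cbind(g, c(0, 2, 0, 2, 0, 2, 0, 2)))
  yC <- c(11, 10, 9, 7, 6, 6, 5, 6)      # minor mean 10, major mean 6
  yD <- c(5, 5, 5, 5, 5, 5, 5, 5)
  eff <- allelic_effects(p, yC, yD, p$map$marker_id[1])
  expect_equal(unname(eff["effect_C"]), 2)
  expect_equal(unname(eff["effect_D"]), 0)
  # hand-computed toy with a heterozygote counted on the carrier side
  g2 <- c(2, 1, 0, 0, 0, 0, 0, 0)
  p2 <- toy_panel(cbind(g2, g))
  eff2 <- allelic_effects(p2, yC, yD, p2$map$marker_id[1])
  expect_equal(unname(eff2["effect_C"]),
               (mean(yC[1:2]) - mean(yC[3:8])) / 2)
  expect_error(allelic_effects(toy_panel(cbind(rep(2, 8), g)), yC, yD,
                               "S01_01000000"), "monomorphic")
})

test_that("classification is total and matches the stated rule on all 32 source sets", {
  combos <- expand.grid(mlmm_C = c(FALSE, TRUE), mlmm_D = c(FALSE, TRUE),
                        mlmm_delta = c(FALSE, TRUE),
                        mtmm_global = c(FALSE, TRUE),
                        mtmm_gxw = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    src <- as.list(combos[i, ])
    if (!any(unlist(src))) {
      expect_error(classify_qtl(src), "empty source set")
      next
    }
    got <- classify_qtl(src, effect_C = 1, effect_D = 2)
    expected <-
      if (src$mlmm_delta || src$mtmm_gxw) "interactive"
      else if ((src$mlmm_C && src$mlmm_D) || src$mtmm_global) "constitutive"
      else if (src$mlmm_C) "control_specific"
      else "drought_specific"
    expect_equal(got$type, expected)
    expect_equal(got$subtype,
                 if (expected == "interactive") "differential" else "none")
  }
  # subtype by effect signs
  expect_equal(classify_qtl(list(mlmm_delta = TRUE), 1, -1)$subtype,
               "antagonist")
  expect_equal(classify_qtl(list(mlmm_delta = TRUE), 1, 2)$subtype,
               "differential")
  expect_equal(classify_qtl(list(mlmm_C = TRUE, mlmm_D = TRUE))$type,
               "constitutive")
})

test_that("trait grouping collects acids and sugars and passes others through", {
  expect_equal(group_trait("pH.Avi"), "acids")
  expect_equal(group_trait("MalicFM.Avi"), "acids")
  expect_equal(group_trait("CitricDM"), "acids")
  expect_equal(group_trait("SSC.Avi"), "sugars")
  expect_equal(group_trait("GlucoseDM.Avi"), "sugars")
  expect_equal(group_trait("FructoseFM"), "sugars")
  expect_equal(group_trait("FW.Avi"), "other:FW")
  expect_equal(group_trait(c("pH", "FW")), c("acids", "other:FW"))
})

test_that("QTL overlap requires same group, same chromosome and touching intervals", {
  A <- data.frame(trait_group = c("acids", "sugars", "acids"),
                  chrom = c(1, 1, 2), start = c(10, 10, 50),
                  end = c(20, 20, 60))
  B <- data.frame(trait_group = c("acids", "acids", "sugars"),
                  chrom = c(1, 1, 1), start = c(20, 21, 15),
                  end = c(30, 30, 25))
  ov <- overlap_qtls(A, B)
  expect_equal(nrow(ov$common), 2L)  # acids [10,20]x[20,30] touch; sugars overlap
  expect_equal(ov$n_A_only, 1L)      # acids on chromosome 2
  expect_equal(ov$n_B_only, 1L)      # acids [21,30] does not touch [10,20]
  ov2 <- overlap_qtls(B, A)
  expect_equal(nrow(ov2$common), nrow(ov$common))
  expect_equal(ov2$n_A_only, ov$n_B_only)
})

test_that("qtl_records assembles interval, classification and effects", {
  p <- interval_panel()
  n <- nrow(p$dosages)
  set.seed(123)
  yC <- p$dosages[, 4] + rnorm(n, sd = 0.5) + 10
  yD <- rnorm(n, sd = 0.5) + 10
  peaks <- data.frame(trait = "SSC.Avi", location = "Avi",
                      marker_id = p$map$marker_id[4],
                      mlmm_C = TRUE, mlmm_D = FALSE, mlmm_delta = TRUE,
                      mtmm_global = FALSE, mtmm_gxw = TRUE)
  rec <- qtl_records(peaks, p, yC, yD, 0.28)
  expect_equal(rec$type, "interactive")
  expect_equal(rec$trait_group, "sugars")
  expect_equal(rec$start, 1e6)
  expect_equal(rec$end, 6e6)
  expect_gt(rec$effect_C, 0.5)
  expect_lt(abs(rec$effect_D), 0.3)
  expect_equal(rec$subtype,
               if (sign(rec$effect_C) != sign(rec$effect_D)) "antagonist"
               else "differential")
})
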