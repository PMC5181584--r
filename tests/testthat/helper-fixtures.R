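# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A tiny hand-specified panel: `dosages` is accessions x markers.
toy_panel <- function(dosages, chrom = NULL, pos = NULL) {
  m <- ncol(dosages)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq(1e6, by = 1e6, length.out = m)
  genotype_panel(dosages, data.frame(chrom = chrom, pos = pos))
}

# Small simulated structured panel + kinship/structure, cached per test file.
small_sim <- function(seed = 1, mpc = 25, n_chrom = 12, fst = 0.2,
                      qtl = list(), ...) {
  cfg <- sim_config(markers_per_chromosome = mpc, n_chromosomes = n_chrom,
                    fst = fst, qtl = qtl, seed = seed, ...)
  panel <- simulate_genotypes(cfg)
  list(cfg = cfg, panel = panel)
}

# Replicate-level phenotype table from per-accession regime means.
pheno_from_means <- function(mC, mD, acc = names(mC), group = "SLC",
                             trait = "t", location = "Avi") {
  rbind(
    data.frame(accession_id = acc, group = group, location = location,
               regime = "C", replicate = 1L, trait = trait, value = mC),
    data.frame(accession_id = acc, group = group, location = location,
               regime = "D", replicate = 1L, trait = trait, value = mD))
}

# Balanced two-group phenotype fixture for the ANOVA tests.
balanced_pheno <- function(seed = 42, n_groups = 2, acc_per_group = 4,
                           reps = 2, effects = NULL) {
  set.seed(seed)
  grid <- expand.grid(g = seq_len(n_groups), a = seq_len(acc_per_group),
                      w = c("C", "D"), r = seq_len(reps))
  val <- rnorm(nrow(grid))
  if (!is.null(effects)) {
    val <- val + effects$group[grid$g] +
      effects$regime[as.integer(grid$w == "D") + 1L]
  }
  data.frame(accession_id = paste0("g", grid$g, "a", grid$a),
             group = paste0("G", grid$g), location = "Avi",
             regime = as.character(grid$w), replicate = grid$r,
             trait = "t", value = val)
}
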