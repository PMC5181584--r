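# End-to-end orchestration: simulate (or load) -> QC -> phenotype statistics
# -> mixed-model scans -> LD intervals -> classification -> manifest.

#' Default pipeline configuration
#'
#' All analysis thresholds are surfaced here; defaults are the conventional
#' values for this design: significance 1e-4, at most 5 cofactors, 95th
#' percentile critical LD from 100 000 unlinked pairs, MAF 0.04, marker
#' missingness 0.10, accession missingness 0.25, 3 structure axes.
#'
#' @param sim A [sim_config()] describing the panel to simulate, or `NULL`
#'   when `genotype_csv`/`phenotype_csv` are given.
#' @param genotype_csv,phenotype_csv Input files (see
#'   [read_dosage_csv()]); used when `sim` is `NULL`.
#' @param annotation_gff3 Optional GFF3 gene annotation for interval gene
#'   counts.
#' @param p_threshold,max_cofactors,ld_percentile,n_unlinked_pairs,maf,missing_marker,missing_accession,pcoa_axes
#'   Analysis thresholds (see Description).
#' @param transform Apply the minimum-skewness Box-Cox transformation to
#'   each trait before mapping (default TRUE).
#' @param seed Integer seed governing every stochastic step.
#' @param outdir Output directory for tables and the JSON manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = NULL, genotype_csv = NULL, phenotype_csv = NULL,
                       annotation_gff3 = NULL, p_threshold = 1e-4,
                       max_cofactors = 5, ld_percentile = 0.95,
                       n_unlinked_pairs = 1e5, maf = 0.04,
                       missing_marker = 0.10, missing_accession = 0.25,
                       pcoa_axes = 3, transform = TRUE, seed = 1,
                       outdir = tempfile("gxwqtl_run")) {
  stopifnot(p_threshold > 0, p_threshold < 1, max_cofactors >= 0,
            ld_percentile > 0, ld_percentile < 1, maf >= 0, maf < 0.5,
            missing_marker >= 0, missing_marker <= 1,
            missing_accession >= 0, missing_accession <= 1, pcoa_axes >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `sim` mapping is
#' passed to [sim_config()] (its `qtl` entry as a list of mappings).
#'
#' @param file YAML path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(run_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full association-mapping pipeline
#'
#' Executes simulate/load -> genotype QC -> kinship, structure and critical
#' LD -> per-trait variance dissection and plasticity -> univariate
#' multi-locus scans (control, drought, plasticity) and the bivariate
#' global / G x W scans -> LD intervals and QTL classification, writing
#' versioned TSV/CSV outputs and a JSON manifest. Fully reproducible from
#' (inputs, seed).
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return The manifest, invisibly (also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)

  truth <- NULL
  if (!is.null(config$sim)) {
    # one sim_config, or a (possibly named) list of them sharing the first
    # config's genotypes: one simulated trait per config
    sims <- if (inherits(config$sim, "sim_config")) list(config$sim)
            else config$sim
    panel <- .stage("simulate", simulate_genotypes(sims[[1]]))
    pheno <- NULL; truth_rows <- list()
    for (i in seq_along(sims)) {
      nm <- names(sims)[i]
      if (is.null(nm) || !nzchar(nm)) nm <- paste0("trait", i)
      sp <- .stage("simulate",
                   simulate_phenotypes(panel, sims[[i]], trait_name = nm))
      pheno <- rbind(pheno, sp$phenotypes)
      if (nrow(sp$truth)) truth_rows[[nm]] <- cbind(trait = nm, sp$truth)
    }
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
    if (!is.null(truth)) {
      rownames(truth) <- NULL
      utils::write.csv(truth, out("sim_truth.csv"), row.names = FALSE)
    }
  } else {
    panel <- .stage("load", {
      if (is.null(config$genotype_csv) || !file.exists(config$genotype_csv))
        stop("genotype file not found: ", config$genotype_csv)
      read_dosage_csv(config$genotype_csv)
    })
    pheno <- .stage("load", {
      if (is.null(config$phenotype_csv) || !file.exists(config$phenotype_csv))
        stop("phenotype file not found: ", config$phenotype_csv)
      utils::read.csv(config$phenotype_csv)
    })
  }

  qc <- .stage("qc", {
    filt <- filter_markers(panel, config$missing_accession,
                           config$missing_marker, config$maf)
    list(panel = impute_missing(filt), log = attr(filt, "filter_log"))
  })
  panel <- qc$panel
  write_dosage_csv(panel, out("panel_filtered.csv"))

  K <- .stage("kinship", compute_kinship(panel))
  utils::write.table(K, out("kinship.tsv"), sep = "\t", quote = FALSE)
  eig <- kinship_eigen(K)
  pcoa <- .stage("structure", compute_pcoa(K, config$pcoa_axes))
  utils::write.table(pcoa$coords, out("pcoa_coords.tsv"), sep = "\t",
                     quote = FALSE)
  ld_thr <- .stage("ld", critical_ld_threshold(
    panel, n_pairs = config$n_unlinked_pairs,
    percentile = config$ld_percentile, seed = config$seed))

  annotation <- if (!is.null(config$annotation_gff3))
    .stage("annotation", read_gene_annotation(config$annotation_gff3))
  else NULL

  pheno <- pheno[pheno$accession_id %in% panel$accession_ids, , drop = FALSE]
  traits <- unique(pheno$trait)
  locations <- unique(pheno$location)
  covs <- pcoa$coords

  pheno_rows <- list(); qtl_rows <- list(); assoc_rows <- list()
  for (loc in locations) for (tr in traits) {
    sub <- pheno[pheno$trait == tr & pheno$location == loc, , drop = FALSE]
    if (nrow(sub) == 0L) next
    res <- .stage(paste0("pheno:", tr), {
      an <- anova_partition(sub, tr, loc)
      hC <- heritability(sub, tr, loc, "C")
      hD <- heritability(sub, tr, loc, "D")
      ip <- interaction_partition(sub, tr, loc)
      list(anova = an, hC = hC, hD = hD, ip = ip)
    })
    pheno_rows[[paste(loc, tr)]] <- data.frame(
      trait = tr, location = loc, H2_C = res$hC$H2, H2_D = res$hD$H2,
      varG_C = res$hC$sigma2_G, varG_D = res$hD$sigma2_G,
      frac_genotype = res$anova$fraction[res$anova$term == "Gr(G)"],
      frac_regime = res$anova$fraction[res$anova$term == "W"],
      frac_reranking = res$ip$fraction_reranking)

    scans <- .stage(paste0("scan:", tr), {
      map_tab <- sub
      if (isTRUE(config$transform)) {
        bc <- boxcox_transform(sub$value)
        map_tab$value <- bc$values
      }
      yC <- accession_means(map_tab, tr, loc, "C", panel)
      yD <- accession_means(map_tab, tr, loc, "D", panel)
      pl <- plasticity(sub, tr, loc)
      delta <- pl$delta[match(panel$accession_ids, pl$accession_id)]
      if (anyNA(yC) || anyNA(yD) || anyNA(delta)) {
        stop("phenotypes missing for some panel accessions")
      }
      mlC <- mlmm_select(panel, yC, covs, eig, config$max_cofactors,
                         config$p_threshold)
      mlD <- mlmm_select(panel, yD, covs, eig, config$max_cofactors,
                         config$p_threshold)
      mlDelta <- mlmm_select(panel, delta, covs, eig, config$max_cofactors,
                             config$p_threshold)
      vc <- fit_mtmm_null(yC, yD, covs, eig)
      mt <- mtmm_tests(panel, vc)
      list(yC = yC, yD = yD, mlC = mlC, mlD = mlD, mlDelta = mlDelta,
           mt = mt)
    })

    sig_global <- scans$mt$marker_id[!is.na(scans$mt$p_global) &
                                       scans$mt$p_global < config$p_threshold]
    sig_gxw <- scans$mt$marker_id[!is.na(scans$mt$p_gxw) &
                                    scans$mt$p_gxw < config$p_threshold]
    mt_sig <- unique(c(sig_global, sig_gxw))
    if (length(mt_sig)) {
      ptab <- data.frame(
        marker_id = mt_sig,
        p_value = pmin(scans$mt$p_global[match(mt_sig, scans$mt$marker_id)],
                       scans$mt$p_gxw[match(mt_sig, scans$mt$marker_id)],
                       na.rm = TRUE))
      mt_sig <- merge_ld_significant(ptab, panel, ld_thr)$marker_id
    }
    peak_ids <- unique(c(scans$mlC$optimal_cofactors,
                         scans$mlD$optimal_cofactors,
                         scans$mlDelta$optimal_cofactors, mt_sig))
    if (length(peak_ids)) {
      peaks <- data.frame(
        trait = tr, location = loc, marker_id = peak_ids,
        mlmm_C = peak_ids %in% scans$mlC$optimal_cofactors,
        mlmm_D = peak_ids %in% scans$mlD$optimal_cofactors,
        mlmm_delta = peak_ids %in% scans$mlDelta$optimal_cofactors,
        mtmm_global = peak_ids %in% sig_global,
        mtmm_gxw = peak_ids %in% sig_gxw)
      # allelic effects on the raw accession means
      yCr <- accession_means(sub, tr, loc, "C", panel)
      yDr <- accession_means(sub, tr, loc, "D", panel)
      qtl_rows[[paste(loc, tr)]] <- .stage(
        paste0("classify:", tr),
        qtl_records(peaks, panel, yCr, yDr, ld_thr, annotation))
    }
    assoc_rows[[paste(loc, tr)]] <- data.frame(
      trait = tr, location = loc,
      global_pve_C = global_pve(panel, scans$yC,
                                scans$mlC$optimal_cofactors, covs, eig),
      global_pve_D = global_pve(panel, scans$yD,
                                scans$mlD$optimal_cofactors, covs, eig))
  }

  pheno_tab <- do.call(rbind, pheno_rows)
  utils::write.table(pheno_tab, out("phenostats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  qtl_tab <- if (length(qtl_rows)) do.call(rbind, qtl_rows) else NULL
  if (!is.null(qtl_tab)) {
    utils::write.table(qtl_tab, out("qtl_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  assoc_tab <- do.call(rbind, assoc_rows)

  type_counts <- if (!is.null(qtl_tab)) {
    tc <- table(factor(qtl_tab$type,
                       levels = c("constitutive", "control_specific",
                                  "drought_specific", "interactive")))
    as.list(tc)
  } else list(constitutive = 0, control_specific = 0, drought_specific = 0,
              interactive = 0)

  manifest <- list(
    seed = config$seed,
    n_accessions = nrow(panel$dosages),
    n_markers = ncol(panel$dosages),
    filter_log = qc$log,
    critical_ld_threshold = as.numeric(ld_thr),
    traits = pheno_tab,
    global_pve = assoc_tab,
    qtl_counts = type_counts,
    n_qtl = if (is.null(qtl_tab)) 0L else nrow(qtl_tab),
    truth = truth)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
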