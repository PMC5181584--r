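#' LD-based confidence interval around a peak marker
#'
#' Computes r-squared between the peak marker and every other marker on the
#' same chromosome. The lower bound is the position of the most distal
#' marker below the peak whose LD with it is at least the critical
#' threshold ("last marker" rule: intervening unlinked markers do not stop
#' the extension); the upper bound is symmetric. With no linked marker in a
#' direction the bound is the peak position itself.
#'
#' @param panel Imputed [genotype_panel()].
#' @param peak_marker Marker id of the significant marker.
#' @param threshold Critical LD threshold (r-squared).
#' @return Integer vector `c(start, end)` in 1-based inclusive base pairs.
#' @export
ld_interval <- function(panel, peak_marker, threshold) {
  j <- match(peak_marker, panel$map$marker_id)
  if (is.na(j)) stop("peak marker not in panel")
  chrom <- panel$map$chrom[j]
  pos <- panel$map$pos[j]
  same <- which(panel$map$chrom == chrom)
  g <- panel$dosages[, j]
  r2 <- vapply(same, function(k) {
    if (k == j) return(1)
    v <- ld_r2(g, panel$dosages[, k])
    if (is.na(v)) -Inf else v
  }, numeric(1))
  linked <- same[r2 >= threshold]
  lp <- panel$map$pos[linked]
  start <- if (any(lp < pos)) min(lp[lp < pos]) else pos
  end <- if (any(lp > pos)) max(lp[lp > pos]) else pos
  c(start = start, end = end)
}

#' Load gene annotation from a GFF3 file
#'
#' Reads features of type `"gene"` into a `GRanges` used by
#' [count_genes()]. Chromosome names are normalized to integers by
#' stripping non-digit prefixes.
#'
#' @param file Path to a GFF3 file. Malformed data lines (fewer than nine
#'   tab-separated fields or non-numeric coordinates) are skipped with a
#'   warning.
#' @return A `GRanges` of gene spans with integer `seqnames`.
#' @export
read_gene_annotation <- function(file) {
  lines <- readLines(file)
  data <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  coord_ok <- vapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    length(f) >= 5 && !is.na(suppressWarnings(as.numeric(f[4]))) &&
      !is.na(suppressWarnings(as.numeric(f[5])))
  }, logical(1))
  bad <- data & (nf < 9 | !coord_ok)
  if (any(bad)) {
    warning(sum(bad), " malformed GFF line(s) skipped")
    file <- tempfile(fileext = ".gff3")
    writeLines(lines[!bad], file)
  }
  gr <- rtracklayer::import(file, format = "gff3")
  gr <- gr[gr$type == "gene"]
  lv <- as.character(GenomicRanges::seqnames(gr))
  chrom <- sub("^.*?(\\d+)$", "\\1", lv)
  chrom <- sub("^0+", "", chrom)
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::ranges(gr),
                         gene_id = if (!is.null(gr$ID)) gr$ID else
                           as.character(seq_along(gr)))
}

#' Count genes overlapping a QTL interval
#'
#' A gene is counted when its span overlaps the interval by at least one
#' base pair (1-based inclusive coordinates; exact abutment counts).
#'
#' @param interval Numeric `c(start, end)` in base pairs.
#' @param chrom Chromosome number of the interval.
#' @param annotation A `GRanges` from [read_gene_annotation()].
#' @return Integer gene count.
#' @export
count_genes <- function(interval, chrom, annotation) {
  q <- GenomicRanges::GRanges(seqnames = as.character(as.integer(chrom)),
                              ranges = IRanges::IRanges(start = interval[1],
                                                        end = interval[2]))
  GenomicRanges::countOverlaps(q, annotation)
}

#' Allelic effects of a marker under both regimes
#'
#' Per regime, half the difference between the mean phenotype of
#' minor-allele carriers and major-allele carriers:
#' `(minor mean - major mean) / 2`. Accessions are assigned by rounded
#' dosage on the minor-allele coding; heterozygotes count as minor-allele
#' carriers (this panel is nearly fully homozygous so the choice is
#' marginal; it is recorded here for reproducibility).
#'
#' @param panel Imputed [genotype_panel()].
#' @param y_C,y_D Accession-mean trait vectors aligned to the panel.
#' @param marker Marker id.
#' @return Numeric `c(effect_C, effect_D)` in trait units.
#' @export
allelic_effects <- function(panel, y_C, y_D, marker) {
  j <- match(marker, panel$map$marker_id)
  if (is.na(j)) stop("marker not in panel")
  g <- panel$dosages[, j]
  if (stats::sd(g) == 0) stop("monomorphic marker: effects undefined")
  if (mean(g) / 2 > 0.5) g <- 2 - g        # minor-allele coding
  carrier <- round(g) >= 1
  if (!any(carrier) || all(carrier)) stop("monomorphic after rounding")
  eff <- function(y) (mean(y[carrier]) - mean(y[!carrier])) / 2
  c(effect_C = eff(y_C), effect_D = eff(y_D))
}

#' Classify a QTL from the tests in which it was significant
#'
#' A marker significant on the plasticity scan and/or the G x W test is
#' `interactive` (this takes precedence); its subtype is `antagonist` when
#' the allelic effect changes sign between regimes and `differential` when
#' only the intensity changes. Otherwise, significance under both regime
#' scans or under the MTMM global test gives `constitutive`; significance
#' in exactly one regime scan gives `control_specific` or
#' `drought_specific`.
#'
#' @param sources Named logical vector (or list) with elements `mlmm_C`,
#'   `mlmm_D`, `mlmm_delta`, `mtmm_global`, `mtmm_gxw` indicating the tests
#'   in which the marker was significant. Missing elements count as FALSE;
#'   all FALSE is an error.
#' @param effect_C,effect_D Allelic effects per regime (needed only for the
#'   interactive subtype).
#' @return List with `type` (one of `"constitutive"`, `"control_specific"`,
#'   `"drought_specific"`, `"interactive"`) and `subtype` (`"antagonist"`,
#'   `"differential"`, or `"none"`).
#' @export
classify_qtl <- function(sources, effect_C = NA_real_, effect_D = NA_real_) {
  s <- c(mlmm_C = isTRUE(as.vector(sources[["mlmm_C"]])),
         mlmm_D = isTRUE(as.vector(sources[["mlmm_D"]])),
         mlmm_delta = isTRUE(as.vector(sources[["mlmm_delta"]])),
         mtmm_global = isTRUE(as.vector(sources[["mtmm_global"]])),
         mtmm_gxw = isTRUE(as.vector(sources[["mtmm_gxw"]])))
  if (!any(s)) stop("empty source set: marker significant in no test")
  if (s[["mlmm_delta"]] || s[["mtmm_gxw"]]) {
    subtype <- if (!is.na(effect_C) && !is.na(effect_D) &&
                   sign(effect_C) != sign(effect_D)) "antagonist"
               else "differential"
    return(list(type = "interactive", subtype = subtype))
  }
  if ((s[["mlmm_C"]] && s[["mlmm_D"]]) || s[["mtmm_global"]]) {
    return(list(type = "constitutive", subtype = "none"))
  }
  if (s[["mlmm_C"]]) return(list(type = "control_specific", subtype = "none"))
  list(type = "drought_specific", subtype = "none")
}

#' Assign a trait to a comparison group
#'
#' pH and the malic/citric acid contents are grouped as `"acids"`; SSC and
#' the glucose/fructose contents as `"sugars"`. Any location or
#' fresh/dry-matter suffix (e.g. `"pH.Avi"`, `"GlucoseDM"`) is ignored.
#' Other traits pass through as `"other:<name>"`.
#'
#' @param trait Trait name(s).
#' @return Character vector of trait groups.
#' @export
group_trait <- function(trait) {
  base <- sub("\\..*$", "", trait)
  core <- sub("(FM|DM)$", "", base)
  vapply(seq_along(trait), function(i) {
    b <- tolower(core[i])
    if (b %in% c("ph", "malic", "citric", "malicacid", "citricacid")) "acids"
    else if (b %in% c("ssc", "glucose", "fructose")) "sugars"
    else paste0("other:", base[i])
  }, character(1))
}

#' Build a QTL record table
#'
#' Combines peak markers, their LD intervals, classification, allelic
#' effects and (optionally) gene counts into one table, one row per QTL.
#'
#' @param peaks Data frame with columns `trait`, `location`, `marker_id`
#'   and logical source columns `mlmm_C`, `mlmm_D`, `mlmm_delta`,
#'   `mtmm_global`, `mtmm_gxw`.
#' @param panel Imputed [genotype_panel()].
#' @param y_C,y_D Accession-mean trait vectors (for allelic effects).
#' @param threshold Critical LD threshold.
#' @param annotation Optional `GRanges` gene annotation.
#' @return Data frame of class `qtl_table` with columns `trait`,
#'   `trait_group`, `location`, `marker_id`, `chrom`, `start`, `end`,
#'   `n_genes`, `type`, `subtype`, `effect_C`, `effect_D`, `sources`.
#' @export
qtl_records <- function(peaks, panel, y_C, y_D, threshold,
                        annotation = NULL) {
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    mk <- peaks$marker_id[i]
    j <- match(mk, panel$map$marker_id)
    iv <- ld_interval(panel, mk, threshold)
    eff <- allelic_effects(panel, y_C, y_D, mk)
    src <- as.list(peaks[i, c("mlmm_C", "mlmm_D", "mlmm_delta",
                              "mtmm_global", "mtmm_gxw")])
    cl <- classify_qtl(src, eff[1], eff[2])
    ng <- if (is.null(annotation)) NA_integer_ else
      count_genes(iv, panel$map$chrom[j], annotation)
    data.frame(trait = peaks$trait[i],
               trait_group = group_trait(peaks$trait[i]),
               location = peaks$location[i], marker_id = mk,
               chrom = panel$map$chrom[j], start = iv[1], end = iv[2],
               n_genes = ng, type = cl$type, subtype = cl$subtype,
               effect_C = unname(eff[1]), effect_D = unname(eff[2]),
               sources = paste(names(src)[unlist(src)], collapse = "+"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qtl_table", "data.frame")
  out
}

#' Overlap QTL sets from two populations
#'
#' Two QTLs are the same when they belong to the same trait group, lie on
#' the same chromosome and their confidence intervals overlap by at least
#' one base pair (inclusive; exact touch counts). QTL type and trial
#' location are ignored. The comparison is symmetric.
#'
#' @param set_A,set_B Data frames with columns `trait_group`, `chrom`,
#'   `start`, `end` (e.g. from [qtl_records()]).
#' @return List: `common` (data frame of index pairs `i_A`, `i_B`),
#'   `n_common_A`, `n_common_B`, `n_A_only`, `n_B_only`.
#' @export
overlap_qtls <- function(set_A, set_B) {
  pairs <- list()
  for (i in seq_len(nrow(set_A))) {
    for (j in seq_len(nrow(set_B))) {
      if (set_A$trait_group[i] == set_B$trait_group[j] &&
          set_A$chrom[i] == set_B$chrom[j] &&
          set_A$start[i] <= set_B$end[j] &&
          set_B$start[j] <= set_A$end[i]) {
        pairs[[length(pairs) + 1L]] <- data.frame(i_A = i, i_B = j)
      }
    }
  }
  common <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(i_A = integer(0), i_B = integer(0))
  list(common = common,
       n_common_A = length(unique(common$i_A)),
       n_common_B = length(unique(common$i_B)),
       n_A_only = nrow(set_A) - length(unique(common$i_A)),
       n_B_only = nrow(set_B) - length(unique(common$i_B)))
}
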