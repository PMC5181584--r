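#' Construct a genotype panel
#'
#' A genotype panel holds a dosage matrix (accessions x markers, values in
#' `[0, 2]`, `NA` for missing calls), a marker map and accession metadata.
#' Dosages count copies of the alternate (arbitrary) allele; all downstream
#' statistics are invariant to the coding orientation of each marker.
#'
#' @param dosages Numeric matrix, accessions in rows, markers in columns.
#'   Values must lie in `[0, 2]` or be `NA`.
#' @param map Data frame with columns `chrom` (integer 1-12), `pos`
#'   (1-based base-pair position) and `marker_id`; one row per marker, in the
#'   column order of `dosages`. If `marker_id` is missing it is generated with
#'   [rename_marker()].
#' @param accession_ids Character vector of accession identifiers.
#' @param groups Character vector of genetic group labels (e.g. `"SP"`,
#'   `"SLC"`, `"mixture"`), one per accession.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages`, `map`, `accession_ids`, `groups`. The map is sorted by
#'   (chromosome, position) and the dosage columns reordered to match.
#' @export
genotype_panel <- function(dosages, map, accession_ids = rownames(dosages),
                           groups = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(accession_ids)) {
    accession_ids <- paste0("acc", seq_len(nrow(dosages)))
  }
  if (is.null(groups)) groups <- rep("pop", nrow(dosages))
  map <- as.data.frame(map)
  if (!all(c("chrom", "pos") %in% names(map))) {
    stop("map must contain columns 'chrom' and 'pos'")
  }
  if (nrow(map) != ncol(dosages)) {
    stop("map has ", nrow(map), " rows but dosages has ", ncol(dosages),
         " markers")
  }
  if (length(groups) != nrow(dosages)) {
    stop("groups length does not match the number of accessions")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosage values must lie in [0, 2]")
  if (is.null(map$marker_id)) {
    map$marker_id <- rename_marker(map$chrom, map$pos)
  }
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  dosages <- dosages[, ord, drop = FALSE]
  dimnames(dosages) <- list(accession_ids, map$marker_id)
  structure(
    list(dosages = dosages, map = map,
         accession_ids = as.character(accession_ids),
         groups = as.character(groups)),
    class = "genotype_panel")
}

#' @exportS3Method base::print
print.genotype_panel <- function(x, ...) {
  nmiss <- sum(is.na(x$dosages))
  cat("genotype_panel:", nrow(x$dosages), "accessions x", ncol(x$dosages),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                                 table(x$groups)), collapse = ", "), "\n")
  if (nmiss > 0) {
    cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss,
                100 * nmiss / length(x$dosages)))
  }
  invisible(x)
}

#' Standard marker identifier from genome coordinates
#'
#' Markers are named `S<chrom>_<pos>` with the chromosome zero-padded to two
#' digits and the position to eight, e.g. base pair 58 000 085 on chromosome 1
#' becomes `"S01_58000085"`.
#'
#' @param chrom Integer chromosome number(s) in 1-12.
#' @param pos Integer base-pair position(s), 1-based, >= 1.
#' @return Character vector of marker identifiers.
#' @examples
#' rename_marker(1, 58000085)  # "S01_58000085"
#' rename_marker(4, 3214865)   # "S04_03214865"
#' @export
rename_marker <- function(chrom, pos) {
  chrom <- as.integer(chrom)
  pos <- as.numeric(pos)
  if (any(is.na(chrom)) || any(chrom < 1L) || any(chrom > 12L)) {
    stop("chromosome must lie in 1-12")
  }
  if (any(is.na(pos)) || any(pos < 1)) stop("position must be >= 1")
  sprintf("S%02d_%08.0f", chrom, pos)
}

#' Write a genotype panel to a dosage CSV
#'
#' Rows are accessions, columns are marker identifiers; the marker map and
#' group labels are written alongside.
#'
#' @param panel A [genotype_panel()].
#' @param file Path of the dosage CSV. The map is written to
#'   `<file>.map.csv` and accession groups to `<file>.groups.csv`.
#' @return `file`, invisibly.
#' @export
write_dosage_csv <- function(panel, file) {
  df <- data.frame(accession_id = panel$accession_ids,
                   group = panel$groups,
                   panel$dosages, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  utils::write.csv(panel$map, paste0(file, ".map.csv"), row.names = FALSE)
  invisible(file)
}

#' Read a genotype panel from a dosage CSV
#'
#' @param file Dosage CSV written by [write_dosage_csv()], with a
#'   `<file>.map.csv` companion. Missing calls may be empty or `NA`.
#' @return A [genotype_panel()].
#' @export
read_dosage_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  map <- utils::read.csv(paste0(file, ".map.csv"))
  dos <- as.matrix(df[, !(names(df) %in% c("accession_id", "group")),
                      drop = FALSE])
  genotype_panel(dos, map, accession_ids = df$accession_id,
                 groups = if ("group" %in% names(df)) df$group else NULL)
}

#' Read a genotype panel from a VCF file
#'
#' Bi-allelic diploid genotypes are converted to alternate-allele dosages
#' (0/1/2); missing calls (`./.`) become `NA`. Chromosome names are parsed to
#' integers by stripping any non-digit prefix (e.g. `SL2.50ch01` or `chr1`).
#'
#' @param file Path to a VCF (4.x) file.
#' @param groups Optional accession group labels, in VCF sample order.
#' @return A [genotype_panel()].
#' @export
read_vcf_panel <- function(file, groups = NULL) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(as.numeric(al))
  })
  chrom <- as.integer(sub("^.*?(\\d+)$", "\\1", vcfR::getCHROM(v)))
  pos <- vcfR::getPOS(v)
  genotype_panel(t(dose),
                 data.frame(chrom = chrom, pos = pos),
                 accession_ids = colnames(gt), groups = groups)
}

#' Write a genotype panel to a minimal VCF 4.2 file
#'
#' Dosages are rounded to 0/1/2 and written as unphased `GT` calls with
#' placeholder `A`/`T` alleles; missing dosages become `./.`.
#'
#' @param panel A [genotype_panel()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_vcf_panel <- function(panel, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=gxwqtl",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$accession_ids),
                     collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(panel$dosages))) {
    d <- round(panel$dosages[, j])
    gt <- ifelse(is.na(d), "./.", gt_codes[d + 1L])
    writeLines(paste(c(panel$map$chrom[j], panel$map$pos[j],
                       panel$map$marker_id[j], "A", "T", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(file)
}
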