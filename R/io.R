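# File formats and the end-to-end pipeline driver.
#
# Internal coordinates are 1-based rCRS throughout; VCF positions are
# 1-based per the standard, BED masks 0-based half-open (converted on
# read).

#' Read a per-site allele-count TSV
#'
#' Expected columns: `position`, `ref`, `A_fwd`, `A_rev`, `C_fwd`,
#' `C_rev`, `G_fwd`, `G_rev`, `T_fwd`, `T_rev`.
#'
#' @param path TSV path.
#' @return Allele-count tibble (validated; depth = sum of the 8 counts).
#' @export
read_allele_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  .validate_counts(counts)
  counts
}

#' @rdname read_allele_counts
#' @param counts Allele-count tibble.
#' @export
write_allele_counts <- function(counts, path) {
  readr::write_tsv(counts[, c("position", "ref", .COUNT_COLS)], path)
  invisible(path)
}

#' Read variants from VCF or a counts TSV
#'
#' VCF (v4.2) records are parsed with vcfR; multiallelic records are split
#' into one call per alternate allele, with per-allele AD and AF taken
#' from the first sample column (AF recomputed from AD/DP when absent).
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"counts"`.
#' @return For VCF, a call tibble (`position`, `ref`, `alt`, `vaf`,
#'   `depth`, `alt_reads`, `filter`); for counts, an allele-count tibble.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "counts")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "counts"
  }
  if (format == "counts") return(read_allele_counts(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  dp <- suppressWarnings(as.numeric(vcfR::extract.gt(v, "DP")[, 1]))
  ad <- vcfR::extract.gt(v, "AD")[, 1]
  af <- tryCatch(vcfR::extract.gt(v, "AF")[, 1], error = function(e) rep(NA_character_, nrow(fix)))
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ads <- suppressWarnings(as.numeric(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    afs <- suppressWarnings(as.numeric(strsplit(af[i], ",", fixed = TRUE)[[1]]))
    for (k in seq_along(alts)) {
      alt_reads <- if (length(ads) >= k + 1) ads[k + 1] else NA_real_
      vaf <- if (!all(is.na(afs)) && length(afs) >= k) afs[k] else alt_reads / dp[i]
      out[[length(out) + 1L]] <- tibble::tibble(
        position = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[k],
        vaf = vaf, depth = dp[i], alt_reads = alt_reads,
        filter = fix$FILTER[i])
    }
  }
  dplyr::bind_rows(out)
}

#' Write calls as VCF 4.2
#'
#' One record per call with `DP`, `AD` (ref,alt) and `AF` sample fields;
#' calls failing the strand-bias filter (when the `strand_bias_pass`
#' column is present) carry a `strand_bias` FILTER flag.
#'
#' @param calls Call tibble from [call_variants()].
#' @param path Output path.
#' @param sample_id Sample column name (default `"SAMPLE"`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_id = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrMT,length=16569>",
    "##FILTER=<ID=strand_bias,Description=\"Significant strand bias of alt reads\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele fraction\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
          sample_id, sep = "\t")
  )
  filt <- if ("strand_bias_pass" %in% names(calls)) {
    ifelse(calls$strand_bias_pass, "PASS", "strand_bias")
  } else rep("PASS", nrow(calls))
  ref_reads <- round(calls$depth - calls$alt_reads)
  rows <- sprintf("chrMT\t%d\t.\t%s\t%s\t.\t%s\tDP=%d\tDP:AD:AF\t%d:%d,%d:%.6g",
                  calls$position, calls$ref, calls$alt, filt,
                  as.integer(round(calls$depth)), as.integer(round(calls$depth)),
                  as.integer(ref_reads), as.integer(round(calls$alt_reads)), calls$vaf)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Run the full paired-cohort pipeline
#'
#' Calls variants per sample from allele counts, applies the strand-bias
#' filter and low-complexity mask, annotates, assigns haplogroups, runs
#' cohort QC (haplogroup concordance then coverage), and produces the
#' burden report, the somatic classification with case/control tests, and
#' codon-usage tables. Deterministic given the inputs and thresholds.
#'
#' @param cohort List with `sample_sheet`, `counts`, `coverage_ok`
#'   (as produced by [simulate_cohort()], or assembled from files).
#' @param map An [mt_locus_map()].
#' @param min_depth,min_alt_reads,min_vaf Calling thresholds.
#' @param min_shift_delta Somatic shift dead band.
#' @param high_het_cut High-heteroplasmy contingency cut.
#' @param strand_alpha,strand_skew Strand-bias filter parameters.
#' @return List: `config` (thresholds echoed), `calls` (annotated cohort
#'   call table), `haplogroups`, `qc` (retained pairs + exclusion ledger),
#'   `burden`, `somatic` (`events`, `summary`, `tests`), `codon_usage`.
#' @export
run_pipeline <- function(cohort, map = mt_locus_map(),
                         min_depth = 1500L, min_alt_reads = 10L, min_vaf = 0.01,
                         min_shift_delta = 0.01, high_het_cut = 0.10,
                         strand_alpha = 0.05, strand_skew = 0.90) {
  sheet <- cohort$sample_sheet
  if (is.null(sheet) || !nrow(sheet)) stop("empty cohort: no samples in the sample sheet")
  config <- list(min_depth = min_depth, min_alt_reads = min_alt_reads, min_vaf = min_vaf,
                 min_shift_delta = min_shift_delta, high_het_cut = high_het_cut,
                 strand_alpha = strand_alpha, strand_skew = strand_skew)

  # per-sample calling
  call_list <- lapply(sheet$sample, function(s) {
    counts <- cohort$counts[[s]]
    if (is.null(counts)) return(NULL)
    calls <- call_variants(counts, min_depth, min_alt_reads, min_vaf)
    calls <- apply_strand_filter(calls, alpha = strand_alpha, skew_limit = strand_skew)
    if (nrow(calls)) calls$sample <- s
    calls
  })
  calls <- dplyr::bind_rows(call_list)
  if (!nrow(calls)) stop("empty cohort: no variant calls in any sample")
  calls <- dplyr::left_join(calls, sheet[, c("sample", "individual", "tissue", "status")],
                            by = "sample")
  calls <- filter_masked(calls, map)
  calls <- annotate_calls(calls, map)

  # haplogroups per sample -> per-pair concordance
  panel <- haplogroup_panel()
  hgs <- vapply(sheet$sample, function(s) {
    assign_haplogroup(calls[calls$sample == s, , drop = FALSE], panel)
  }, character(1))
  haplogroups <- tibble::tibble(sample = sheet$sample, individual = sheet$individual,
                                tissue = sheet$tissue, haplogroup = unname(hgs))
  pairs <- haplogroups %>%
    tidyr::pivot_wider(id_cols = "individual", names_from = "tissue",
                       values_from = "haplogroup") %>%
    dplyr::rename(fc_haplogroup = "FC", snpc_haplogroup = "SNpc")
  pairs <- dplyr::left_join(pairs,
                            dplyr::distinct(sheet[, c("individual", "status")]),
                            by = "individual")
  coverage_ok <- cohort$coverage_ok
  if (is.null(coverage_ok)) coverage_ok <- setNames(rep(TRUE, nrow(pairs)), pairs$individual)
  qc <- apply_cohort_qc(pairs, coverage_ok)

  retained_sheet <- sheet[sheet$individual %in% qc$retained$individual, , drop = FALSE]
  retained_calls <- calls[calls$individual %in% qc$retained$individual, , drop = FALSE]

  burden <- burden_report(retained_calls, retained_sheet, map, high_het_cut = high_het_cut)

  events <- classify_somatic_cohort(retained_calls, qc$retained,
                                    min_shift_delta = min_shift_delta)
  som_summary <- somatic_summary(events, qc$retained)
  som_tests <- compare_class_rates(som_summary)

  # codon usage per tissue on unique coding variants
  usage_in <- lapply(c("SNpc", "FC"), function(tis) {
    uv <- unique_variants(retained_calls[retained_calls$tissue == tis, ], map)
    if (!nrow(uv)) return(NULL)
    ann <- annotate_variants(uv, map)
    ann <- ann[ann$category == "coding", , drop = FALSE]
    if (!nrow(ann)) return(NULL)
    tibble::tibble(group = tis, consequence = ann$consequence,
                   codon_position = ann$codon_position)
  })
  usage_in <- dplyr::bind_rows(usage_in)
  codon_usage <- if (nrow(usage_in)) codon_usage_table(usage_in) else NULL

  list(config = config, calls = calls, haplogroups = haplogroups, qc = qc,
       burden = burden,
       somatic = list(events = events, summary = som_summary, tests = som_tests),
       codon_usage = codon_usage)
}

#' Write the pipeline report bundle as tidy TSVs
#'
#' @param result Output of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_reports <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) if (!is.null(x) && nrow(x)) readr::write_tsv(x, file.path(dir, name))
  w(result$qc$ledger, "qc_exclusions.tsv")
  w(result$qc$retained, "qc_retained_pairs.tsv")
  w(result$burden$group_tests, "burden_group_tests.tsv")
  w(result$burden$locus_tests, "burden_locus_tests.tsv")
  w(result$burden$region_tests, "burden_region_tests.tsv")
  w(result$burden$high_het, "burden_high_heteroplasmy.tsv")
  w(result$burden$titv, "burden_titv.tsv")
  w(result$burden$mean_vaf, "burden_mean_vaf.tsv")
  w(result$somatic$events, "somatic_events.tsv")
  w(result$somatic$summary$totals, "somatic_totals.tsv")
  w(result$somatic$tests$class_tests, "somatic_class_tests.tsv")
  if (!is.null(result$somatic$tests$locus_tests)) {
    w(result$somatic$tests$locus_tests, "somatic_locus_tests.tsv")
  }
  if (!is.null(result$codon_usage)) w(result$codon_usage, "codon_usage.tsv")
  invisible(dir)
}
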