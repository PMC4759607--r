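# Threshold heteroplasmy caller on per-site allele counts.
#
# Inputs are strand-split base counts from reads that already passed
# base-quality (>= 30) and mapping-quality (>= 20) filters upstream; the
# caller does not re-examine per-read quality.

.COUNT_COLS <- c("A_fwd", "A_rev", "C_fwd", "C_rev", "G_fwd", "G_rev", "T_fwd", "T_rev")

#' Default calling thresholds
#'
#' Minimum depth 1500, minimum supporting (alt) reads 10, minimum variant
#' allele fraction 1.0%. The VAF threshold is inclusive (call iff
#' `vaf >= min_vaf`).
#' @return Named list of thresholds.
#' @export
calling_defaults <- function() {
  list(min_depth = 1500L, min_alt_reads = 10L, min_vaf = 0.01)
}

.validate_counts <- function(counts) {
  stopifnot(all(c("position", "ref", .COUNT_COLS) %in% names(counts)))
  cm <- as.matrix(counts[, .COUNT_COLS])
  if (any(cm < 0)) stop("input error: negative read counts")
  depth <- rowSums(cm)
  if ("depth" %in% names(counts) && any(counts$depth != depth)) {
    stop("input error: depth column does not equal the sum of strand counts")
  }
  depth
}

#' Call variants from a per-site allele-count table
#'
#' One call is emitted per non-reference base at a site when all three
#' predicates hold: `alt_reads >= min_alt_reads`, `vaf >= min_vaf` and
#' `depth >= min_depth`. Multiple alternate alleles at one site yield
#' multiple calls. Sites with zero depth are not "no variant" but "no
#' coverage"; their positions are returned in the `no_coverage` attribute.
#'
#' @param counts Data frame with columns `position`, `ref` and strand-split
#'   base counts `A_fwd`, `A_rev`, ..., `T_rev` (reads already filtered for
#'   base/mapping quality).
#' @param min_depth,min_alt_reads,min_vaf Calling thresholds; defaults are
#'   [calling_defaults()].
#' @return Tibble of calls: `position`, `ref`, `alt`, `vaf`, `depth`,
#'   `alt_reads`, `alt_fwd`, `alt_rev`, `ref_fwd`, `ref_rev`, `zygosity`.
#' @export
call_variants <- function(counts, min_depth = 1500L, min_alt_reads = 10L, min_vaf = 0.01) {
  depth <- .validate_counts(counts)
  no_cov <- counts$position[depth == 0]
  out <- vector("list", 3L)
  k <- 0L
  ref <- toupper(counts$ref)
  for (base in .BASES) {
    is_alt <- ref != base & depth > 0
    if (!any(is_alt)) next
    fwd <- counts[[paste0(base, "_fwd")]]
    rev <- counts[[paste0(base, "_rev")]]
    alt_reads <- fwd + rev
    vaf <- ifelse(depth > 0, alt_reads / depth, 0)
    keep <- is_alt & alt_reads >= min_alt_reads & vaf >= min_vaf & depth >= min_depth
    if (!any(keep)) next
    k <- k + 1L
    # ref strand counts: per-row lookup of the ref base's columns
    rf <- mapply(function(i, b) counts[[paste0(b, "_fwd")]][i], which(keep), ref[keep])
    rr <- mapply(function(i, b) counts[[paste0(b, "_rev")]][i], which(keep), ref[keep])
    out[[k]] <- tibble::tibble(
      position = counts$position[keep],
      ref = ref[keep],
      alt = base,
      vaf = vaf[keep],
      depth = depth[keep],
      alt_reads = alt_reads[keep],
      alt_fwd = fwd[keep],
      alt_rev = rev[keep],
      ref_fwd = as.numeric(rf),
      ref_rev = as.numeric(rr)
    )
  }
  calls <- dplyr::bind_rows(out)
  if (!nrow(calls)) {
    calls <- tibble::tibble(position = integer(), ref = character(), alt = character(),
                            vaf = numeric(), depth = numeric(), alt_reads = numeric(),
                            alt_fwd = numeric(), alt_rev = numeric(),
                            ref_fwd = numeric(), ref_rev = numeric(), zygosity = character())
  } else {
    calls <- dplyr::arrange(calls, .data$position, .data$alt)
    calls$zygosity <- classify_zygosity(calls$vaf, min_vaf = min_vaf)
  }
  attr(calls, "no_coverage") <- no_cov
  calls
}

#' Call a single site
#'
#' @param counts One-row allele-count data frame (see [call_variants()]).
#' @inheritParams call_variants
#' @return Tibble of calls at the site (possibly zero rows).
#' @export
call_site <- function(counts, min_depth = 1500L, min_alt_reads = 10L, min_vaf = 0.01) {
  stopifnot(nrow(counts) == 1L)
  call_variants(counts, min_depth, min_alt_reads, min_vaf)
}

#' Heteroplasmic or homoplasmic
#'
#' Heteroplasmic: VAF in `[min_vaf, 0.99)`; homoplasmic: VAF `>= 0.99`.
#' A VAF below the calling threshold is a contract violation (no call
#' should exist there).
#'
#' @param vaf Variant allele fraction(s) of existing calls.
#' @param min_vaf Calling threshold (default 0.01).
#' @param hom_threshold Homoplasmy bound (default 0.99).
#' @return Character vector: `"heteroplasmic"` or `"homoplasmic"`.
#' @export
classify_zygosity <- function(vaf, min_vaf = 0.01, hom_threshold = 0.99) {
  if (any(vaf < min_vaf)) stop("contract violation: vaf below calling threshold")
  if (any(vaf > 1)) stop("input error: vaf > 1")
  ifelse(vaf >= hom_threshold, "homoplasmic", "heteroplasmic")
}

#' Strand-bias filter
#'
#' A call fails (returns `FALSE`) iff the two-sided exact test on the
#' (ref/alt x fwd/rev) 2x2 table is significant at `alpha` AND the alt
#' reads are skewed to one strand beyond `skew_limit`.
#'
#' @param alt_fwd,alt_rev,ref_fwd,ref_rev Strand counts (vectorized).
#' @param alpha Significance level (default 0.05).
#' @param skew_limit Maximum tolerated alt strand fraction (default 0.90).
#' @return Logical: `TRUE` = pass.
#' @export
strand_bias_pass <- function(alt_fwd, alt_rev, ref_fwd, ref_rev,
                             alpha = 0.05, skew_limit = 0.90) {
  if (any(alt_fwd + alt_rev == 0)) stop("contract violation: zero alt reads")
  n <- length(alt_fwd)
  vapply(seq_len(n), function(i) {
    tab <- matrix(c(ref_fwd[i], ref_rev[i], alt_fwd[i], alt_rev[i]), nrow = 2, byrow = TRUE)
    p <- fisher_exact_2x2(tab)
    skew <- max(alt_fwd[i], alt_rev[i]) / (alt_fwd[i] + alt_rev[i])
    !(p < alpha && skew > skew_limit)
  }, logical(1))
}

#' Apply the strand-bias filter to a call table
#'
#' Adds a `strand_bias_pass` column and, if `drop = TRUE`, removes failing
#' calls (mirroring a FILTER flag in VCF output).
#'
#' @param calls Call tibble from [call_variants()].
#' @param drop Remove failing calls (default `TRUE`).
#' @inheritParams strand_bias_pass
#' @return Filtered (or flagged) call tibble.
#' @export
apply_strand_filter <- function(calls, alpha = 0.05, skew_limit = 0.90, drop = TRUE) {
  if (!nrow(calls)) {
    calls$strand_bias_pass <- logical(0)
    return(calls)
  }
  calls$strand_bias_pass <- strand_bias_pass(calls$alt_fwd, calls$alt_rev,
                                             calls$ref_fwd, calls$ref_rev,
                                             alpha = alpha, skew_limit = skew_limit)
  if (drop) calls[calls$strand_bias_pass, , drop = FALSE] else calls
}

#' Intersect two call sets (second-caller concordance hook)
#'
#' The study design calls variants with two callers and keeps concordant
#' calls; this hook intersects this package's calls with a second caller's
#' call set on (position, alt).
#'
#' @param calls Primary call tibble.
#' @param other Second call set, any data frame with `position` and `alt`.
#' @return Subset of `calls` present in `other`.
#' @export
concordant_calls <- function(calls, other) {
  key <- paste(calls$position, calls$alt)
  calls[key %in% paste(other$position, other$alt), , drop = FALSE]
}
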