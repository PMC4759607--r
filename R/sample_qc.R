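# Coverage QC, marker-panel haplogroup assignment, paired-tissue
# concordance and cohort bookkeeping.

#' Load the bundled haplogroup marker panel
#'
#' A small panel of defining variants for the macro-haplogroups
#' V, J, T, U, K, W, X and I (the rCRS-like H branch is the root label and
#' carries no markers). Sufficient for checking that two tissues of one
#' individual share a backbone; it is not a fine-clade classifier.
#'
#' @param path Optional panel TSV (columns `haplogroup`, `position`, `alt`).
#' @return Tibble of marker variants.
#' @export
haplogroup_panel <- function(path = NULL) {
  if (is.null(path)) path <- system.file("extdata", "haplogroup_panel.tsv", package = "mthet")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Coverage QC for one sample
#'
#' Passes iff the fraction of genome positions with depth at or above
#' `min_depth` is at least `min_fraction` (defaults: 1500x over 99% of
#' positions).
#'
#' @param profile Either a numeric depth vector over all 16,569 positions,
#'   or a run-length data frame with columns `start`, `end`, `depth`
#'   covering every position exactly once.
#' @param min_depth Depth threshold (default 1500).
#' @param min_fraction Required covered fraction (default 0.99).
#' @return `TRUE`/`FALSE`.
#' @export
coverage_pass <- function(profile, min_depth = 1500L, min_fraction = 0.99) {
  if (is.data.frame(profile)) {
    stopifnot(all(c("start", "end", "depth") %in% names(profile)))
    widths <- profile$end - profile$start + 1L
    if (sum(widths) != MT_GENOME_LENGTH) {
      stop("input error: run-length profile must cover every position exactly once")
    }
    frac <- sum(widths[profile$depth >= min_depth]) / MT_GENOME_LENGTH
  } else {
    if (!length(profile)) stop("input error: empty coverage profile")
    if (length(profile) != MT_GENOME_LENGTH) {
      stop("input error: depth vector must have length ", MT_GENOME_LENGTH)
    }
    frac <- mean(profile >= min_depth)
  }
  frac >= min_fraction
}

#' Assign a haplogroup from homoplasmic calls
#'
#' Scores each panel haplogroup by the fraction of its defining variants
#' present among the sample's homoplasmic calls; the best-scoring label
#' wins. Ties are broken by the larger defining set (most derived), then
#' lexicographically. When no marker matches at all the root label is
#' returned (rCRS-like backbone, `"H"` by default). Heteroplasmic calls
#' never influence the assignment.
#'
#' @param calls Call tibble with `position`, `alt` and (optionally)
#'   `zygosity`; rows with `zygosity != "homoplasmic"` are ignored.
#' @param panel Marker panel from [haplogroup_panel()].
#' @param root_label Label when no marker matches (default `"H"`).
#' @return Single haplogroup label.
#' @export
assign_haplogroup <- function(calls, panel = haplogroup_panel(), root_label = "H") {
  if (!nrow(panel)) stop("configuration error: empty marker panel")
  if ("zygosity" %in% names(calls)) calls <- calls[calls$zygosity == "homoplasmic", , drop = FALSE]
  have <- paste(calls$position, toupper(calls$alt))
  sc <- panel %>%
    dplyr::group_by(.data$haplogroup) %>%
    dplyr::summarise(
      size = dplyr::n(),
      matched = sum(paste(.data$position, .data$alt) %in% have),
      score = .data$matched / .data$size,
      .groups = "drop"
    )
  if (max(sc$matched) == 0) return(root_label)
  sc <- sc[order(-sc$score, -sc$size, sc$haplogroup), ]
  sc$haplogroup[1]
}

#' Do a pair's tissues share a haplogroup?
#'
#' @param fc_haplogroup,snpc_haplogroup Assigned labels for the two tissues.
#' @return `TRUE` iff the labels are identical.
#' @export
pair_concordant <- function(fc_haplogroup, snpc_haplogroup) {
  if (any(is.na(fc_haplogroup)) || any(is.na(snpc_haplogroup))) {
    stop("pairing error: missing haplogroup for one tissue")
  }
  fc_haplogroup == snpc_haplogroup
}

#' Cohort-level QC with an exclusion ledger
#'
#' Applies the two pair-level QC rules sequentially: haplogroup
#' discordance first, then coverage failure (a pair failing both is
#' ledgered once, under discordance). Conservation holds: every input pair
#' is either retained or appears exactly once in the ledger.
#'
#' @param pairs Tibble with one row per individual: `individual`, `status`
#'   (`"case"`/`"control"`), `fc_haplogroup`, `snpc_haplogroup`.
#' @param coverage_ok Named logical vector (by individual id): `TRUE` if
#'   both tissues passed coverage QC. Alternatively a tibble with columns
#'   `individual`, `pass`.
#' @return List: `retained` (tibble), `ledger` (tibble `individual`,
#'   `status`, `reason`), `counts` (retained n by status).
#' @export
apply_cohort_qc <- function(pairs, coverage_ok) {
  if (is.data.frame(coverage_ok)) {
    coverage_ok <- setNames(coverage_ok$pass, coverage_ok$individual)
  }
  if (!nrow(pairs)) {
    return(list(retained = pairs,
                ledger = tibble::tibble(individual = character(), status = character(),
                                        reason = character()),
                counts = c(case = 0L, control = 0L)))
  }
  discordant <- !pair_concordant(pairs$fc_haplogroup, pairs$snpc_haplogroup)
  cov_fail <- !coverage_ok[as.character(pairs$individual)]
  cov_fail[is.na(cov_fail)] <- FALSE
  reason <- rep(NA_character_, nrow(pairs))
  reason[cov_fail] <- "coverage_fail"
  reason[discordant] <- "haplogroup_discordant"  # sequential: discordance ledgered first
  ledger <- tibble::tibble(individual = pairs$individual[!is.na(reason)],
                           status = pairs$status[!is.na(reason)],
                           reason = reason[!is.na(reason)])
  retained <- pairs[is.na(reason), , drop = FALSE]
  counts <- c(case = sum(retained$status == "case"),
              control = sum(retained$status == "control"))
  list(retained = retained, ledger = ledger, counts = counts)
}
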