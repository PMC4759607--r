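# Four-class somatic taxonomy for paired tissues, treating FC as the
# ancestral reference and SNpc as the affected tissue.

SOMATIC_CLASSES <- c("de_novo", "loss", "positive_shift", "negative_shift")

#' Classify FC -> SNpc differential variants for one individual
#'
#' Calls from the two tissues are matched on (position, alt). Presence
#' means "called" (the calling thresholds define existence): a variant
#' present only in SNpc is `de_novo`, only in FC is `loss`; present in
#' both, the heteroplasmy delta `het_snpc - het_fc` gives
#' `positive_shift`/`negative_shift` when its magnitude reaches
#' `min_shift_delta`, else `"unchanged"`. Variants homoplasmic in both
#' tissues are `"unchanged"` (no room to shift). The absent-tissue VAF is
#' recorded as 0.
#'
#' @param fc_calls,snpc_calls Call tibbles for the two tissues
#'   (`position`, `ref`, `alt`, `vaf`; annotation columns are carried
#'   through when present).
#' @param min_shift_delta Dead band for shift classes, absolute VAF
#'   (default 0.01, suppressing binomial sampling noise at typical depth).
#' @return Tibble of events: `position`, `ref`, `alt`, `class`, `het_fc`,
#'   `het_snpc`, `delta`, plus any shared annotation columns.
#' @export
classify_somatic <- function(fc_calls, snpc_calls, min_shift_delta = 0.01) {
  keep <- function(df) {
    df <- tibble::as_tibble(df)
    ann_cols <- intersect(c("loci", "region_class", "consequence", "substitution_class",
                            "zygosity"), names(df))
    df[, c("position", "ref", "alt", "vaf", ann_cols)]
  }
  fc <- keep(fc_calls); sn <- keep(snpc_calls)
  both_pos <- intersect(fc$position, sn$position)
  if (length(both_pos)) {
    rf <- unique(fc[fc$position %in% both_pos, c("position", "ref")])
    rs <- unique(sn[sn$position %in% both_pos, c("position", "ref")])
    chk <- dplyr::inner_join(rf, rs, by = "position", suffix = c("_fc", "_snpc"))
    if (any(chk$ref_fc != chk$ref_snpc)) {
      stop("data inconsistency error: ref alleles differ between tissues at position(s) ",
           paste(utils::head(chk$position[chk$ref_fc != chk$ref_snpc], 5), collapse = ", "))
    }
  }
  fc$zyg_fc <- if ("zygosity" %in% names(fc)) fc$zygosity else NA_character_
  sn$zyg_sn <- if ("zygosity" %in% names(sn)) sn$zygosity else NA_character_
  fc$zygosity <- NULL; sn$zygosity <- NULL
  key_cols <- intersect(setdiff(names(fc), c("vaf", "zyg_fc")),
                        setdiff(names(sn), c("vaf", "zyg_sn")))
  m <- dplyr::full_join(dplyr::rename(fc, het_fc = "vaf"),
                        dplyr::rename(sn, het_snpc = "vaf"),
                        by = key_cols)
  m$het_fc[is.na(m$het_fc)] <- 0
  m$het_snpc[is.na(m$het_snpc)] <- 0
  m$delta <- m$het_snpc - m$het_fc
  in_fc <- m$het_fc > 0; in_sn <- m$het_snpc > 0
  hom_both <- !is.na(m$zyg_fc) & !is.na(m$zyg_sn) &
    m$zyg_fc == "homoplasmic" & m$zyg_sn == "homoplasmic"
  m$class <- dplyr::case_when(
    !in_fc & in_sn ~ "de_novo",
    in_fc & !in_sn ~ "loss",
    hom_both ~ "unchanged",
    m$delta >= min_shift_delta ~ "positive_shift",
    m$delta <= -min_shift_delta ~ "negative_shift",
    TRUE ~ "unchanged"
  )
  m$zyg_fc <- NULL; m$zyg_sn <- NULL
  dplyr::arrange(m, .data$position, .data$alt)
}

#' Classify somatic events for a whole cohort
#'
#' @param cohort_calls Long call tibble with `individual`, `tissue`
#'   (`"FC"`/`"SNpc"`) and call columns.
#' @param pairs Tibble of QC-passed pairs: `individual`, `status`.
#' @param min_shift_delta Passed to [classify_somatic()].
#' @return Event tibble with `individual` and `status` columns prepended.
#' @export
classify_somatic_cohort <- function(cohort_calls, pairs, min_shift_delta = 0.01) {
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    id <- pairs$individual[i]
    cc <- cohort_calls[cohort_calls$individual == id, , drop = FALSE]
    ev <- classify_somatic(cc[cc$tissue == "FC", setdiff(names(cc), c("individual", "tissue", "status", "sample"))],
                           cc[cc$tissue == "SNpc", setdiff(names(cc), c("individual", "tissue", "status", "sample"))],
                           min_shift_delta = min_shift_delta)
    if (nrow(ev)) {
      ev$individual <- id
      ev$status <- pairs$status[i]
    }
    ev
  })
  ev <- dplyr::bind_rows(out)
  if (nrow(ev)) ev <- ev[, c("individual", "status", setdiff(names(ev), c("individual", "status")))]
  ev
}

#' Summarize somatic events
#'
#' @param events Event tibble from [classify_somatic_cohort()] (the
#'   `"unchanged"` rows are not differential variants and are excluded
#'   from the totals).
#' @param pairs QC-passed pairs (`individual`, `status`), defining the
#'   per-sample denominator (individuals with zero events count as zeros).
#' @return List: `totals` (per-class event counts), `per_sample`
#'   (individual x class counts with status), `by_type` (per-class
#'   variant-type percentages), `by_locus` (per-class locus counts of
#'   nonsynonymous events).
#' @export
somatic_summary <- function(events, pairs) {
  diff_ev <- events[events$class %in% SOMATIC_CLASSES, , drop = FALSE]
  totals <- tibble::tibble(
    class = SOMATIC_CLASSES,
    n = unname(vapply(SOMATIC_CLASSES, function(k) sum(diff_ev$class == k), numeric(1))))
  grid <- tidyr::expand_grid(individual = pairs$individual, class = SOMATIC_CLASSES)
  grid <- dplyr::left_join(grid, pairs[, c("individual", "status")], by = "individual")
  cnt <- diff_ev %>% dplyr::count(.data$individual, .data$class, name = "count")
  per_sample <- dplyr::left_join(grid, cnt, by = c("individual", "class"))
  per_sample$count[is.na(per_sample$count)] <- 0L

  by_type <- NULL
  if ("region_class" %in% names(diff_ev) && nrow(diff_ev)) {
    typ <- ifelse(diff_ev$region_class == "coding", diff_ev$consequence, diff_ev$region_class)
    by_type <- tibble::as_tibble(diff_ev) %>%
      dplyr::mutate(variant_type = typ) %>%
      dplyr::count(.data$class, .data$variant_type, name = "n") %>%
      dplyr::group_by(.data$class) %>%
      dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) %>%
      dplyr::ungroup()
  }
  by_locus <- NULL
  if (all(c("loci", "consequence") %in% names(diff_ev)) && nrow(diff_ev)) {
    ns <- diff_ev[diff_ev$consequence == "nonsynonymous", , drop = FALSE]
    if (nrow(ns)) {
      by_locus <- ns %>%
        tidyr::separate_rows("loci", sep = ",") %>%
        dplyr::count(.data$class, .data$status, locus = .data$loci, name = "n")
    }
  }
  list(totals = totals, per_sample = per_sample, by_type = by_type, by_locus = by_locus)
}

#' Case/control comparison of somatic class rates
#'
#' Per class, a Mann-Whitney test on per-sample event counts (cases vs
#' controls, zero-inflated counts included); and, when locus annotation is
#' available, a per-locus Pearson chi-squared test on the distribution of
#' nonsynonymous events (each locus vs the rest, cases vs controls).
#'
#' @param summary Output of [somatic_summary()].
#' @return List: `class_tests` tibble (class, means, U, p, direction),
#'   `locus_tests` tibble or `NULL`.
#' @export
compare_class_rates <- function(summary) {
  ps <- summary$per_sample
  if (length(unique(ps$status)) < 2) stop("report error: need both case and control pairs")
  class_tests <- lapply(SOMATIC_CLASSES, function(k) {
    a <- ps$count[ps$class == k & ps$status == "case"]
    b <- ps$count[ps$class == k & ps$status == "control"]
    mw <- .mw_or_na(a, b)
    tibble::tibble(class = k, mean_case = mean(a), mean_control = mean(b),
                   U = mw$U, p_value = mw$p_value,
                   direction = dplyr::case_when(mean(a) > mean(b) ~ "case-elevated",
                                                mean(a) < mean(b) ~ "control-elevated",
                                                TRUE ~ "equal"),
                   method = mw$method)
  })
  locus_tests <- NULL
  bl <- summary$by_locus
  if (!is.null(bl) && nrow(bl)) {
    wide <- bl %>%
      dplyr::group_by(.data$status, .data$locus) %>%
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
    tot <- tapply(wide$n, wide$status, sum)
    if (all(c("case", "control") %in% names(tot))) {
      loci <- sort(unique(wide$locus))
      locus_tests <- dplyr::bind_rows(lapply(loci, function(loc) {
        a <- sum(wide$n[wide$locus == loc & wide$status == "case"])
        b <- sum(wide$n[wide$locus == loc & wide$status == "control"])
        tab <- matrix(c(a, tot[["case"]] - a, b, tot[["control"]] - b), 2, byrow = TRUE)
        res <- tryCatch(pearson_chi2_2x2(tab),
                        error = function(e) list(statistic = NA_real_, p_value = NA_real_))
        tibble::tibble(locus = loc, case_n = a, control_n = b,
                       statistic = res$statistic, p_value = res$p_value)
      }))
    }
  }
  list(class_tests = dplyr::bind_rows(class_tests), locus_tests = locus_tests)
}
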