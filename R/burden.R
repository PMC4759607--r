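# Cohort-level variant summarization and case/control burden statistics.
#
# The cohort call table is long format: one row per call with `sample`,
# `individual`, `tissue` ("SNpc"/"FC"), `status` ("case"/"control"),
# `position`, `ref`, `alt`, `vaf`, `zygosity` plus the collapsed
# annotation columns from annotate_calls().

#' Unique variants across a cohort
#'
#' Distinct (position, alt) pairs over all calls, after excluding masked
#' low-complexity positions when a map is supplied.
#'
#' @param calls Cohort call tibble.
#' @param map Optional [mt_locus_map()] whose mask is applied first.
#' @return Tibble of distinct `position`, `ref`, `alt`.
#' @export
unique_variants <- function(calls, map = NULL) {
  if (!is.null(map)) calls <- filter_masked(calls, map)
  dplyr::distinct(tibble::as_tibble(calls)[, c("position", "ref", "alt")])
}

#' Transition/transversion ratio
#'
#' @param variants Tibble with either a `substitution_class` column or
#'   `ref`/`alt` alleles.
#' @return List: `ratio` (Ti/Tv; `Inf` with `infinite = TRUE` when there
#'   are no transversions), `tv_fraction`, `n_transition`,
#'   `n_transversion`. The identity `ratio = (1 - f) / f` with
#'   `f = tv_fraction` holds exactly.
#' @export
titv_ratio <- function(variants) {
  cls <- if ("substitution_class" %in% names(variants)) variants$substitution_class
         else substitution_class(variants$ref, variants$alt)
  n_ti <- sum(cls == "transition")
  n_tv <- sum(cls == "transversion")
  if (n_ti + n_tv == 0) stop("input error: no substitutions")
  list(ratio = if (n_tv == 0) Inf else n_ti / n_tv,
       tv_fraction = n_tv / (n_ti + n_tv),
       n_transition = n_ti, n_transversion = n_tv,
       infinite = n_tv == 0)
}

.apply_restriction <- function(calls, restriction) {
  switch(restriction,
    "all" = calls,
    "heteroplasmic" = calls[calls$zygosity == "heteroplasmic", , drop = FALSE],
    "homoplasmic" = calls[calls$zygosity == "homoplasmic", , drop = FALSE],
    "nonsynonymous-heteroplasmic" =
      calls[calls$zygosity == "heteroplasmic" & calls$consequence == "nonsynonymous", , drop = FALSE],
    stop("input error: unknown restriction '", restriction, "'")
  )
}

#' Mean heteroplasmy level
#'
#' Arithmetic mean VAF over calls qualifying under the restriction.
#'
#' @param calls Annotated call tibble.
#' @param restriction `"heteroplasmic"` (default) or
#'   `"nonsynonymous-heteroplasmic"`.
#' @return Mean VAF; `NA` with a warning when no call qualifies.
#' @export
mean_heteroplasmy <- function(calls, restriction = "heteroplasmic") {
  sub <- .apply_restriction(calls, restriction)
  if (!nrow(sub)) {
    warning("undefined mean: no calls qualify under restriction '", restriction, "'")
    return(NA_real_)
  }
  mean(sub$vaf)
}

# BLOSUM62-derived amino-acid dissimilarity, rescaled to [0, 1]
.aa_dissimilarity_matrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    B <- e$BLOSUM62
    aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V", "*")
    B <- B[aa, aa]
    d <- (outer(diag(B), diag(B), "+") / 2) - B
    dimnames(d) <- list(aa, aa)
    cache <<- d / max(d)
    cache
  }
})

#' Pathogenicity scores for variants
#'
#' By default an explicit surrogate scorer: 0 for synonymous and
#' non-coding variants; for nonsynonymous changes a BLOSUM62-derived
#' dissimilarity of the amino-acid exchange rescaled to `[0, 1]`. A
#' user-supplied `score_table` (columns `position`, `alt`, `score`) takes
#' precedence; variants absent from it are handled per `missing`.
#'
#' @param variants Tibble with `position`, `ref`, `alt`.
#' @param map An [mt_locus_map()] (used by the surrogate).
#' @param score_table Optional lookup table.
#' @param missing For variants not in `score_table`: `"surrogate"`
#'   (default), `"zero"`, or `"skip"` (drop with a warning).
#' @return `variants` with a `score` column (variants hitting several
#'   coding loci score their maximum).
#' @export
pathogenicity_scores <- function(variants, map, score_table = NULL,
                                 missing = c("surrogate", "zero", "skip")) {
  missing <- match.arg(missing)
  v <- dplyr::distinct(tibble::as_tibble(variants)[, c("position", "ref", "alt")])
  surrogate <- function(vv) {
    ann <- annotate_variants(vv, map)
    D <- .aa_dissimilarity_matrix()
    ann$s <- 0
    ns <- ann$consequence == "nonsynonymous"
    if (any(ns)) ann$s[ns] <- D[cbind(ann$ref_aa[ns], ann$alt_aa[ns])]
    ann %>%
      dplyr::group_by(.data$position, .data$ref, .data$alt) %>%
      dplyr::summarise(score = max(.data$s), .groups = "drop")
  }
  if (is.null(score_table)) {
    sc <- surrogate(v)
  } else {
    key <- paste(v$position, v$alt)
    tkey <- paste(score_table$position, score_table$alt)
    hit <- match(key, tkey)
    sc <- v
    sc$score <- score_table$score[hit]
    miss <- is.na(hit)
    if (any(miss)) {
      if (missing == "surrogate") {
        sub <- surrogate(v[miss, , drop = FALSE])
        sc$score[miss] <- sub$score[match(paste(sc$position[miss], sc$alt[miss]),
                                          paste(sub$position, sub$alt))]
      } else if (missing == "zero") {
        sc$score[miss] <- 0
      } else {
        warning(sum(miss), " variant(s) absent from score table; skipped")
        sc <- sc[!miss, , drop = FALSE]
      }
    }
  }
  out <- dplyr::left_join(tibble::as_tibble(variants), sc[, c("position", "alt", "score")],
                          by = c("position", "alt"))
  if (missing == "skip") out <- out[!is.na(out$score), , drop = FALSE]
  out
}

#' Compare pathogenicity score distributions between two call sets
#'
#' @param callsA,callsB Call tibbles (e.g. case vs control calls).
#' @param map An [mt_locus_map()].
#' @param score_table,missing Passed to [pathogenicity_scores()].
#' @return List: `mean_a`, `mean_b`, Mann-Whitney `U` and `p_value`.
#' @export
pathogenicity_compare <- function(callsA, callsB, map, score_table = NULL,
                                  missing = "surrogate") {
  a <- pathogenicity_scores(callsA, map, score_table, missing)$score
  b <- pathogenicity_scores(callsB, map, score_table, missing)$score
  mw <- mann_whitney(a, b)
  list(mean_a = mean(a), mean_b = mean(b), U = mw$U, p_value = mw$p_value)
}

# one row per (call, locus) for locus-stratified burden; overlap positions
# contribute once per gene by design
.calls_by_locus <- function(calls, map) {
  uv <- unique_variants(calls)
  if (!nrow(uv)) return(tibble::tibble())
  ann <- annotate_variants(uv, map)
  dplyr::inner_join(tibble::as_tibble(calls),
                    ann[, c("position", "ref", "alt", "locus", "category", "consequence",
                            "codon_position")],
                    by = c("position", "ref", "alt"), suffix = c("", "_locus"),
                    relationship = "many-to-many")
}

# per-sample counts for one stratum definition, completed with zeros over
# the sample sheet
.per_sample_counts <- function(rows, samples) {
  cnt <- rows %>%
    dplyr::count(.data$sample, name = "count")
  out <- dplyr::left_join(samples, cnt, by = "sample")
  out$count[is.na(out$count)] <- 0L
  out
}

.mw_or_na <- function(case_counts, ctrl_counts) {
  if (length(case_counts) < 2 || length(ctrl_counts) < 2) {
    return(list(U = NA_real_, p_value = NA_real_, method = "not-computable"))
  }
  mann_whitney(case_counts, ctrl_counts)
}

#' Full case/control burden report
#'
#' For each tissue: (i) Mann-Whitney case-vs-control tests of per-sample
#' variant counts for total / homoplasmic / heteroplasmic variants, (ii)
#' per-locus tests of nonsynonymous-heteroplasmic counts with Bonferroni
#' correction (family = number of locus strata tested in that tissue), and
#' region-class (DLOOP/rRNA/tRNA) heteroplasmic tests, (iii) Fisher's
#' exact test on the high-heteroplasmy (> `high_het_cut`, strict)
#' contingency table of heteroplasmic coding variants, (iv) Ti/Tv ratio
#' per tissue on unique variants, and (v) mean VAF per restriction.
#' Low-complexity positions are excluded throughout.
#'
#' @param calls Annotated cohort call tibble (see module header).
#' @param samples Sample sheet tibble: `sample`, `individual`, `tissue`,
#'   `status` (one row per sequenced sample, including samples with zero
#'   calls).
#' @param map An [mt_locus_map()].
#' @param high_het_cut Heteroplasmy cut for the contingency analysis
#'   (default 0.10, strict `>`).
#' @return List of tidy tibbles: `group_tests`, `locus_tests`,
#'   `region_tests`, `high_het`, `titv`, `mean_vaf`, `per_sample`.
#' @export
burden_report <- function(calls, samples, map, high_het_cut = 0.10) {
  stopifnot(all(c("sample", "tissue", "status") %in% names(samples)))
  if (length(unique(samples$status)) < 2) stop("report error: need both case and control samples")
  calls <- filter_masked(tibble::as_tibble(calls), map)
  tissues <- sort(unique(samples$tissue))

  group_tests <- list(); locus_tests <- list(); region_tests <- list()
  high_het <- list(); titv <- list(); mean_vaf <- list(); per_sample <- list()

  for (tis in tissues) {
    sam <- samples[samples$tissue == tis, , drop = FALSE]
    cl <- calls[calls$tissue == tis, , drop = FALSE]
    is_case <- function(df) df$status == "case"

    # (i) total / homoplasmic / heteroplasmic per-sample burden
    for (vt in c("all", "homoplasmic", "heteroplasmic")) {
      rows <- .apply_restriction(cl, vt)
      pc <- .per_sample_counts(rows, sam)
      mw <- .mw_or_na(pc$count[is_case(pc)], pc$count[!is_case(pc)])
      group_tests[[length(group_tests) + 1L]] <- tibble::tibble(
        tissue = tis, variant_type = vt,
        mean_case = mean(pc$count[is_case(pc)]), mean_control = mean(pc$count[!is_case(pc)]),
        U = mw$U, p_value = mw$p_value, method = mw$method)
      per_sample[[length(per_sample) + 1L]] <- dplyr::mutate(pc, variant_type = vt, stratum = "total")
    }

    # (ii) per-locus nonsynonymous-heteroplasmic burden, Bonferroni family =
    # loci tested in this tissue
    byloc <- .calls_by_locus(cl, map)
    if (nrow(byloc)) {
      ns_het <- byloc[byloc$zygosity == "heteroplasmic" &
                        byloc$consequence_locus == "nonsynonymous", , drop = FALSE]
      loci_here <- sort(unique(ns_het$locus))
      m_fam <- max(1L, length(loci_here))
      for (loc in loci_here) {
        pc <- .per_sample_counts(ns_het[ns_het$locus == loc, ], sam)
        mw <- .mw_or_na(pc$count[is_case(pc)], pc$count[!is_case(pc)])
        locus_tests[[length(locus_tests) + 1L]] <- tibble::tibble(
          tissue = tis, stratum = loc, variant_type = "nonsynonymous-heteroplasmic",
          n_family = m_fam,
          mean_case = mean(pc$count[is_case(pc)]), mean_control = mean(pc$count[!is_case(pc)]),
          U = mw$U, p_value = mw$p_value,
          p_adjusted = if (is.na(mw$p_value)) NA_real_ else bonferroni(mw$p_value, m_fam),
          method = mw$method)
      }
      # region classes on heteroplasmic variation
      het <- cl[cl$zygosity == "heteroplasmic", , drop = FALSE]
      for (rc in c("DLOOP", "rRNA", "tRNA")) {
        pc <- .per_sample_counts(het[het$region_class == rc, ], sam)
        mw <- .mw_or_na(pc$count[is_case(pc)], pc$count[!is_case(pc)])
        region_tests[[length(region_tests) + 1L]] <- tibble::tibble(
          tissue = tis, stratum = rc, variant_type = "heteroplasmic",
          mean_case = mean(pc$count[is_case(pc)]), mean_control = mean(pc$count[!is_case(pc)]),
          U = mw$U, p_value = mw$p_value, method = mw$method)
      }
    }

    # (iii) >cut heteroplasmy contingency on coding heteroplasmic variants
    het_cod <- cl[cl$zygosity == "heteroplasmic" & cl$region_class == "coding", , drop = FALSE]
    if (nrow(het_cod)) {
      tab <- matrix(c(sum(het_cod$vaf > high_het_cut & is_case(het_cod)),
                      sum(het_cod$vaf <= high_het_cut & is_case(het_cod)),
                      sum(het_cod$vaf > high_het_cut & !is_case(het_cod)),
                      sum(het_cod$vaf <= high_het_cut & !is_case(het_cod))),
                    nrow = 2, byrow = TRUE)
      high_het[[length(high_het) + 1L]] <- tibble::tibble(
        tissue = tis,
        case_high = tab[1, 1], case_total = sum(tab[1, ]),
        control_high = tab[2, 1], control_total = sum(tab[2, ]),
        p_value = fisher_exact_2x2(tab))
    }

    # (iv) Ti/Tv on unique variants; (v) mean VAF
    uv <- unique_variants(cl)
    if (nrow(uv)) {
      tt <- titv_ratio(uv)
      titv[[length(titv) + 1L]] <- tibble::tibble(
        tissue = tis, titv = tt$ratio, tv_fraction = tt$tv_fraction,
        n_transition = tt$n_transition, n_transversion = tt$n_transversion)
    }
    for (restr in c("heteroplasmic", "nonsynonymous-heteroplasmic")) {
      sub <- .apply_restriction(cl, restr)
      mean_vaf[[length(mean_vaf) + 1L]] <- tibble::tibble(
        tissue = tis, restriction = restr, n = nrow(sub),
        mean_vaf = if (nrow(sub)) mean(sub$vaf) else NA_real_)
    }
  }

  list(group_tests = dplyr::bind_rows(group_tests),
       locus_tests = dplyr::bind_rows(locus_tests),
       region_tests = dplyr::bind_rows(region_tests),
       high_het = dplyr::bind_rows(high_het),
       titv = dplyr::bind_rows(titv),
       mean_vaf = dplyr::bind_rows(mean_vaf),
       per_sample = dplyr::bind_rows(per_sample))
}
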