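# Reference-set filter chain and codon-usage tables.
#
# Operates on flagged record tables (id, length, species, pathogenic-carrier
# flag, non-European marker alleles, haplogroup), not on raw GenBank
# downloads; fixture builders construct collections with stated
# compositions (see make_bookkeeping_fixture()).

MAJOR_HAPLOGROUPS <- c("H", "V", "J", "T", "U", "K", "W", "X", "I", "R", "N")
NON_EURO_MARKERS <- c("8701A", "8540T", "10873T")

#' Sequential reference-set filter chain
#'
#' Filters are applied in a fixed order -- pathogenic-variant carriers,
#' non-Homo-sapiens records, non-European marker carriers, truncated
#' sequences, then (optionally, when `haplogroup_filter = TRUE`) records
#' outside the major haplogroups. Each record is ledgered under the first
#' filter it fails; conservation (input = survivors + sum of removals)
#' holds by construction.
#'
#' @param records Tibble with columns `id`, `length`, `species`,
#'   `carries_pathogenic` (logical), `marker_alleles` (character,
#'   comma-separated subset of `"8701A"`, `"8540T"`, `"10873T"`, `""` for
#'   none), `haplogroup`.
#' @param major_haplogroups Major haplogroup set (default
#'   H,V,J,T,U,K,W,X,I,R,N).
#' @param noneuro_rule `"any"` (default): a record is non-European if it
#'   carries any of the three markers; `"all"`: only if it carries all.
#' @param min_length Minimum full-length sequence (default 16,500 bp).
#' @param haplogroup_filter Apply the final major-haplogroup filter.
#' @return List: `survivors` (record tibble), `ledger` (tibble `step`,
#'   `removed`), `record_ledger` (id, step of first failure).
#' @export
filter_reference_chain <- function(records,
                                   major_haplogroups = MAJOR_HAPLOGROUPS,
                                   noneuro_rule = c("any", "all"),
                                   min_length = 16500L,
                                   haplogroup_filter = TRUE) {
  noneuro_rule <- match.arg(noneuro_rule)
  records <- tibble::as_tibble(records)
  steps <- c("pathogenic", "non_homo_sapiens", "non_european", "truncated", "non_major_haplogroup")
  if (!haplogroup_filter) steps <- steps[1:4]
  fail <- rep(NA_character_, nrow(records))
  x <- as.character(records$marker_alleles)
  x[is.na(x) | x == ""] <- "none"
  mh <- lapply(strsplit(x, ",", fixed = TRUE), trimws)
  n_hit <- vapply(mh, function(v) sum(v %in% NON_EURO_MARKERS), numeric(1))
  noneuro <- if (noneuro_rule == "any") n_hit >= 1 else n_hit == length(NON_EURO_MARKERS)
  pred <- list(
    pathogenic = records$carries_pathogenic,
    non_homo_sapiens = records$species != "Homo sapiens",
    non_european = noneuro,
    truncated = records$length < min_length,
    non_major_haplogroup = !(records$haplogroup %in% major_haplogroups)
  )
  for (s in steps) {
    fail[is.na(fail) & pred[[s]]] <- s
  }
  ledger <- tibble::tibble(
    step = steps,
    removed = unname(vapply(steps, function(s) sum(fail == s, na.rm = TRUE), numeric(1))))
  list(survivors = records[is.na(fail), , drop = FALSE],
       ledger = ledger,
       record_ledger = tibble::tibble(id = records$id, step = fail)[!is.na(fail), ])
}

#' Codon-usage table for variant groups
#'
#' Per group, the percentage of coding variants in each (consequence x
#' codon position) cell; cells sum to 100% of the group's coding variants.
#'
#' @param variants Tibble with `group`, `consequence`
#'   (`"synonymous"`/`"nonsynonymous"`) and `codon_position` (1-3);
#'   non-coding rows (missing codon position) are dropped.
#' @return Tibble: `group`, `consequence`, `codon_position`, `n`,
#'   `percent`. A group with zero coding variants raises an error.
#' @export
codon_usage_table <- function(variants) {
  v <- tibble::as_tibble(variants)
  stopifnot(all(c("group", "consequence", "codon_position") %in% names(v)))
  v <- v[!is.na(v$codon_position) & v$consequence %in% c("synonymous", "nonsynonymous"), ]
  if (!nrow(v)) stop("undefined-table error: no coding variants in any group")
  grid <- tidyr::expand_grid(group = unique(v$group),
                             consequence = c("synonymous", "nonsynonymous"),
                             codon_position = 1:3)
  cnt <- v %>% dplyr::count(.data$group, .data$consequence, .data$codon_position, name = "n")
  out <- dplyr::left_join(grid, cnt, by = c("group", "consequence", "codon_position"))
  out$n[is.na(out$n)] <- 0L
  out <- out %>%
    dplyr::group_by(.data$group) %>%
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
  empty <- tapply(out$n, out$group, sum) == 0
  if (any(empty)) stop("undefined-table error: group(s) with zero coding variants: ",
                       paste(names(empty)[empty], collapse = ", "))
  out
}
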