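# helper: deterministic nonsynonymous / synonymous coding variants from the map
coding_variants_by_consequence <- function(map, locus, consequence, n) {
  oracle <- oracle_coding_annotation(map)
  sub <- oracle[oracle$locus == locus & oracle$consequence == consequence, ]
  sub <- sub[!duplicated(sub$position), ]
  sub <- sub[!in_low_complexity(sub$position, map), ]
  head(sub[, c("position", "ref", "alt")], n)
}

test_that("unique variants deduplicate across samples and respect the mask", {
  map <- shared_map()
  calls <- tibble::tibble(position = c(1000, 1000, 1000, 2000, 310),
                          ref = map$seq[c(1000, 1000, 1000, 2000, 310)],
                          alt = c("G", "G", "T", "C", "A"))
  uv <- unique_variants(calls, map)
  expect_equal(nrow(uv), 3)  # two alts at 1000 + one at 2000; masked 310 dropped
  # set-union oracle over three spike-in samples
  sets <- list(c(100, 200, 300), c(200, 300, 400), c(500))
  calls2 <- dplyr::bind_rows(lapply(sets, function(p) {
    tibble::tibble(position = p, ref = map$seq[p], alt = "A")
  }))
  calls2$alt <- ifelse(calls2$ref == "A", "G", "A")
  expect_equal(nrow(unique_variants(calls2)), length(unique(unlist(sets))))
})

test_that("Ti/Tv ratio and transversion fraction satisfy the exact identity", {
  tt <- titv_ratio(tibble::tibble(ref = rep("A", 20), alt = rep(c("G", "T"), each = 10)))
  expect_equal(tt$ratio, 1.0)
  expect_equal(titv_ratio(tibble::tibble(ref = rep("C", 5), alt = rep("A", 5)))$ratio, 0)
  inf <- titv_ratio(tibble::tibble(ref = "A", alt = "G"))
  expect_true(inf$infinite)
  expect_equal(inf$ratio, Inf)
  set.seed(3)
  for (i in 1:10) {
    n_ti <- sample(1:50, 1); n_tv <- sample(1:50, 1)
    tt <- titv_ratio(tibble::tibble(ref = "A", alt = rep(c("G", "C"), c(n_ti, n_tv))))
    expect_equal(tt$ratio, (1 - tt$tv_fraction) / tt$tv_fraction, tolerance = 1e-12)
  }
})

test_that("mean heteroplasmy averages qualifying calls only", {
  calls <- tibble::tibble(vaf = c(0.02, 0.04, 0.06, 0.995),
                          zygosity = c(rep("heteroplasmic", 3), "homoplasmic"),
                          consequence = c("nonsynonymous", "synonymous", "noncoding",
                                          "nonsynonymous"))
  expect_equal(mean_heteroplasmy(calls), 0.04)
  expect_equal(mean_heteroplasmy(calls, "nonsynonymous-heteroplasmic"), 0.02)
  expect_equal(mean_heteroplasmy(calls[1, ]), 0.02)
  expect_warning(res <- mean_heteroplasmy(calls[4, ], "heteroplasmic"), "undefined")
  expect_true(is.na(res))
})

test_that("surrogate pathogenicity scores are zero for silent variants and positive otherwise", {
  map <- shared_map()
  syn <- coding_variants_by_consequence(map, "MTCOX1", "synonymous", 5)
  ns <- coding_variants_by_consequence(map, "MTCOX1", "nonsynonymous", 5)
  expect_equal(pathogenicity_scores(syn, map)$score, rep(0, 5))
  ns_scores <- pathogenicity_scores(ns, map)$score
  expect_true(all(ns_scores > 0 & ns_scores <= 1))
  # user table takes precedence; missing entries configurable
  tab <- tibble::tibble(position = ns$position[1], alt = ns$alt[1], score = 0.77)
  got <- pathogenicity_scores(ns[1:2, ], map, score_table = tab, missing = "zero")
  expect_equal(got$score, c(0.77, 0))
  expect_warning(skipped <- pathogenicity_scores(ns[1:2, ], map, tab, missing = "skip"),
                 "skipped")
  expect_equal(nrow(skipped), 1)
})

test_that("pathogenicity comparison detects a shifted score distribution", {
  map <- shared_map()
  ns <- coding_variants_by_consequence(map, "MTCYTB", "nonsynonymous", 15)
  syn <- coding_variants_by_consequence(map, "MTCYTB", "synonymous", 15)
  res <- pathogenicity_compare(ns, syn, map)
  expect_gt(res$mean_a, res$mean_b)
  expect_lt(res$p_value, 0.05)
})

test_that("burden report flags an injected case excess in MTCOX1 after Bonferroni", {
  map <- shared_map()
  ns <- coding_variants_by_consequence(map, "MTCOX1", "nonsynonymous", 6)
  n_case <- 20; n_ctrl <- 10
  samples <- tibble::tibble(
    sample = sprintf("S%02d_SN", 1:(n_case + n_ctrl)),
    individual = sprintf("S%02d", 1:(n_case + n_ctrl)),
    tissue = "SNpc",
    status = rep(c("case", "control"), c(n_case, n_ctrl)))
  case_calls <- dplyr::bind_rows(lapply(seq_len(n_case), function(i) {
    v <- ns[1:3, ]
    tibble::tibble(sample = samples$sample[i], individual = samples$individual[i],
                   tissue = "SNpc", status = "case",
                   position = v$position, ref = v$ref, alt = v$alt,
                   vaf = 0.05, depth = 5000, zygosity = "heteroplasmic")
  }))
  calls <- annotate_calls(case_calls, map)
  rep <- burden_report(calls, samples, map)
  co1 <- rep$locus_tests[rep$locus_tests$stratum == "MTCOX1", ]
  expect_equal(nrow(co1), 1)
  expect_lt(co1$p_adjusted, 0.05)
  expect_gt(co1$mean_case, co1$mean_control)
  # group-level heteroplasmic burden is also case-elevated
  het <- rep$group_tests[rep$group_tests$variant_type == "heteroplasmic", ]
  expect_lt(het$p_value, 0.05)
  # high-heteroplasmy table present with Fisher p
  expect_true(all(rep$high_het$p_value >= 0 & rep$high_het$p_value <= 1))
})

test_that("degenerate single-sample groups yield a report with not-computable tests", {
  map <- shared_map()
  ns <- coding_variants_by_consequence(map, "MTND1", "nonsynonymous", 2)
  samples <- tibble::tibble(sample = c("A_SN", "B_SN"), individual = c("A", "B"),
                            tissue = "SNpc", status = c("case", "control"))
  calls <- annotate_calls(
    tibble::tibble(sample = "A_SN", individual = "A", tissue = "SNpc", status = "case",
                   position = ns$position, ref = ns$ref, alt = ns$alt,
                   vaf = 0.03, depth = 3000, zygosity = "heteroplasmic"), map)
  rep <- burden_report(calls, samples, map)
  expect_true(all(rep$group_tests$method == "not-computable"))
  expect_true(all(is.na(rep$group_tests$p_value)))
})

test_that("locus-stratum counts conserve the per-sample coding total modulo overlap double counts", {
  map <- shared_map()
  set.seed(21)
  calls <- random_call_set(map, 60)
  calls$sample <- "S1"
  byloc <- mthet:::.calls_by_locus(calls, map)
  coding_rows <- byloc[byloc$category == "coding", ]
  ann <- annotate_calls(calls, map)
  n_coding_calls <- sum(ann$region_class == "coding")
  ov <- sum(table(paste(coding_rows$position, coding_rows$alt)) > 1)
  expect_equal(nrow(coding_rows) - ov, n_coding_calls)
})
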