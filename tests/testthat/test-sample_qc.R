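test_that("coverage QC applies the 99% at 1500x rule on vectors and run-length profiles", {
  n <- 16569
  prof <- rep(5000, n)
  prof[seq_len(round(0.008 * n))] <- 100  # 99.2% covered
  expect_true(coverage_pass(prof))
  prof[seq_len(round(0.011 * n))] <- 100  # 98.9% covered
  expect_false(coverage_pass(prof))
  expect_true(coverage_pass(rep(1500, n)))  # boundary: fraction exactly 1
  rle_pass <- data.frame(start = c(1, 201), end = c(200, 16569), depth = c(100, 3000))
  expect_false(coverage_pass(rle_pass))  # 200/16569 ~ 1.2% below depth
  rle_ok <- data.frame(start = c(1, 101), end = c(100, 16569), depth = c(100, 3000))
  expect_true(coverage_pass(rle_ok))
  expect_error(coverage_pass(numeric(0)), "input")
  expect_error(coverage_pass(data.frame(start = 1, end = 100, depth = 5)), "input")
})

test_that("haplogroup assignment scores panel fractions with most-derived tie-breaking", {
  panel <- haplogroup_panel()
  j <- panel[panel$haplogroup == "J", ]
  calls_j <- tibble::tibble(position = j$position, alt = j$alt, zygosity = "homoplasmic")
  expect_equal(assign_haplogroup(calls_j, panel), "J")
  # no markers matched: root (rCRS-like) label
  expect_equal(assign_haplogroup(tibble::tibble(position = integer(), alt = character(),
                                                zygosity = character()), panel), "H")
  # all J plus all T markers: brute-force the expected winner from the panel
  jt <- panel[panel$haplogroup %in% c("J", "T"), ]
  calls_jt <- tibble::tibble(position = jt$position, alt = jt$alt, zygosity = "homoplasmic")
  have <- paste(jt$position, jt$alt)
  scores <- sapply(split(panel, panel$haplogroup), function(g) {
    mean(paste(g$position, g$alt) %in% have)
  })
  sizes <- sapply(split(panel, panel$haplogroup), nrow)
  best <- names(scores)[order(-scores, -sizes, names(scores))][1]
  expect_equal(assign_haplogroup(calls_jt, panel), best)
  expect_error(assign_haplogroup(calls_j, panel[0, ]), "configuration")
})

test_that("assignment ignores heteroplasmic calls and call order", {
  panel <- haplogroup_panel()
  u <- panel[panel$haplogroup == "U", ]
  calls <- tibble::tibble(position = u$position, alt = u$alt, zygosity = "homoplasmic")
  noisy <- rbind(tibble::tibble(position = c(16069, 4216), alt = c("T", "C"),
                                zygosity = "heteroplasmic"),  # J markers, het only
                 calls)
  expect_equal(assign_haplogroup(noisy, panel), "U")
  expect_equal(assign_haplogroup(noisy[sample(nrow(noisy)), ], panel), "U")
})

test_that("pair concordance compares backbone labels only", {
  expect_true(pair_concordant("H", "H"))
  expect_false(pair_concordant("H", "J"))
  expect_true(pair_concordant("U", "U"))
  expect_error(pair_concordant("H", NA), "pairing")
})

test_that("cohort QC retains 103 of 120 on the bookkeeping fixture and conserves pairs", {
  fx <- make_bookkeeping_fixture("cohort_qc")
  qc <- apply_cohort_qc(fx$pairs, fx$coverage_ok)
  expect_equal(nrow(qc$retained), 103)
  expect_equal(unname(qc$counts["case"]), 84)
  expect_equal(unname(qc$counts["control"]), 19)
  expect_equal(nrow(qc$ledger), 17)
  expect_equal(sum(qc$ledger$reason == "haplogroup_discordant"), 8)
  expect_equal(sum(qc$ledger$reason == "coverage_fail"), 9)
  # conservation: retained + excluded = input, disjointly
  expect_equal(nrow(qc$retained) + nrow(qc$ledger), nrow(fx$pairs))
  expect_length(intersect(qc$retained$individual, qc$ledger$individual), 0)
})

test_that("cohort QC edge behavior: identity, total exclusion, double-failure precedence", {
  fx <- make_bookkeeping_fixture("cohort_qc")
  all_ok <- setNames(rep(TRUE, nrow(fx$pairs)), fx$pairs$individual)
  clean <- fx$pairs
  clean$snpc_haplogroup <- clean$fc_haplogroup
  expect_equal(nrow(apply_cohort_qc(clean, all_ok)$retained), 120)
  # all discordant: empty cohort, full ledger
  bad <- clean
  bad$snpc_haplogroup <- "X"
  qc <- apply_cohort_qc(bad, all_ok)
  expect_equal(nrow(qc$retained), 0)
  expect_equal(nrow(qc$ledger), 120)
  # a pair failing both rules is ledgered once, under discordance
  both <- clean[1:2, ]
  both$snpc_haplogroup[1] <- "J"
  cov <- setNames(c(FALSE, TRUE), both$individual)
  qc2 <- apply_cohort_qc(both, cov)
  expect_equal(qc2$ledger$reason, "haplogroup_discordant")
  expect_equal(nrow(qc2$ledger), 1)
})
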