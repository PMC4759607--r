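mk_calls <- function(position, ref, alt, vaf) {
  tibble::tibble(position = position, ref = ref, alt = alt, vaf = vaf,
                 zygosity = ifelse(vaf >= 0.99, "homoplasmic", "heteroplasmic"))
}

test_that("the four somatic classes follow the presence/delta rules", {
  fc <- mk_calls(c(200, 300, 400, 500), "A", "G", c(0.05, 0.02, 0.08, 0.5))
  sn <- mk_calls(c(300, 400, 500, 600), "A", "G", c(0.08, 0.02, 0.503, 0.05))
  ev <- classify_somatic(fc, sn)
  expect_equal(ev$class[ev$position == 600], "de_novo")
  expect_equal(ev$het_fc[ev$position == 600], 0)
  expect_equal(ev$class[ev$position == 200], "loss")
  expect_equal(ev$het_snpc[ev$position == 200], 0)
  expect_equal(ev$class[ev$position == 300], "positive_shift")
  expect_equal(ev$class[ev$position == 400], "negative_shift")
  expect_equal(ev$class[ev$position == 500], "unchanged")  # |delta| below dead band
  expect_equal(ev$delta, ev$het_snpc - ev$het_fc)
})

test_that("presence is defined by calling, and double homoplasmy cannot shift", {
  # sub-threshold FC signal is absent by definition: SNpc-only call is de novo
  ev <- classify_somatic(mk_calls(integer(0), character(0), character(0), numeric(0)),
                         mk_calls(100, "A", "G", 0.012))
  expect_equal(ev$class, "de_novo")
  # homoplasmic in both tissues: unchanged even with a measurable delta
  ev2 <- classify_somatic(mk_calls(100, "A", "G", 1.0), mk_calls(100, "A", "G", 0.991))
  expect_equal(ev2$class, "unchanged")
  # homoplasmic -> heteroplasmic is a negative shift
  ev3 <- classify_somatic(mk_calls(100, "A", "G", 0.995), mk_calls(100, "A", "G", 0.60))
  expect_equal(ev3$class, "negative_shift")
})

test_that("inconsistent reference alleles at a shared position are rejected", {
  expect_error(classify_somatic(mk_calls(100, "A", "G", 0.05), mk_calls(100, "C", "G", 0.05)),
               "inconsistency")
})

test_that("classification is idempotent, order-independent, and symmetric under tissue swap", {
  map <- shared_map()
  set.seed(31)
  for (i in 1:200) {
    fc <- random_call_set(map, sample(0:8, 1))
    sn_own <- random_call_set(map, sample(0:8, 1))
    shared_idx <- seq_len(min(nrow(fc), 3))
    sn <- rbind(sn_own[!sn_own$position %in% fc$position, ],
                transform(fc[shared_idx, , drop = FALSE],
                          vaf = pmin(0.98, pmax(0.011,
                                                vaf + sample(c(-0.05, 0, 0.002, 0.05),
                                                             length(shared_idx), replace = TRUE)))))
    sn$zygosity <- ifelse(sn$vaf >= 0.99, "homoplasmic", "heteroplasmic")
    ev <- classify_somatic(fc, sn)
    # partition: every variant in >= 1 tissue appears exactly once
    all_keys <- unique(c(paste(fc$position, fc$alt), paste(sn$position, sn$alt)))
    expect_setequal(paste(ev$position, ev$alt), all_keys)
    expect_equal(nrow(ev), length(all_keys))
    # idempotence / order independence
    ev_shuf <- classify_somatic(fc[sample(nrow(fc)), ], sn[sample(nrow(sn)), ])
    expect_equal(ev, ev_shuf)
    # swap maps de_novo<->loss and positive<->negative exactly
    swapped <- classify_somatic(sn, fc)
    swap_rule <- c(de_novo = "loss", loss = "de_novo", positive_shift = "negative_shift",
                   negative_shift = "positive_shift", unchanged = "unchanged")
    m <- merge(ev[, c("position", "alt", "class")], swapped[, c("position", "alt", "class")],
               by = c("position", "alt"))
    expect_equal(unname(swap_rule[m$class.x]), m$class.y)
  }
})

test_that("summaries count classes with zero-completion and percentage breakdowns", {
  pairs <- tibble::tibble(individual = c("I1", "I2"), status = c("case", "control"))
  ev <- tibble::tibble(individual = "I1", status = "case",
                       position = 1:4, ref = "A", alt = "G",
                       class = c("de_novo", "loss", "positive_shift", "negative_shift"),
                       het_fc = c(0, 0.05, 0.02, 0.08), het_snpc = c(0.05, 0, 0.08, 0.02),
                       delta = c(0.05, -0.05, 0.06, -0.06))
  s <- somatic_summary(ev, pairs)
  expect_equal(s$totals$n, rep(1, 4))
  expect_equal(sum(s$per_sample$count[s$per_sample$individual == "I2"]), 0)
  expect_equal(nrow(s$per_sample), 8)  # 2 individuals x 4 classes
  # empty event set gives an all-zero summary
  s0 <- somatic_summary(ev[0, ], pairs)
  expect_equal(s0$totals$n, rep(0, 4))
})

test_that("class-rate comparison reports the direction of effect", {
  pairs <- tibble::tibble(individual = sprintf("I%02d", 1:20),
                          status = rep(c("case", "control"), each = 10))
  # controls lose more variants than cases
  ev <- dplyr::bind_rows(lapply(11:20, function(i) {
    tibble::tibble(individual = sprintf("I%02d", i), status = "control",
                   position = 1:5 + i, ref = "A", alt = "G", class = "loss",
                   het_fc = 0.05, het_snpc = 0, delta = -0.05)
  }))
  res <- compare_class_rates(somatic_summary(ev, pairs))
  loss <- res$class_tests[res$class_tests$class == "loss", ]
  expect_equal(loss$direction, "control-elevated")
  expect_lt(loss$p_value, 0.05)
  expect_error(compare_class_rates(somatic_summary(ev, pairs[11:20, ])), "report")
})
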