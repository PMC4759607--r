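test_that("positions map to the expected loci, including overlaps and the origin wrap", {
  map <- shared_map()
  expect_equal(locus_of(3243, map)$name, "MTTL1")
  expect_equal(locus_of(3243, map)$category, "tRNA")
  expect_setequal(locus_of(8550, map)$name, c("MTATP8", "MTATP6"))
  expect_setequal(locus_of(10762, map)$name, c("MTND4L", "MTND4"))
  expect_equal(locus_of(16100, map)$name, "DLOOP")
  # control region wraps 16024 -> 576
  expect_equal(locus_of(16569, map)$name, "DLOOP")
  expect_equal(locus_of(1, map)$name, "DLOOP")
  expect_equal(locus_of(576, map)$name, "DLOOP")
  expect_false("DLOOP" %in% locus_of(600, map)$name)
  expect_equal(nrow(locus_of(3306, map)), 0)  # intergenic gap
  expect_error(locus_of(0, map), "coordinate")
  expect_error(locus_of(16570, map), "coordinate")
})

test_that("locus lookup is deterministic and covers the coding length accounting", {
  map <- shared_map()
  coding <- map$loci[map$loci$category == "coding", ]
  len <- sum(coding$end - coding$start + 1)
  # positions hit by >= 1 coding locus, counted once
  hits <- rep(0L, map$genome_length)
  for (i in seq_len(nrow(coding))) {
    hits[coding$start[i]:coding$end[i]] <- hits[coding$start[i]:coding$end[i]] + 1L
  }
  overlap <- sum(hits[hits > 1] - 1L)
  expect_equal(sum(hits > 0), len - overlap)
  expect_equal(nrow(map$codon_table), len)  # one codon row per coding position per locus
})

test_that("low-complexity mask membership follows the configured tracts", {
  map <- shared_map()
  expect_true(in_low_complexity(310, map))
  expect_true(all(in_low_complexity(c(302, 316, 513, 526, 16181, 16194), map)))
  expect_false(in_low_complexity(5000, map))
  empty <- mt_locus_map(mask = integer(0))
  expect_false(any(in_low_complexity(c(310, 520, 16190), empty)))
  # BED override: 0-based half-open converts to 1-based inclusive
  bed <- tempfile(fileext = ".bed")
  writeLines("chrMT\t99\t105", bed)
  custom <- mt_locus_map(mask = bed)
  expect_equal(custom$low_complexity, 100:105)
})

test_that("substitution classes partition the 12 ordered base pairs 4/8", {
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- substitution_class(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "transition"), 4)
  expect_equal(sum(cls == "transversion"), 8)
  expect_equal(substitution_class("A", "G"), "transition")
  expect_error(substitution_class("A", "N"), "allele")
  expect_error(substitution_class("A", "A"), "allele")
})

test_that("annotation handles coding, noncoding, light-strand and overlap cases", {
  map <- shared_map()
  ann <- annotate_variants(data.frame(position = 8701, ref = "A", alt = "G"), map)
  expect_equal(ann$locus, "MTATP6")
  expect_equal(ann$consequence, "nonsynonymous")
  expect_equal(ann$substitution_class, "transition")
  expect_equal(ann$codon_position, 1L)

  # D-loop substitution is noncoding whatever the alleles
  ref16100 <- map$seq[16100]
  alt <- setdiff(c("A", "C"), ref16100)[1]
  dl <- annotate_variants(data.frame(position = 16100, ref = ref16100, alt = alt), map)
  expect_equal(dl$consequence, "noncoding")
  expect_true(is.na(dl$codon_position))

  # overlap position annotated once per gene, independently
  ref8550 <- map$seq[8550]
  ov <- annotate_variants(data.frame(position = 8550, ref = ref8550,
                                     alt = setdiff(c("A", "G", "C"), ref8550)[1]), map)
  expect_setequal(ov$locus, c("MTATP8", "MTATP6"))
  expect_equal(nrow(ov), 2)

  # light-strand gene translates off the reverse complement
  nd6 <- annotate_variants(data.frame(position = 14400, ref = map$seq[14400],
                                      alt = setdiff(c("A", "G"), map$seq[14400])[1]), map)
  expect_equal(nd6$locus, "MTND6")
  expect_true(nd6$consequence %in% c("synonymous", "nonsynonymous"))

  expect_error(annotate_variants(data.frame(position = 8701,
                                            ref = setdiff(c("C", "G"), map$seq[8701])[1],
                                            alt = "T"), map),
               "reference error")
  expect_error(annotate_variants(data.frame(position = 100, ref = map$seq[100], alt = "N"), map),
               "allele")
})

test_that("coding annotation agrees with the translation oracle on sampled positions", {
  map <- shared_map()
  oracle <- oracle_coding_annotation(map)
  set.seed(42)
  idx <- sample(nrow(oracle), 400)
  sub <- oracle[idx, ]
  ann <- annotate_variants(sub[, c("position", "ref", "alt")], map)
  merged <- merge(sub, ann, by = c("position", "ref", "alt", "locus"),
                  suffixes = c("_oracle", "_impl"))
  expect_equal(nrow(merged), nrow(sub))
  expect_equal(merged$consequence_impl, merged$consequence_oracle)
  expect_equal(merged$ref_aa_impl, merged$ref_aa_oracle)
  expect_equal(merged$alt_aa_impl, merged$alt_aa_oracle)
  expect_equal(merged$codon_position_impl, merged$codon_position_oracle)
})

test_that("locus aliases normalize to the map's symbols", {
  expect_equal(normalize_locus(c("MT-CO1", "MTCO2", "COX3", "MT-CYB", "MTND4", "MTDN4")),
               c("MTCOX1", "MTCOX2", "MTCOX3", "MTCYTB", "MTND4", "MTND4"))
})
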