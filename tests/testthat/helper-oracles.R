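# Independent oracles and small fixture builders shared across the suite.

# Fisher two-sided p by direct enumeration with binomial coefficients
# (independent of the dhyper-based implementation).
oracle_fisher <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  p_obs <- pr[support == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings
# (midranks), independent of the shift-algorithm implementation.
oracle_mw_exact <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  mu <- n * m / 2
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  subsets <- utils::combn(N, n)
  U_all <- colSums(matrix(r[subsets], nrow = n)) - n * (n + 1) / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# Codon-by-codon translation of every coding locus straight off the map's
# sequence: plain loops, no shared code with annotate_variants().
oracle_coding_annotation <- function(map) {
  gc2 <- Biostrings::getGeneticCode("2")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  coding <- map$loci[map$loci$category == "coding", ]
  rows <- list()
  for (g in seq_len(nrow(coding))) {
    st <- coding$start[g]; en <- coding$end[g]; strand <- coding$strand[g]
    cds <- if (strand == "heavy") map$seq[st:en] else unname(comp[map$seq[en:st]])
    gpos <- if (strand == "heavy") st:en else en:st
    len <- length(cds)
    n_codon <- ceiling(len / 3)
    cds_pad <- c(cds, rep("A", n_codon * 3 - len))
    for (k in seq_len(n_codon)) {
      codon <- cds_pad[(3 * k - 2):(3 * k)]
      for (j in 1:3) {
        idx <- 3 * (k - 1) + j
        if (idx > len) next
        pos <- gpos[idx]
        ref_aa <- gc2[[paste(codon, collapse = "")]]
        for (alt in setdiff(c("A", "C", "G", "T"), map$seq[pos])) {
          alt_cds <- if (strand == "heavy") alt else unname(comp[alt])
          mut <- codon; mut[j] <- alt_cds
          alt_aa <- gc2[[paste(mut, collapse = "")]]
          rows[[length(rows) + 1L]] <- data.frame(
            position = pos, ref = map$seq[pos], alt = alt,
            locus = coding$name[g], codon_position = j,
            ref_aa = ref_aa, alt_aa = alt_aa,
            consequence = if (ref_aa == alt_aa) "synonymous" else "nonsynonymous",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

# one-row allele-count table with given ref/alt evidence, balanced strands
make_counts_row <- function(position, ref, alt, depth, alt_reads,
                            alt_fwd = alt_reads %/% 2, ref_fwd = NULL) {
  ref_reads <- depth - alt_reads
  if (is.null(ref_fwd)) ref_fwd <- ref_reads %/% 2
  row <- data.frame(position = position, ref = ref,
                    A_fwd = 0L, A_rev = 0L, C_fwd = 0L, C_rev = 0L,
                    G_fwd = 0L, G_rev = 0L, T_fwd = 0L, T_rev = 0L)
  row[[paste0(alt, "_fwd")]] <- alt_fwd
  row[[paste0(alt, "_rev")]] <- alt_reads - alt_fwd
  row[[paste0(ref, "_fwd")]] <- row[[paste0(ref, "_fwd")]] + ref_fwd
  row[[paste0(ref, "_rev")]] <- row[[paste0(ref, "_rev")]] + ref_reads - ref_fwd
  row
}

# random call set on non-masked positions, for somatic property tests
random_call_set <- function(map, n, vaf_range = c(0.011, 0.98)) {
  pos <- sample(setdiff(seq_len(map$genome_length), map$low_complexity), n)
  ref <- map$seq[pos]
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  vaf <- runif(n, vaf_range[1], vaf_range[2])
  tibble::tibble(position = pos, ref = unname(ref), alt = unname(alt), vaf = vaf,
                 zygosity = ifelse(vaf >= 0.99, "homoplasmic", "heteroplasmic"))
}

shared_map <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- mt_locus_map()
    m
  }
})
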