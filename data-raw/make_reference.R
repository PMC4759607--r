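# One-off: generate the synthetic rCRS stand-in sequence.
# Real locus coordinates; simulated bases. Coding regions are kept free of
# in-frame stop codons (vertebrate mito code) in each gene's own frame where
# positions are not locked by a constraint or an already-built overlapping gene.
set.seed(20120920L)
L <- 16569L
loci <- read.delim("inst/extdata/rcrs_loci.tsv")
panel <- read.delim("inst/extdata/haplogroup_panel.tsv")

bases <- c("A", "C", "G", "T")
seqv <- sample(bases, L, replace = TRUE)

comp <- c(A = "T", C = "G", G = "C", T = "A")

# fixed-base constraints: MELAS site ref A, m.8701 ref A, panel refs != alt
fixed <- c("3243" = "A", "8701" = "A", "8540" = "T", "10873" = "T")
for (i in seq_len(nrow(panel))) {
  p <- as.character(panel$position[i])
  if (!p %in% names(fixed)) {
    alt <- panel$alt[i]
    fixed[p] <- sample(setdiff(bases, alt), 1)
  }
}
locked <- rep(FALSE, L)
for (p in names(fixed)) {
  seqv[as.integer(p)] <- fixed[[p]]
  locked[as.integer(p)] <- TRUE
}

stops_h <- c("TAA", "TAG", "AGA", "AGG")
coding <- loci[loci$category == "coding", ]
coding <- coding[order(coding$start), ]
for (g in seq_len(nrow(coding))) {
  st <- coding$start[g]; en <- coding$end[g]; strand <- coding$strand[g]
  n_codon <- (en - st + 1L) %/% 3L
  for (k in seq_len(n_codon)) {
    if (strand == "heavy") pos <- st + 3L * (k - 1L) + 0:2 else pos <- en - 3L * (k - 1L) - 0:2
    free <- !locked[pos]
    for (try in 1:50) {
      cod <- seqv[pos]
      if (strand == "light") cod <- comp[cod]
      if (!paste(cod, collapse = "") %in% stops_h) break
      if (!any(free)) break
      seqv[pos[free]] <- sample(bases, sum(free), replace = TRUE)
    }
  }
  locked[seq(min(st, en), max(st, en))] <- TRUE
}

fa <- paste(seqv, collapse = "")
lines <- c(">rCRS_synthetic stand-in for NC_012920 coordinates; simulated sequence",
           substring(fa, seq(1, L, 70), pmin(seq(1, L, 70) + 69, L)))
writeLines(lines, "inst/extdata/rcrs_synthetic.fasta")
cat("length", nchar(fa), " base at 3243:", seqv[3243], " 8701:", seqv[8701], "\n")
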