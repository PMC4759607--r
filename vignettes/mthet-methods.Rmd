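---
title: "Methods: heteroplasmy calling, somatic classification and burden statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heteroplasmy calling, somatic classification and burden statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mthet)
```

## The problem

Mitochondrial DNA is present in hundreds to thousands of copies per cell, so a
point substitution is not simply present or absent: it has a *heteroplasmy
level*, the fraction of mtDNA molecules carrying the alternate allele,
estimated from deep sequencing as the variant allele fraction (VAF). In
neurodegeneration research, a central question is whether an affected region
(here the substantia nigra pars compacta, SNpc) accumulates more somatic mtDNA
mutation than a relatively spared region of the same brain (frontal cortex,
FC). Because both tissues inherit the same maternal mtDNA backbone, FC can be
used as an ancestral reference against which SNpc-specific changes are read
off.

`mthet` implements the post-alignment part of such a study as a reusable,
tested pipeline: threshold heteroplasmy calling from per-site allele counts,
consequence annotation in rCRS coordinates, coverage and haplogroup-concordance
sample QC, case/control burden statistics, a four-class somatic taxonomy for
FC→SNpc changes, and a reference-set filter chain with codon-usage tables. A
synthetic paired-cohort generator stands in for tissue data, so every stage is
exercisable end-to-end and the somatic classifier can be checked against known
truth labels.

## Coordinates, reference and annotation

All coordinates are 1-based inclusive rCRS positions (the m.-notation of the
16,569 bp human mitochondrial reference, NC_012920). The control region
(`DLOOP`) wraps the origin (16024 → 576); wrap is handled by interval logic,
never by shifting coordinates. Overlapping gene pairs (MTATP8/MTATP6,
MTND4L/MTND4) are annotated independently, and a variant in an overlap
contributes once to *each* gene in locus-stratified burden tables, because the
locus tests are per-gene.

The bundled reference sequence is a **synthetic stand-in**
(`inst/extdata/rcrs_synthetic.fasta`): the locus intervals are the true
published rCRS gene coordinates, but the bases are simulated (coding regions
generated free of in-frame stops in each gene's own frame, with fixed bases at
a few positions used by examples and the haplogroup panel). Annotation is
therefore internally consistent — the test suite verifies it against an
independent codon-by-codon translation oracle over every coding position — but
amino-acid identities at specific rCRS positions are not biological. To
annotate real data, pass a genuine NC_012920 FASTA to `mt_locus_map(fasta =
...)`; no other part of the package changes.

Consequence calls use the vertebrate mitochondrial genetic code (`Biostrings`
code table 2: AGA/AGG are stop, ATA is Met, TGA is Trp). The light-strand gene
(MTND6) is translated from the reverse complement with codon 1 at its high
genomic coordinate. Genes whose length is not a codon multiple end in an
incomplete stop codon; the missing 1–2 bases are completed with A's, mirroring
mRNA polyadenylation.

The default low-complexity mask covers the three rCRS homopolymer (poly-C)
tracts m.302–316, m.513–526 and m.16181–16194; variants there are excluded
from all comparative analyses. The mask is replaceable by any BED file
(0-based half-open, converted on read). The literature this design follows
cites low-complexity exclusion without printing coordinates, so the default is
an explicit, overridable surrogate.

## Calling model

Input is a per-site table of strand-split base counts from reads that already
passed base-quality (≥ 30) and mapping-quality (≥ 20) filters upstream — the
caller deliberately does not re-examine per-read quality. A call is emitted
for every non-reference base satisfying all of:

* depth ≥ 1500 (`min_depth`),
* supporting reads ≥ 10 (`min_alt_reads`),
* VAF ≥ 1.0 % (`min_vaf`, inclusive).

Calls with VAF in [1 %, 99 %) are *heteroplasmic*; ≥ 99 % *homoplasmic*. The
boundary conventions (≥ at 1 %, ≥ at 99 %) make the classification total; the
inclusive 1 % threshold matches the common caller convention. A site with zero
depth is reported as *no coverage*, distinct from "no variant".

Strand bias is filtered as a post-call step: a call fails only when a
two-sided exact test on the (ref/alt × fwd/rev) table is significant at α =
0.05 **and** the alt reads are > 90 % on one strand. The two-condition rule
avoids discarding deep, mildly unbalanced calls that are statistically
"significant" only because of depth. These two parameters are declared
surrogates for an upstream caller's unpublished internals, and are
configurable. A `concordant_calls()` hook intersects two call sets for designs
that call with two independent callers and keep the concordant set.

## Sample QC and haplogroup concordance

A sample passes coverage QC when ≥ 99 % of the 16,569 positions have depth
≥ 1500×. Pairs must also be haplogroup-concordant: both tissues of one
individual are assigned a haplogroup from a small bundled marker panel
(macro-haplogroups V, J, T, U, K, W, X, I; the rCRS-like H branch is the root
label) and discordant pairs are removed. Assignment scores each haplogroup by
the fraction of its defining variants present among *homoplasmic* calls; ties
break to the larger defining set (most derived), then lexicographically. The
panel is sufficient for concordance checking — its only job here — and is not
a fine-clade classifier; a custom panel TSV can be supplied.

QC is sequential: a pair failing both rules is ledgered once, under
discordance. The ledger plus retained set always reconstructs the input
exactly (conservation), which the suite asserts.

## Burden statistics

Per tissue, case/control comparisons of per-sample variant counts use the
Mann-Whitney U test; per-locus tests of nonsynonymous-heteroplasmic counts are
Bonferroni-corrected with family size = number of locus strata tested in that
tissue. The high-heteroplasmy analysis (variants above 10 % VAF, strict `>`;
the boundary is untested by any published value) uses Fisher's exact test,
because the published p-values on the printed tables (0.49 and 1.00) are
reproduced by Fisher and not by Pearson's chi-squared (≈ 0.25 on the same
table).

The test statistics are authored in the package rather than wrapped:

* **Fisher's exact test** sums all hypergeometric outcomes with probability ≤
  that of the observed table (with a 1 + 10⁻⁷ relative guard against
  floating-point ties, the same convention as base R). The suite checks it
  against brute-force enumeration with binomial coefficients on *every* 2×2
  table with N ≤ 60, and against `stats::fisher.test` on random tables.
* **Mann-Whitney U** uses midranks; for n + m ≤ 20 the exact two-sided
  p-value comes from the shift-algorithm (generating-function) distribution of
  the doubled rank sum, so ties are handled exactly; larger samples use the
  normal approximation with tie-corrected variance and continuity correction.
  The exact route is verified against full permutation enumeration, the
  approximate route against `stats::wilcox.test`.
* **Pearson's chi-squared** is the direct Σ(O−E)²/E with a 1-df p-value, no
  continuity correction, used for the per-locus somatic comparisons.

Dual routes (own implementation vs base R vs enumeration oracle) are kept
deliberately separate so no check collapses into testing a library against
itself.

The default pathogenicity scorer is an explicit surrogate: 0 for synonymous
and non-coding variants, and for nonsynonymous changes a BLOSUM62-derived
dissimilarity of the amino-acid exchange, rescaled to [0, 1]. BLOSUM62 is used
because it ships with `Biostrings` and gives a monotone "chemical surprise"
ordering; it is *not* a clinical score, and any user-supplied (position, alt)
→ score table takes precedence. Published analyses in this area used an
external scorer that is not redistributable; the surrogate keeps the module
exercisable and the comparison machinery (per-stratum means + Mann-Whitney)
identical.

## Somatic taxonomy

For each QC-passed pair, calls are matched on (position, alt), FC as the
ancestral tissue. Classes:

* `de_novo` — called in SNpc, not in FC;
* `loss` — called in FC, not in SNpc;
* `positive_shift` / `negative_shift` — called in both, with the heteroplasmy
  delta (SNpc − FC) at least `min_shift_delta` in magnitude, signed
  accordingly;
* `unchanged` — called in both with |Δ| below the dead band (not a
  differential variant).

Presence means *called*: a variant at 0.9 % in FC and 1.2 % in SNpc is
`de_novo`, because the class definitions operate on the caller's notion of
existence. `min_shift_delta` defaults to one percentage point, which is ≈ 5
binomial standard deviations of a VAF estimate at 2000× and low VAF, so
sampling noise essentially never fabricates a shift; it is configurable and
echoed in the report. Variants homoplasmic in both tissues are `unchanged` by
fiat (there is no room to shift upward, and reference-allele dropout at
≥ 99 % VAF is not interpretable as selection). Swapping the two tissues maps
de_novo ↔ loss and positive ↔ negative shifts exactly; the suite asserts this
swap symmetry and the partition property on 1000 random pairs.

## Reference-set filter chain

The codon-bias module operates on *flagged record tables*, not raw GenBank
downloads (the originating database query is not reproducible desk-side).
Filters apply sequentially in a fixed order — pathogenic-variant carriers,
non-Homo-sapiens, non-European marker carriers (m.8701A, m.8540T, m.10873T),
truncated sequences (< 16,500 bp), then records outside the major haplogroups
H, V, J, T, U, K, W, X, I, R, N — and each record is ledgered under the first
filter it fails. Whether *any* or *all* of the three markers defines
non-European is unstated in the source literature; the default is "any",
configurable. On fixtures with disjoint flags (as bundled), filter order does
not affect the survivor set, which the suite asserts. Codon-usage tables
report, per group, the percentage of coding variants in each (consequence ×
codon position) cell, summing to 100 %.

## The synthetic cohort generator

`sim_params()` defaults *are* the study conditions: 97 case and 23 control
pairs; negative-binomial depth (mean 5000, size 10) floored at 1500; per-
sample FC heteroplasmic variant counts ~ Poisson(5); VAF ~ Beta(1.2, 40)
truncated to [0.015, 0.95], giving mean ≈ 0.03 with the overwhelming majority
below 10 %, as low-level somatic heteroplasmy shows; Ti:Tv probability 0.9;
D-loop positions upweighted 3×; and, in cases, a 3× position weight on
MTCOX1/MTCOX2/MTCYTB. Somatic dynamics: FC variants are retained in SNpc with
probability 0.70 (cases) / 0.85 (controls) — the difference injects the
purifying-loss excess; retained variants shift with probability 0.35, with
magnitude |N(0.03, 0.015)| floored at 0.015 and positive direction probability
0.30 (cases) / 0.50 (controls); de-novo SNpc variants ~ Poisson(6) in cases vs
Poisson(3) in controls. These effect sizes were chosen once to give essentially
full power for the direction-recovery checks at cohort scale, and are stated
in the tests that use them. Where the source study printed no value (rates,
Beta shapes, weights), the defaults are the package's own choice of what a
deep-sequencing mtDNA study plausibly looks like, and they are not revisited.

Sequencing error is per-base (default 10⁻³): alt reads are drawn binomially
with the error folded in, and each sample also emits error-only background
positions. With `error_rate = 0` the generator emits *idealized* counts
(`alt = round(vaf · depth)`, balanced strands): combined with the VAF and
shift floors above, rounding at the depth floor can never cross the 1 %
calling bound or the shift dead band, so somatic truth-label recovery is
*exactly* assertable — the test suite requires 100 % agreement at zero
error, and the analysis scripts report ≈ 99 % at error 10⁻³.

What the generator does **not** emulate: read-level artifacts (PCR chimeras,
index hopping, alignment error), position-dependent error spectra, copy-number
variation, and contamination. Passing tests therefore show that the analysis
logic is correct under the stated statistical model, not that the pipeline is
robust to every artifact of real sequencing data.

Deterministic bookkeeping fixtures (`make_bookkeeping_fixture()`) reproduce
two published compositions exactly: the 120-pair cohort-QC structure (8
discordant + 9 coverage-failed, disjoint → 103 retained, 84 cases / 19
controls; the case/control split of the exclusions is not printed in the
source and is derived from the retained counts as 13/4) and the
18,114-record reference chain (458 + 7 + 7051 + 663 removed → 9935; 2206
non-major → 7729).

## Numerical and design choices

* Problem sizes in the test suite (cohorts of 20–100 pairs, 3000-site error
  studies, 1000-pair somatic property loops) are the package's chosen balance
  of statistical resolution against a suite that runs in a few minutes on one
  CPU.
* Exact tests switch to approximations only where stated (Mann-Whitney above
  n + m = 20); Fisher is always exact.
* Ratios with empty denominators are reported as explicit signals (`Inf` +
  flag for zero transversions; `NA` + warning for empty mean-VAF sets; errors
  for zero-margin chi-squared tables), never silently coerced.
* The pipeline driver (`run_pipeline()`) echoes every threshold into its
  output, and every reported number is reproducible from the emitted tidy
  tables — there is no hidden state. The numbered scripts under `analysis/`
  are thin narrative drivers over the same exported functions; the package
  functions, those scripts and this vignette are the interface (there is no
  shell CLI).

## Known limitations

* The bundled reference sequence is synthetic (above); biological amino-acid
  identities require a real NC_012920 FASTA.
* Indels are out of scope throughout (calling, annotation, somatic classes).
* Haplogrouping is a macro-haplogroup marker panel, adequate for pair
  concordance only.
* The somatic taxonomy is presence-based; partial signal below the calling
  threshold in one tissue is treated as absence, so very low-VAF shifts are
  classified as gains/losses. This matches the class definitions but callers
  with different thresholds will move variants between classes.
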