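# mthet — heteroplasmy and somatic mtDNA variation in paired tissues

`mthet` is an R package plus a numbered analysis workflow for studying
mitochondrial DNA point-mutational burden in paired brain tissues, where the
frontal cortex (FC) serves as an ancestral mtDNA reference and the substantia
nigra pars compacta (SNpc) as the vulnerable tissue. It is aimed at groups
analyzing deep (>1500×) mtDNA sequencing of case/control cohorts who need the
post-alignment steps as tested, reusable code.

## What it computes

* **Heteroplasmy calling** from strand-split per-site allele counts: a call
  requires depth ≥ 1500, supporting reads ≥ 10 and VAF ≥ 1 %; heteroplasmic
  means 1 % ≤ VAF < 99 %, homoplasmic VAF ≥ 99 %; exact-test strand-bias
  filtering; VCF 4.2 and counts-TSV I/O.
* **Annotation** in 1-based rCRS coordinates under the vertebrate
  mitochondrial code: per-locus synonymous/nonsynonymous consequences (both
  genes of MTATP8/MTATP6 and MTND4L/MTND4 overlaps, light-strand MTND6,
  incomplete stop codons completed with A's), transition/transversion class,
  low-complexity masking.
* **Sample QC**: ≥ 99 % of positions at ≥ 1500×; marker-panel haplogroup
  assignment and FC/SNpc concordance; a sequential exclusion ledger with
  conservation guarantees.
* **Burden statistics**: per-sample counts by tissue, locus, region class and
  variant type; Mann–Whitney U (exact, tie-aware, for n + m ≤ 20; tie-corrected
  normal approximation beyond), Fisher's exact test, Pearson's chi-squared and
  Bonferroni correction — all authored in-package and verified against
  enumeration oracles and base R as independent routes; Ti/Tv ratios; mean
  heteroplasmy; a pluggable pathogenicity scorer (BLOSUM62-based surrogate by
  default).
* **Somatic taxonomy** per pair, FC → SNpc: `de_novo` (SNpc only), `loss` (FC
  only), `positive_shift` / `negative_shift` (|ΔVAF| ≥ 1 point), with swap
  symmetry and partition invariants, and case/control rate comparisons.
* **Reference-set filter chain**: sequential pathogenic / species / marker /
  length / haplogroup filters with per-step ledgers, plus codon-usage
  percentage tables by consequence × codon position.
* **Synthetic paired-cohort generator**: Poisson variant counts, Beta VAFs
  concentrated below 10 %, case-weighted loci (MTCOX1/MTCOX2/MTCYTB),
  retention/shift/de-novo somatic dynamics, negative-binomial depths and a
  per-base error model, with truth tables so classifier agreement is exactly
  checkable.

See `vignettes/mthet-methods.Rmd` for the models, parameter meanings and
design decisions.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
full-scale cohort (97 case / 23 control pairs, seed 20160201, sequencing
error 10⁻³):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_qc.R
Rscript analysis/03_burden.R
Rscript analysis/04_somatic.R
Rscript analysis/05_codon_bias.R
```

which prints (abridged):

```
Simulated 240 samples from 120 pairs; 1749 true variants ( 581 FC heteroplasmies ), seed 20160201
Called 2682 variants across 240 samples; QC retained 120 pairs ( 97 cases / 23 controls ), 0 excluded
Heteroplasmic burden case vs control:
  FC    mean 4.75 vs 5.17, Mann-Whitney p = 0.317
  SNpc  mean 9.60 vs 7.70, Mann-Whitney p = 0.00376
Loci with Bonferroni-significant nonsynonymous-heteroplasmic excess: FC:MTCYTB, SNpc:MTCOX1, SNpc:MTCYTB
Differential variants: 902 ( de_novo 670, loss 142, positive_shift 50, negative_shift 40 )
  de_novo        case-elevated    p = 6.54e-08
  loss           case-elevated    p = 0.00465
Truth-label agreement: 898/903 (99.4%) at error rate 1e-3
Reference chain: 18114 records -> 9935 after four filters -> 7729 in major haplogroups
```

Reading this: the generator injects a higher de-novo rate and lower FC→SNpc
retention in cases, and the pipeline recovers both — SNpc heteroplasmic burden
is case-elevated (Mann–Whitney p ≈ 0.004) while FC shows no injected group
difference; the somatic classifier reproduces 99.4 % of the generator's truth
labels at a 10⁻³ per-base error rate (and 100 % at zero error, asserted in the
test suite); the case-weighted loci surface as the Bonferroni-significant
strata. Each stage writes tidy TSVs under `results/`.

A minimal interactive session:

```r
library(mthet)
map <- mt_locus_map()
annotate_variants(data.frame(position = 8701, ref = "A", alt = "G"), map)
#> 8701 A>G: MTATP6, coding, nonsynonymous, codon position 1, transition
fisher_exact_2x2(matrix(c(17, 253, 1, 46), 2, byrow = TRUE))
#> [1] 0.490526
```

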