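# Generative model for paired-tissue mtDNA cohorts.
#
# The generator emulates the statistical structure the analysis assumes:
# a germline homoplasmic backbone (haplogroup markers + private variants)
# shared by both tissues, low-level heteroplasmy (VAF mostly below 10%)
# arising in FC and propagating to SNpc through retention / shift /
# de-novo dynamics, case multipliers on nonsynonymous-prone loci, and a
# per-base sequencing error model on negative-binomial depths. True
# somatic class labels are assigned at generation time so classifier
# agreement is exactly assertable.

#' Simulation parameters for a paired-tissue cohort
#'
#' Defaults describe the full-scale study conditions: 97 case and 23
#' control pairs, ~5000x depth floored near the 1500x QC bound, Poisson
#' heteroplasmic variant counts with Beta-distributed VAFs concentrated
#' below 10%, case-elevated de-novo rates and case-depressed retention
#' (purifying loss), and a 3x case weight on the cytochrome-c-oxidase /
#' cytochrome-b loci.
#'
#' VAFs are truncated below at `vaf_min` (0.015) and shift magnitudes at
#' `shift_min` (0.015) so that, at the depth floor, rounding can never
#' move a true variant across the 1% calling bound or a true shift across
#' the 1-point dead band; this is what makes exact truth recovery at zero
#' sequencing error well-defined.
#'
#' @param n_case_pairs,n_control_pairs Pair counts (defaults 97 / 23).
#' @param depth_mean,depth_size,depth_floor Negative-binomial read depth
#'   (mean, size) with a hard floor (defaults 5000, 10, 1500).
#' @param haplogroup_freq Named sampling frequencies for the germline
#'   haplogroup backbone.
#' @param lambda_private Poisson mean of private germline homoplasmies.
#' @param lambda_het_fc Poisson mean of FC heteroplasmic variants per
#'   sample; a scalar applies to both statuses, or a named
#'   `c(case = , control = )` pair.
#' @param vaf_shape1,vaf_shape2,vaf_min Beta VAF model (defaults 1.2, 40,
#'   truncated at 0.015: mean ~0.03, overwhelmingly < 0.10).
#' @param dloop_weight Position-sampling weight multiplier for the control
#'   region (default 3; the D-loop is the fastest-evolving region).
#' @param case_loci,case_locus_multiplier Loci whose positions are
#'   upweighted in cases (default MTCOX1/MTCOX2/MTCYTB at 3x).
#' @param retention_prob Named (case/control) probability that an FC
#'   variant is still present in SNpc.
#' @param p_shift Probability a retained variant shifts (vs unchanged).
#' @param p_positive_shift Named probability a shift is positive.
#' @param shift_mean,shift_sd,shift_min Magnitude model for heteroplasmy
#'   shifts (absolute VAF).
#' @param lambda_dn Named Poisson mean of SNpc de-novo variants.
#' @param ti_prob Probability a simulated substitution is a transition
#'   (default 0.9, Ti/Tv expectation 9).
#' @param error_rate Per-base sequencing error rate (default 1e-3; 0 gives
#'   idealized counts `alt = round(vaf * depth)`).
#' @param n_background_sites Error-only reference positions emitted per
#'   sample when `error_rate > 0` (default 100).
#' @param p_discordant,p_coverage_fail Per-pair probabilities of a
#'   haplogroup-discordant SNpc label and of coverage QC failure
#'   (defaults 0).
#' @param seed Integer seed fixing the full output stream.
#' @return Object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_case_pairs = 97L, n_control_pairs = 23L,
                       depth_mean = 5000, depth_size = 10, depth_floor = 1500L,
                       haplogroup_freq = c(H = 0.44, U = 0.12, J = 0.10, T = 0.10,
                                           K = 0.08, V = 0.05, W = 0.04, X = 0.04, I = 0.03),
                       lambda_private = 3,
                       lambda_het_fc = 5,
                       vaf_shape1 = 1.2, vaf_shape2 = 40, vaf_min = 0.015,
                       dloop_weight = 3,
                       case_loci = c("MTCOX1", "MTCOX2", "MTCYTB"),
                       case_locus_multiplier = 3,
                       retention_prob = c(case = 0.70, control = 0.85),
                       p_shift = 0.35,
                       p_positive_shift = c(case = 0.30, control = 0.50),
                       shift_mean = 0.03, shift_sd = 0.015, shift_min = 0.015,
                       lambda_dn = c(case = 6, control = 3),
                       ti_prob = 0.9,
                       error_rate = 1e-3,
                       n_background_sites = 100L,
                       p_discordant = 0, p_coverage_fail = 0,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_case_pairs >= 0, p$n_control_pairs >= 0,
            p$vaf_shape1 > 0, p$vaf_shape2 > 0,
            all(p$retention_prob >= 0 & p$retention_prob <= 1),
            all(p$lambda_dn >= 0), p$lambda_het_fc >= 0, p$lambda_private >= 0)
  if (p$error_rate < 0 || p$error_rate >= 1) stop("parameter error: error_rate must be in [0, 1)")
  if (abs(sum(p$haplogroup_freq) - 1) > 1e-6) stop("parameter error: haplogroup_freq must sum to 1")
  if (length(p$lambda_het_fc) == 1L) {
    p$lambda_het_fc <- c(case = unname(p$lambda_het_fc), control = unname(p$lambda_het_fc))
  }
  structure(p, class = "sim_params")
}

.rdepth <- function(n, p) {
  pmax(p$depth_floor, rnbinom(n, size = p$depth_size, mu = p$depth_mean))
}

.rvaf <- function(n, p) {
  v <- rbeta(n, p$vaf_shape1, p$vaf_shape2)
  pmin(pmax(v, p$vaf_min), 0.95)
}

# position-sampling weights; cases upweight the configured loci
.position_weights <- function(map, p, status) {
  w <- rep(1, map$genome_length)
  dl <- map$loci[map$loci$name == "DLOOP", ]
  if (nrow(dl)) w[.in_interval(seq_len(map$genome_length), dl$start, dl$end)] <- p$dloop_weight
  if (status == "case") {
    for (loc in p$case_loci) {
      li <- map$loci[map$loci$name == loc, ]
      if (nrow(li)) w[li$start:li$end] <- w[li$start:li$end] * p$case_locus_multiplier
    }
  }
  w[map$low_complexity] <- 0  # masked tracts never harbor simulated variants
  w
}

.ralt <- function(ref, ti_prob) {
  ti <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  vapply(ref, function(r) {
    if (runif(1) < ti_prob) ti[[r]] else sample(tv[[r]], 1)
  }, character(1), USE.NAMES = FALSE)
}

# allele counts for one sample at its variant positions (+ background)
.emit_counts <- function(positions, refs, alts, vafs, p, map) {
  n <- length(positions)
  depth <- .rdepth(n, p)
  e <- p$error_rate
  if (e == 0) {
    # idealized, fully deterministic counts: exact truth recovery is assertable
    alt_reads <- as.integer(round(vafs * depth))
    alt_fwd <- alt_reads %/% 2L
    ref_reads <- depth - alt_reads
    ref_fwd <- ref_reads %/% 2L
  } else {
    alt_reads <- rbinom(n, depth, pmin(1, vafs * (1 - e) + e / 3))
    ref_reads <- depth - alt_reads
    alt_fwd <- rbinom(n, alt_reads, 0.5)
    ref_fwd <- rbinom(n, ref_reads, 0.5)
  }
  counts <- tibble::tibble(position = positions, ref = refs)
  for (b in .BASES) {
    counts[[paste0(b, "_fwd")]] <- 0L
    counts[[paste0(b, "_rev")]] <- 0L
  }
  for (i in seq_len(n)) {
    counts[[paste0(alts[i], "_fwd")]][i] <- alt_fwd[i]
    counts[[paste0(alts[i], "_rev")]][i] <- alt_reads[i] - alt_fwd[i]
    counts[[paste0(refs[i], "_fwd")]][i] <- counts[[paste0(refs[i], "_fwd")]][i] + ref_fwd[i]
    counts[[paste0(refs[i], "_rev")]][i] <- counts[[paste0(refs[i], "_rev")]][i] +
      ref_reads[i] - ref_fwd[i]
  }
  if (e > 0 && p$n_background_sites > 0) {
    bg <- sample(setdiff(seq_len(map$genome_length), positions), p$n_background_sites)
    counts <- dplyr::bind_rows(counts, simulate_error_counts(bg, map, p))
  }
  dplyr::arrange(counts, .data$position)
}

#' Error-only allele counts at reference positions
#'
#' Reads at each site are drawn at a negative-binomial depth; each
#' non-reference base receives `Binomial(depth, error_rate / 3)` error
#' reads, split evenly across strands. Used to study the caller's
#' false-positive behavior.
#'
#' @param positions rCRS positions (no true variant).
#' @param map An [mt_locus_map()] (reference bases).
#' @param params A [sim_params()] (depth model and error rate).
#' @return Allele-count tibble in the caller's input format.
#' @export
simulate_error_counts <- function(positions, map, params) {
  n <- length(positions)
  depth <- .rdepth(n, params)
  refs <- map$seq[positions]
  counts <- tibble::tibble(position = positions, ref = refs)
  for (b in .BASES) {
    counts[[paste0(b, "_fwd")]] <- 0L
    counts[[paste0(b, "_rev")]] <- 0L
  }
  err_total <- rep(0L, n)
  for (b in .BASES) {
    is_err <- refs != b
    e_reads <- integer(n)
    e_reads[is_err] <- rbinom(sum(is_err), depth[is_err], params$error_rate / 3)
    fwd <- rbinom(n, e_reads, 0.5)
    counts[[paste0(b, "_fwd")]] <- counts[[paste0(b, "_fwd")]] + fwd
    counts[[paste0(b, "_rev")]] <- counts[[paste0(b, "_rev")]] + (e_reads - fwd)
    err_total <- err_total + e_reads
  }
  ref_reads <- pmax(0L, depth - err_total)
  ref_fwd <- rbinom(n, ref_reads, 0.5)
  for (i in seq_len(n)) {
    counts[[paste0(refs[i], "_fwd")]][i] <- counts[[paste0(refs[i], "_fwd")]][i] + ref_fwd[i]
    counts[[paste0(refs[i], "_rev")]][i] <- counts[[paste0(refs[i], "_rev")]][i] +
      ref_reads[i] - ref_fwd[i]
  }
  counts
}

#' Simulate a paired-tissue cohort
#'
#' For each individual: a haplogroup backbone (panel markers + private
#' homoplasmies, shared by both tissues), FC heteroplasmic variants drawn
#' at weighted positions, propagated to SNpc via retention / shift /
#' de-novo rules, then per-sample allele counts drawn at sampled depths
#' with the error model. Truth tables record every true variant, its VAF
#' in both tissues, and its somatic class.
#'
#' @param params A [sim_params()].
#' @param map An [mt_locus_map()] (defaults to the bundled map).
#' @return List: `sample_sheet` (sample, individual, tissue, status, age,
#'   sex), `pairs` (individual, status, haplogroups), `counts` (named list
#'   of allele-count tibbles, one per sample), `truth` (individual,
#'   position, ref, alt, vaf_fc, vaf_snpc, class), `coverage_ok` (named
#'   logical by individual), `params`.
#' @export
simulate_cohort <- function(params, map = mt_locus_map()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  panel <- haplogroup_panel()
  n_tot <- params$n_case_pairs + params$n_control_pairs
  ids <- sprintf("P%03d", seq_len(n_tot))
  status <- rep(c("case", "control"), c(params$n_case_pairs, params$n_control_pairs))

  sheet <- list(); truth <- list(); counts <- list(); pair_rows <- list()
  coverage_ok <- setNames(rep(TRUE, n_tot), ids)

  for (i in seq_len(n_tot)) {
    id <- ids[i]; st <- status[i]
    hg <- sample(names(params$haplogroup_freq), 1, prob = params$haplogroup_freq)
    markers <- panel[panel$haplogroup == hg, , drop = FALSE]
    w <- .position_weights(map, params, st)

    # germline backbone: panel markers + private homoplasmies, VAF 1 in both
    n_priv <- rpois(1, params$lambda_private)
    used <- markers$position
    priv_pos <- sample(seq_len(map$genome_length), n_priv, prob = replace(w, used, 0))
    germ_pos <- c(markers$position, priv_pos)
    germ_alt <- c(markers$alt, .ralt(map$seq[priv_pos], params$ti_prob))

    # FC heteroplasmies
    n_fc <- rpois(1, params$lambda_het_fc[[st]])
    w2 <- replace(w, germ_pos, 0)
    fc_pos <- sample(seq_len(map$genome_length), n_fc, prob = w2)
    fc_alt <- .ralt(map$seq[fc_pos], params$ti_prob)
    fc_vaf <- .rvaf(n_fc, params)

    # propagate to SNpc
    retained <- runif(n_fc) < params$retention_prob[[st]]
    shifted <- retained & runif(n_fc) < params$p_shift
    sn_vaf <- ifelse(retained, fc_vaf, 0)
    if (any(shifted)) {
      mag <- pmax(params$shift_min, abs(rnorm(sum(shifted), params$shift_mean, params$shift_sd)))
      up <- runif(sum(shifted)) < params$p_positive_shift[[st]]
      delta <- ifelse(up, mag, -mag)
      nv <- fc_vaf[shifted] + delta
      # keep shifted variants present and the shift direction intact
      nv <- pmin(pmax(nv, params$vaf_min), 0.95)
      flip <- sign(nv - fc_vaf[shifted]) != sign(delta) | abs(nv - fc_vaf[shifted]) < params$shift_min
      nv[flip] <- fc_vaf[shifted][flip]  # degenerate clamp: revert to unchanged
      sn_vaf[shifted] <- nv
    }

    # de novo in SNpc
    n_dn <- rpois(1, params$lambda_dn[[st]])
    w3 <- replace(w2, fc_pos, 0)
    dn_pos <- sample(seq_len(map$genome_length), n_dn, prob = w3)
    dn_alt <- .ralt(map$seq[dn_pos], params$ti_prob)
    dn_vaf <- .rvaf(n_dn, params)

    all_pos <- c(germ_pos, fc_pos, dn_pos)
    all_ref <- map$seq[all_pos]
    all_alt <- c(germ_alt, fc_alt, dn_alt)
    vaf_fc <- c(rep(1, length(germ_pos)), fc_vaf, rep(0, n_dn))
    vaf_sn <- c(rep(1, length(germ_pos)), sn_vaf, dn_vaf)
    cls <- dplyr::case_when(
      vaf_fc >= 1 & vaf_sn >= 1 ~ "unchanged",
      vaf_fc == 0 & vaf_sn > 0 ~ "de_novo",
      vaf_fc > 0 & vaf_sn == 0 ~ "loss",
      vaf_sn - vaf_fc >= params$shift_min ~ "positive_shift",
      vaf_fc - vaf_sn >= params$shift_min ~ "negative_shift",
      TRUE ~ "unchanged"
    )
    truth[[i]] <- tibble::tibble(individual = id, position = all_pos, ref = all_ref,
                                 alt = all_alt, vaf_fc = vaf_fc, vaf_snpc = vaf_sn,
                                 class = cls)

    fc_present <- vaf_fc > 0
    sn_present <- vaf_sn > 0
    counts[[paste0(id, "_FC")]] <- .emit_counts(all_pos[fc_present], all_ref[fc_present],
                                                all_alt[fc_present], vaf_fc[fc_present],
                                                params, map)
    counts[[paste0(id, "_SNpc")]] <- .emit_counts(all_pos[sn_present], all_ref[sn_present],
                                                  all_alt[sn_present], vaf_sn[sn_present],
                                                  params, map)

    snpc_hg <- hg
    if (runif(1) < params$p_discordant) {
      snpc_hg <- sample(setdiff(names(params$haplogroup_freq), hg), 1)
    }
    if (runif(1) < params$p_coverage_fail) coverage_ok[id] <- FALSE
    pair_rows[[i]] <- tibble::tibble(individual = id, status = st,
                                     fc_haplogroup = hg, snpc_haplogroup = snpc_hg)
    age <- round(rnorm(1, 78, 6))
    sex <- sample(c("M", "F"), 1)
    sheet[[i]] <- tibble::tibble(sample = paste0(id, c("_FC", "_SNpc")),
                                 individual = id,
                                 tissue = c("FC", "SNpc"),
                                 status = st, age = age, sex = sex)
  }
  list(sample_sheet = dplyr::bind_rows(sheet),
       pairs = dplyr::bind_rows(pair_rows),
       counts = counts,
       truth = dplyr::bind_rows(truth),
       coverage_ok = coverage_ok,
       params = params)
}

#' Deterministic bookkeeping fixtures
#'
#' Builds cohort compositions whose category flags are disjoint, for
#' exercising the sequential QC and reference-filter ledgers at the
#' published scale.
#'
#' `"cohort_qc"`: 120 pairs (97 case, 23 control); 8 haplogroup-discordant
#' (6 case, 2 control) and 9 coverage-failed (7 case, 2 control), disjoint,
#' so sequential QC retains 103 individuals (84 cases, 19 controls).
#'
#' `"reference_chain"`: 18,114 records; 458 pathogenic carriers, 7
#' non-Homo-sapiens, 7,051 non-European marker carriers, 663 truncated
#' (< 16,500 bp), 2,206 survivors assigned non-major haplogroups and 7,729
#' assigned major haplogroups.
#'
#' @param kind `"cohort_qc"` or `"reference_chain"`.
#' @return For `"cohort_qc"`, list(`pairs`, `coverage_ok`); for
#'   `"reference_chain"`, a record tibble for
#'   [filter_reference_chain()].
#' @export
make_bookkeeping_fixture <- function(kind = c("cohort_qc", "reference_chain")) {
  kind <- match.arg(kind)
  if (kind == "cohort_qc") {
    ids <- sprintf("P%03d", 1:120)
    status <- rep(c("case", "control"), c(97, 23))
    fc_hg <- rep("H", 120)
    snpc_hg <- rep("H", 120)
    discordant <- c(ids[1:6], ids[98:99])     # 6 cases + 2 controls
    snpc_hg[ids %in% discordant] <- "J"
    cov_fail <- c(ids[7:13], ids[100:101])    # 7 cases + 2 controls, disjoint
    coverage_ok <- setNames(!(ids %in% cov_fail), ids)
    return(list(pairs = tibble::tibble(individual = ids, status = status,
                                       fc_haplogroup = fc_hg, snpc_haplogroup = snpc_hg),
                coverage_ok = coverage_ok))
  }
  n <- 18114L
  blocks <- c(pathogenic = 458L, non_homo = 7L, non_euro = 7051L,
              short = 663L, non_major = 2206L, major = 7729L)
  stopifnot(sum(blocks) == n)
  block <- rep(names(blocks), blocks)
  tibble::tibble(
    id = sprintf("R%05d", seq_len(n)),
    length = ifelse(block == "short", 16000L, 16569L),
    species = ifelse(block == "non_homo", "Pan troglodytes", "Homo sapiens"),
    carries_pathogenic = block == "pathogenic",
    marker_alleles = ifelse(block == "non_euro", "8701A", ""),
    haplogroup = dplyr::case_when(block == "non_major" ~ "L2", TRUE ~ "H")
  )
}
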