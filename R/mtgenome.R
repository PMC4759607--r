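# rCRS coordinate system, locus map and consequence annotation.
#
# All coordinates are 1-based inclusive rCRS (m.-notation); the control
# region (DLOOP) wraps the origin (16024 -> 576), handled by modular
# arithmetic on the genome length. The bundled sequence is a synthetic
# stand-in for NC_012920: real locus intervals, simulated bases (see
# ?mt_locus_map).

MT_GENOME_LENGTH <- 16569L

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# rCRS homopolymer (poly-C) tracts used as the default low-complexity mask
.DEFAULT_MASK_INTERVALS <- list(c(302L, 316L), c(513L, 526L), c(16181L, 16194L))

#' Build the mitochondrial locus map
#'
#' Loads the bundled rCRS locus intervals (gene symbols, strand, category,
#' reading-frame offset), the reference sequence, and the low-complexity
#' mask, and precomputes the per-position codon table used by
#' [annotate_variants()].
#'
#' The bundled sequence (`rcrs_synthetic.fasta`) is a synthetic stand-in for
#' NC_012920: the locus intervals are the true published rCRS coordinates,
#' but the bases are simulated (coding regions free of in-frame stops in
#' their own frame). Supply `fasta` to annotate against a real reference.
#'
#' @param loci Path to a locus TSV (columns `name`, `start`, `end`,
#'   `strand`, `category`, `frame_offset`). Default: bundled rCRS map.
#' @param fasta Path to the reference FASTA (single 16,569 nt record).
#' @param mask Low-complexity mask: `NULL` for the default rCRS poly-C
#'   tracts (m.302-316, m.513-526, m.16181-16194), an integer vector of
#'   positions, a path to a BED file (0-based half-open), or `integer(0)`
#'   for no mask.
#' @return An object of class `mt_locus_map`.
#' @export
mt_locus_map <- function(loci = NULL, fasta = NULL, mask = NULL) {
  if (is.null(loci)) loci <- system.file("extdata", "rcrs_loci.tsv", package = "mthet")
  if (is.null(fasta)) fasta <- system.file("extdata", "rcrs_synthetic.fasta", package = "mthet")
  tab <- readr::read_tsv(loci, show_col_types = FALSE)
  stopifnot(all(c("name", "start", "end", "strand", "category", "frame_offset") %in% names(tab)))
  dna <- Biostrings::readDNAStringSet(fasta)
  seqv <- strsplit(as.character(dna[[1]]), "")[[1]]
  if (length(seqv) != MT_GENOME_LENGTH) {
    stop("reference error: expected a ", MT_GENOME_LENGTH, " nt mtDNA sequence, got ", length(seqv))
  }
  if (is.null(mask)) {
    mask_pos <- unlist(lapply(.DEFAULT_MASK_INTERVALS, function(iv) seq(iv[1], iv[2])))
  } else if (is.character(mask)) {
    mask_pos <- read_mask_bed(mask)
  } else {
    mask_pos <- as.integer(mask)
  }
  map <- structure(
    list(
      loci = tab,
      genome_length = MT_GENOME_LENGTH,
      low_complexity = sort(unique(mask_pos)),
      seq = seqv
    ),
    class = "mt_locus_map"
  )
  map$codon_table <- .build_codon_table(map)
  map
}

#' @export
print.mt_locus_map <- function(x, ...) {
  cat("mt_locus_map:", nrow(x$loci), "loci over", x$genome_length, "bp;",
      length(x$low_complexity), "masked positions\n")
  invisible(x)
}

#' Read a BED mask into 1-based positions
#'
#' BED intervals are 0-based half-open; positions are converted to 1-based
#' inclusive rCRS coordinates.
#'
#' @param path BED file (chrom, start, end; further columns ignored).
#' @return Sorted integer vector of masked positions.
#' @export
read_mask_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("parse error: BED needs at least 3 columns")
  pos <- unlist(mapply(function(s, e) seq(s + 1L, e), as.integer(bed[[2]]), as.integer(bed[[3]]),
                       SIMPLIFY = FALSE))
  sort(unique(as.integer(pos)))
}

.check_positions <- function(position) {
  position <- as.integer(position)
  bad <- is.na(position) | position < 1L | position > MT_GENOME_LENGTH
  if (any(bad)) {
    stop("coordinate error: position(s) outside [1, ", MT_GENOME_LENGTH, "]: ",
         paste(utils::head(position[bad], 5), collapse = ", "))
  }
  position
}

# wrapped-interval membership: DLOOP has start > end; recycles over either
# a vector of positions or a vector of intervals
.in_interval <- function(position, start, end) {
  nowrap <- start <= end
  (nowrap & position >= start & position <= end) |
    (!nowrap & (position >= start | position <= end))
}

#' Loci overlapping a position
#'
#' Returns every locus whose (possibly origin-wrapping) interval contains
#' the position: overlapping gene pairs (MTATP8/MTATP6, MTND4L/MTND4) are
#' both returned, intergenic positions give zero rows.
#'
#' @param position A single rCRS position in 1..16569.
#' @param map An [mt_locus_map()].
#' @return Tibble of matching locus rows.
#' @export
locus_of <- function(position, map) {
  position <- .check_positions(position)
  stopifnot(length(position) == 1L)
  map$loci[.in_interval(position, map$loci$start, map$loci$end), ]
}

#' Low-complexity mask membership
#'
#' @param position Vector of rCRS positions.
#' @param map An [mt_locus_map()].
#' @return Logical vector: `TRUE` where the position is masked.
#' @export
in_low_complexity <- function(position, map) {
  .check_positions(position) %in% map$low_complexity
}

#' Transition or transversion
#'
#' A substitution is a transition iff both alleles are purines (A/G) or
#' both pyrimidines (C/T); the remaining 8 ordered pairs are transversions.
#'
#' @param ref,alt Single-base alleles (vectorized).
#' @return Character vector, `"transition"` or `"transversion"`.
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% .BASES & alt %in% .BASES & ref != alt
  if (!all(ok)) stop("allele error: non-ACGT or identical ref/alt allele")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}

#' Canonical locus symbol
#'
#' Maps common alias spellings (MT-CO1, MTCO1, COX1, MT-CYB, ...) onto the
#' symbols used in the bundled map (MTCOX1, MTCYTB, ...).
#'
#' @param x Character vector of locus symbols.
#' @return Canonical symbols; unrecognized input is returned unchanged.
#' @export
normalize_locus <- function(x) {
  key <- toupper(gsub("[-_]", "", x))
  key <- sub("^(?!MT)", "MT", key, perl = TRUE)
  alias <- c(MTCO1 = "MTCOX1", MTCO2 = "MTCOX2", MTCO3 = "MTCOX3",
             MTCOX1 = "MTCOX1", MTCOX2 = "MTCOX2", MTCOX3 = "MTCOX3",
             MTCYB = "MTCYTB", MTCYTB = "MTCYTB", MTDLOOP = "DLOOP",
             MTDN4 = "MTND4")
  out <- ifelse(key %in% names(alias), alias[key], key)
  unname(out)
}

# Per-position codon context for every coding locus. Incomplete terminal
# codons (1-2 nt genes ending short of a full stop) are completed with A's,
# mirroring mRNA polyadenylation. Light-strand genes (MTND6) are read off
# the reverse complement, codon 1 starting at the high genomic coordinate.
.build_codon_table <- function(map) {
  coding <- map$loci[map$loci$category == "coding", ]
  out <- vector("list", nrow(coding))
  for (g in seq_len(nrow(coding))) {
    st <- coding$start[g]; en <- coding$end[g]
    strand <- coding$strand[g]
    len <- en - st + 1L
    n_codon <- ceiling(len / 3)
    if (strand == "heavy") gpos <- st:en else gpos <- en:st
    cds <- map$seq[gpos]
    if (strand == "light") cds <- unname(.COMP[cds])
    pad <- n_codon * 3L - len
    cds_pad <- c(cds, rep("A", pad))
    codon_id <- rep(seq_len(n_codon), each = 3L)[seq_len(len)]
    codon_pos <- rep(1:3, n_codon)[seq_len(len)]
    codons <- vapply(seq_len(n_codon), function(k) {
      paste(cds_pad[(3L * k - 2L):(3L * k)], collapse = "")
    }, character(1))
    out[[g]] <- tibble::tibble(
      position = gpos,
      locus = coding$name[g],
      strand = strand,
      codon_id = codon_id,
      codon_position = codon_pos,
      codon = codons[codon_id]
    )
  }
  dplyr::bind_rows(out)
}

.genetic_code <- function() {
  gc <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  setNames(as.character(gc), names(gc))
}

#' Annotate substitutions against the locus map
#'
#' For each variant, every overlapping locus is annotated independently:
#' coding hits get the codon position, reference and alternate amino acids
#' under the vertebrate mitochondrial genetic code (light-strand genes are
#' translated from the reverse complement; incomplete terminal codons are
#' completed with A's) and a synonymous/nonsynonymous consequence;
#' non-coding categories get `consequence = "noncoding"`. A variant hitting
#' no locus yields one `"intergenic"` row.
#'
#' @param variants Data frame with columns `position`, `ref`, `alt`
#'   (single-base alleles; `ref` must match the map's reference base).
#' @param map An [mt_locus_map()].
#' @return Tibble with one row per (variant, locus): `position`, `ref`,
#'   `alt`, `locus`, `category`, `consequence`, `codon_position`, `ref_aa`,
#'   `alt_aa`, `substitution_class`.
#' @export
annotate_variants <- function(variants, map) {
  stopifnot(all(c("position", "ref", "alt") %in% names(variants)))
  v <- tibble::as_tibble(variants[, c("position", "ref", "alt")])
  v$position <- .check_positions(v$position)
  v$ref <- toupper(v$ref); v$alt <- toupper(v$alt)
  if (!all(v$ref %in% .BASES & v$alt %in% .BASES)) {
    stop("allele error: alleles must be single A/C/G/T bases")
  }
  mism <- v$ref != map$seq[v$position]
  if (any(mism)) {
    stop("reference error: ref allele does not match the reference base at position(s) ",
         paste(utils::head(v$position[mism], 5), collapse = ", "))
  }
  v$substitution_class <- substitution_class(v$ref, v$alt)

  # which loci does each variant hit
  hits <- lapply(seq_len(nrow(map$loci)), function(i) {
    sel <- .in_interval(v$position, map$loci$start[i], map$loci$end[i])
    if (!any(sel)) return(NULL)
    cbind(v[sel, , drop = FALSE],
          locus = map$loci$name[i], category = map$loci$category[i])
  })
  hits <- dplyr::bind_rows(hits)
  n_hit <- if (nrow(hits)) table(factor(hits$position, levels = unique(v$position))) else NULL
  orphan <- v[!v$position %in% hits$position, , drop = FALSE]
  if (nrow(orphan)) {
    orphan$locus <- NA_character_
    orphan$category <- "intergenic"
    hits <- dplyr::bind_rows(hits, orphan)
  }

  gc2 <- .genetic_code()
  cod <- map$codon_table
  key_map <- paste(cod$position, cod$locus)
  idx <- match(paste(hits$position, hits$locus), key_map)
  hits$codon_position <- cod$codon_position[idx]
  coding_row <- !is.na(idx)
  hits$ref_aa <- NA_character_
  hits$alt_aa <- NA_character_
  hits$consequence <- "noncoding"
  if (any(coding_row)) {
    ci <- idx[coding_row]
    codon <- cod$codon[ci]
    cpos <- cod$codon_position[ci]
    alt_in_codon <- ifelse(cod$strand[ci] == "light",
                           unname(.COMP[hits$alt[coding_row]]),
                           hits$alt[coding_row])
    alt_codon <- codon
    substr(alt_codon, cpos, cpos) <- alt_in_codon
    hits$ref_aa[coding_row] <- unname(gc2[codon])
    hits$alt_aa[coding_row] <- unname(gc2[alt_codon])
    hits$consequence[coding_row] <- ifelse(
      hits$ref_aa[coding_row] == hits$alt_aa[coding_row], "synonymous", "nonsynonymous")
  }
  tibble::as_tibble(hits[, c("position", "ref", "alt", "locus", "category", "consequence",
                             "codon_position", "ref_aa", "alt_aa", "substitution_class")])
}

# priority when collapsing a variant's locus hits to one region class
.REGION_PRIORITY <- c("coding", "rRNA", "tRNA", "DLOOP", "intergenic")

#' Attach collapsed annotation columns to a call table
#'
#' Convenience wrapper around [annotate_variants()] that collapses the
#' per-locus rows to one row per call: `loci` (comma-joined symbols),
#' `region_class` (highest-priority category hit: coding > rRNA > tRNA >
#' DLOOP > intergenic), `consequence` (nonsynonymous if any coding hit is),
#' and `substitution_class`. Burden analyses that need per-locus rows use
#' [annotate_variants()] directly.
#'
#' @param calls Data frame with `position`, `ref`, `alt` (other columns kept).
#' @param map An [mt_locus_map()].
#' @return `calls` with annotation columns appended.
#' @export
annotate_calls <- function(calls, map) {
  if (!nrow(calls)) {
    calls$loci <- character(0); calls$region_class <- character(0)
    calls$consequence <- character(0); calls$substitution_class <- character(0)
    return(tibble::as_tibble(calls))
  }
  uv <- dplyr::distinct(tibble::as_tibble(calls[, c("position", "ref", "alt")]))
  ann <- annotate_variants(uv, map)
  coll <- ann %>%
    dplyr::group_by(.data$position, .data$ref, .data$alt) %>%
    dplyr::summarise(
      loci = paste(stats::na.omit(.data$locus), collapse = ","),
      region_class = .REGION_PRIORITY[min(match(.data$category, .REGION_PRIORITY))],
      consequence = if (any(.data$consequence == "nonsynonymous")) "nonsynonymous"
                    else if (any(.data$consequence == "synonymous")) "synonymous"
                    else "noncoding",
      substitution_class = .data$substitution_class[1],
      .groups = "drop"
    )
  out <- dplyr::left_join(tibble::as_tibble(calls), coll, by = c("position", "ref", "alt"))
  out
}

#' Drop calls in low-complexity regions
#'
#' Comparative analyses exclude variants in the masked homopolymer tracts.
#'
#' @param calls Data frame with a `position` column.
#' @param map An [mt_locus_map()].
#' @return `calls` without masked positions.
#' @export
filter_masked <- function(calls, map) {
  if (!nrow(calls)) return(calls)
  calls[!in_low_complexity(calls$position, map), , drop = FALSE]
}
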