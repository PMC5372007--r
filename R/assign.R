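# --- read-to-genotype assignment -------------------------------------------
#
# Instead of enumerating all 2^y haplotypes and mapping reads against them,
# reads are assigned directly: the read and the consensus are walked in
# lockstep, branching only at polymorphic sites, where the read must carry
# either the reference or the alternate allele verbatim. A read is assigned
# iff exactly one bitmask explains it as a character-perfect, gap-free,
# full-length haplotype. The brute-force enumerate-then-exact-match mirror
# (`assign_reads_bruteforce()`) is kept as an independent oracle and the two
# are proven equivalent by property tests.
#
# Rejection reasons are a function of (number of exact haplotype matches,
# read length) only, so both routes classify identically:
#   >= 2 matches                          -> ambiguous
#   no match, length not achievable       -> length_mismatch
#   no match, achievable length != consensus length -> gapped_or_indel_mismatch
#   no match, length == consensus length  -> allele_mismatch

REJECTION_REASONS <- c("gapped_or_indel_mismatch", "allele_mismatch",
                       "length_mismatch", "ambiguous")

# precompute everything the per-read walk needs
prep_region_for_assignment <- function(region, config = pipeline_config()) {
  y <- check_enumeration_guard(region, config)
  polys <- region$polymorphisms
  S <- region$consensus_seq
  L <- nchar(S)
  p <- polys$local_pos
  rl <- nchar(polys$ref_allele)
  al <- nchar(polys$alt_allele)
  if (y > 1 && any(p[-1] <= (p + rl - 1L)[-y])) {
    abort("assignment requires non-overlapping polymorphism reference spans")
  }
  pe <- c(0L, p + rl - 1L) # pe[i] = last consensus position consumed before poly i
  segs <- character(y + 1L)
  for (i in seq_len(y)) segs[i] <- substr(S, pe[i] + 1L, p[i] - 1L)
  segs[y + 1L] <- substr(S, pe[y + 1L] + 1L, L)
  deltas <- al - rl
  feasible <- 0L
  for (d in deltas) feasible <- unique(c(feasible, feasible + d))
  list(
    y = y, L = L, p = p, rl = rl, al = al,
    refs = polys$ref_allele, alts = polys$alt_allele,
    segs = segs, pe = pe, bitval = if (y > 0) 2^(seq_len(y) - 1) else numeric(0),
    feasible_lengths = sort(L + feasible),
    has_indel = any(deltas != 0)
  )
}

# depth-first walk; returns the (up to 2) bitmasks that fully explain `s`
match_bitmasks <- function(s, prep) {
  n <- nchar(s)
  found <- numeric(0)
  rec <- function(i, delta, mask) {
    if (length(found) >= 2L) return(invisible(NULL))
    if (i > prep$y) {
      if (n != prep$L + delta) return(invisible(NULL))
      a <- prep$pe[prep$y + 1L] + 1L + delta
      if (substr(s, a, n) == prep$segs[prep$y + 1L]) found <<- c(found, mask)
      return(invisible(NULL))
    }
    seg <- prep$segs[i]
    if (nzchar(seg)) {
      a <- prep$pe[i] + 1L + delta
      if (substr(s, a, a + nchar(seg) - 1L) != seg) return(invisible(NULL))
    }
    pos <- prep$p[i] + delta
    if (substr(s, pos, pos + prep$rl[i] - 1L) == prep$refs[i]) {
      rec(i + 1L, delta, mask)
    }
    if (substr(s, pos, pos + prep$al[i] - 1L) == prep$alts[i]) {
      rec(i + 1L, delta + prep$al[i] - prep$rl[i], mask + prep$bitval[i])
    }
    invisible(NULL)
  }
  rec(1L, 0L, 0)
  found
}

classify_outcome <- function(n_matches, read_length, feasible_lengths,
                             consensus_length) {
  if (n_matches == 1L) return(c("assigned", NA_character_))
  if (n_matches >= 2L) return(c("rejected", "ambiguous"))
  if (!(read_length %in% feasible_lengths)) return(c("rejected", "length_mismatch"))
  if (read_length != consensus_length) return(c("rejected", "gapped_or_indel_mismatch"))
  c("rejected", "allele_mismatch")
}

#' Assign one read sequence to a genotype bitmask
#'
#' @param sequence A single read sequence, already trimmed to the barcode
#'   span.
#' @param region A [barcode_region()].
#' @param config A [pipeline_config()]; supplies the y guard.
#' @return A one-row tibble with `outcome` (`"assigned"`/`"rejected"`),
#'   `bitmask` (NA when rejected) and `reason` (NA when assigned; otherwise
#'   one of `"gapped_or_indel_mismatch"`, `"allele_mismatch"`,
#'   `"length_mismatch"`, `"ambiguous"`).
#' @export
assign_read <- function(sequence, region, config = pipeline_config()) {
  out <- assign_reads(tibble(read_id = "read", sequence = sequence),
                      region, config = config)
  dplyr::select(out, -"read_id")
}

#' Assign amplicon reads to genotype bitmasks
#'
#' Direct, indel-aware assignment of each read to the unique genotype whose
#' haplotype sequence it matches perfectly (see the package vignette for the
#' walk and for the rejection-reason taxonomy). Identical read sequences are
#' assigned once and the result broadcast, so error-free deep-coverage data
#' costs one walk per distinct sequence.
#'
#' @param reads Tibble with `read_id` and `sequence` (quality columns are
#'   carried along untouched).
#' @param region A [barcode_region()].
#' @param config A [pipeline_config()]; supplies the y guard.
#' @return `reads` with added `outcome`, `bitmask`, `reason` columns.
#' @export
assign_reads <- function(reads, region, config = pipeline_config()) {
  prep <- prep_region_for_assignment(region, config)
  uniq <- unique(reads$sequence)
  res <- matrix(NA_character_, nrow = length(uniq), ncol = 2)
  masks <- rep(NA_real_, length(uniq))
  for (k in seq_along(uniq)) {
    hits <- match_bitmasks(uniq[k], prep)
    res[k, ] <- classify_outcome(length(hits), nchar(uniq[k]),
                                 prep$feasible_lengths, prep$L)
    if (length(hits) == 1L) masks[k] <- hits
  }
  i <- match(reads$sequence, uniq)
  out <- reads
  out$outcome <- res[i, 1]
  out$bitmask <- masks[i]
  out$reason <- res[i, 2]
  out
}

#' Assign reads by brute-force comparison against an enumerated database
#'
#' The oracle mirror of [assign_reads()]: every read is compared, as an
#' exact string, against every enumerated haplotype record. Practical only
#' for small y, and used to validate the direct assigner.
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param database Tibble from [enumerate_haplotypes()] (`bitmask`,
#'   `sequence`).
#' @param consensus_length Length of the region consensus, used only to
#'   separate the rejection flavours.
#' @return Same contract as [assign_reads()].
#' @export
assign_reads_bruteforce <- function(reads, database, consensus_length) {
  feasible <- sort(unique(nchar(database$sequence)))
  uniq <- unique(reads$sequence)
  res <- matrix(NA_character_, nrow = length(uniq), ncol = 2)
  masks <- rep(NA_real_, length(uniq))
  for (k in seq_along(uniq)) {
    hits <- database$bitmask[database$sequence == uniq[k]]
    res[k, ] <- classify_outcome(length(hits), nchar(uniq[k]),
                                 feasible, consensus_length)
    if (length(hits) == 1L) masks[k] <- hits
  }
  i <- match(reads$sequence, uniq)
  out <- reads
  out$outcome <- res[i, 1]
  out$bitmask <- masks[i]
  out$reason <- res[i, 2]
  out
}
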