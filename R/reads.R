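#' Quality-filter amplicon reads
#'
#' Retains reads whose mean Phred quality is at least
#' `config$min_read_quality` and which contain no ambiguous base (N). Input
#' order is preserved and the retained/removed counts are reported as a
#' message.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (Phred+33
#'   string, same length as the sequence).
#' @param config A [pipeline_config()].
#' @return The retained subset of `reads`.
#' @export
quality_filter <- function(reads, config = pipeline_config()) {
  if (nrow(reads) == 0L) return(reads)
  bad_len <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad_len)) {
    abort(sprintf(
      "read '%s': sequence and quality strings differ in length",
      reads$read_id[which(bad_len)[1]]
    ))
  }
  keep <- mean_phred(reads$quality) >= config$min_read_quality &
    !grepl("N", reads$sequence, fixed = TRUE)
  inform(sprintf("quality_filter: retained %d of %d reads (removed %d)",
                 sum(keep), length(keep), sum(!keep)))
  reads[keep, , drop = FALSE]
}

# first match start/end of `primer` in each sequence, exact first then
# allowing up to `max_mismatch`; NA where absent
locate_primer <- function(primer, sequences, max_mismatch = 1L) {
  subj <- Biostrings::DNAStringSet(sequences)
  hit_end <- rep(NA_integer_, length(sequences))
  for (mm in 0:max_mismatch) {
    todo <- which(is.na(hit_end))
    if (length(todo) == 0L) break
    m <- Biostrings::vmatchPattern(primer, subj[todo], max.mismatch = mm)
    starts <- Biostrings::startIndex(m)
    ends <- Biostrings::endIndex(m)
    got <- lengths(starts) > 0
    hit_end[todo[got]] <- vapply(ends[got], function(e) e[[1]], integer(1))
  }
  hit_end
}

#' Trim reads to the expected amplicon span
#'
#' Orients each read (forward, or reverse-complemented when the forward
#' primer is only found on the reverse strand), locates the forward primer
#' at the 5' end — exact match first, then allowing one mismatch — removes
#' the primer and any upstream bases, optionally cuts at the reverse
#' primer's complement, and truncates to `expected_length`. Reads in which
#' the forward primer cannot be found are dropped, with counts reported as
#' a message.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param forward_primer,reverse_primer Primer sequences, 5'->3' on their
#'   respective strands; `reverse_primer` may be `NULL`.
#' @param expected_length Expected amplicon insert size in bp (e.g. 365 or
#'   325).
#' @param max_mismatch Mismatches tolerated in the primer search after an
#'   exact pass.
#' @return The trimmed subset of `reads` (sequences of length at most
#'   `expected_length`).
#' @export
trim_to_amplicon <- function(reads, forward_primer, reverse_primer = NULL,
                             expected_length, max_mismatch = 1L) {
  check_dna(forward_primer, "forward_primer")
  if (!is.null(reverse_primer)) check_dna(reverse_primer, "reverse_primer")
  if (!is_scalar_number(expected_length) || expected_length < 1) {
    abort("`expected_length` must be a positive number")
  }
  if (!is.null(reverse_primer) &&
      expected_length < nchar(forward_primer) + nchar(reverse_primer)) {
    abort("`expected_length` is shorter than the two primers combined")
  }
  if (nrow(reads) == 0L) return(reads)

  fwd_end <- locate_primer(forward_primer, reads$sequence, max_mismatch)
  miss <- is.na(fwd_end)
  rc_end <- rep(NA_integer_, nrow(reads))
  if (any(miss)) {
    rc_end[miss] <- locate_primer(forward_primer, revcomp(reads$sequence[miss]),
                                  max_mismatch)
  }
  use_rc <- is.na(fwd_end) & !is.na(rc_end)
  keep <- !is.na(fwd_end) | use_rc
  inform(sprintf(
    "trim_to_amplicon: primer found in %d of %d reads (dropped %d without a recognisable forward primer)",
    sum(keep), nrow(reads), sum(!keep)
  ))
  out <- reads[keep, , drop = FALSE]
  seqs <- out$sequence
  quals <- out$quality
  flip <- use_rc[keep]
  if (any(flip)) {
    seqs[flip] <- revcomp(seqs[flip])
    quals[flip] <- vapply(quals[flip], function(q) {
      intToUtf8(rev(utf8ToInt(q)))
    }, character(1), USE.NAMES = FALSE)
  }
  from <- ifelse(flip, rc_end[keep], fwd_end[keep]) + 1L
  seqs <- substr(seqs, from, nchar(seqs))
  quals <- substr(quals, from, nchar(quals))
  if (!is.null(reverse_primer)) {
    # locate_primer() reports the match end; back out the match start
    rp_end <- locate_primer(revcomp(reverse_primer), seqs, max_mismatch)
    rp_from <- rp_end - nchar(reverse_primer) + 1L
    has <- !is.na(rp_from) & rp_from >= 1
    seqs[has] <- substr(seqs[has], 1L, rp_from[has] - 1L)
    quals[has] <- substr(quals[has], 1L, rp_from[has] - 1L)
  }
  seqs <- substr(seqs, 1L, expected_length)
  quals <- substr(quals, 1L, expected_length)
  out$sequence <- seqs
  out$quality <- quals
  out
}
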