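#' Classify a variant as substitution, insertion or deletion
#'
#' Classification follows the VCF allele-length rule for anchored biallelic
#' records: equal allele lengths are substitutions, a longer alternate is an
#' insertion, a shorter alternate is a deletion.
#'
#' @param ref_allele,alt_allele Uppercase nucleotide strings (A/C/G/T only,
#'   length >= 1). Vectorised.
#' @return Character vector over `"substitution"`, `"insertion"`,
#'   `"deletion"`.
#' @examples
#' classify_variant("T", "A")
#' classify_variant(c("A", "AT"), c("AT", "A"))
#' @export
classify_variant <- function(ref_allele, alt_allele) {
  check_dna(ref_allele, "ref_allele")
  check_dna(alt_allele, "alt_allele")
  dplyr::case_when(
    nchar(alt_allele) == nchar(ref_allele) ~ "substitution",
    nchar(alt_allele) > nchar(ref_allele) ~ "insertion",
    TRUE ~ "deletion"
  )
}

#' Hard-filter and classify raw variant records
#'
#' Applies the pipeline's hard filters to raw variant records: sites must
#' have genotype quality >= `min_genotype_quality` and depth >=
#' `min_site_depth`. Surviving records are classified by
#' [classify_variant()] and, when a consensus is supplied, validated against
#' it: a reference allele that does not match the consensus at its position
#' is an error, never a silent drop.
#'
#' @param records Tibble of raw variant records as returned by
#'   [read_vcf_variants()] (columns `contig`, `position`, `ref_allele`,
#'   `alt_allele`, `genotype_quality`, `depth`; a `record` column, if
#'   present, is used in error messages).
#' @param config A [pipeline_config()].
#' @param consensus Optional named character vector of contig sequences (or
#'   a single unnamed sequence) for reference-allele validation.
#' @return A tibble of polymorphisms sorted by (contig, position,
#'   ref_allele, alt_allele) with an added `kind` column.
#' @export
filter_variants <- function(records, config = pipeline_config(),
                            consensus = NULL) {
  required <- c("contig", "position", "ref_allele", "alt_allele",
                "genotype_quality", "depth")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("`records` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0L) {
    return(mutate(records, kind = character(0)))
  }
  rec_id <- if ("record" %in% names(records)) records$record else seq_len(nrow(records))
  bad <- !grepl("^[ACGT]+$", records$ref_allele) |
    !grepl("^[ACGT]+$", records$alt_allele)
  if (any(bad)) {
    abort(sprintf(
      "malformed variant record %s: alleles must be non-empty A/C/G/T strings",
      paste(rec_id[bad][seq_len(min(3, sum(bad)))], collapse = ", ")
    ))
  }
  if (anyNA(records$genotype_quality) || anyNA(records$depth)) {
    i <- which(is.na(records$genotype_quality) | is.na(records$depth))[1]
    abort(sprintf("variant record %s lacks GQ/DP annotations", rec_id[i]))
  }
  if (!is.null(consensus)) {
    validate_ref_alleles(records, consensus)
  }
  out <- records[records$genotype_quality >= config$min_genotype_quality &
                   records$depth >= config$min_site_depth, , drop = FALSE]
  out$kind <- classify_variant(out$ref_allele, out$alt_allele)
  arrange(as_tibble(out), .data$contig, .data$position, .data$ref_allele,
          .data$alt_allele)
}

validate_ref_alleles <- function(records, consensus) {
  if (is.null(names(consensus)) && length(consensus) == 1L) {
    names(consensus) <- unique(records$contig)[1]
  }
  for (i in seq_len(nrow(records))) {
    ctg <- records$contig[i]
    seq <- consensus[[ctg]]
    if (is.null(seq) || is.na(seq)) {
      abort(sprintf("no consensus sequence supplied for contig '%s'", ctg))
    }
    ref <- records$ref_allele[i]
    span <- substr(seq, records$position[i],
                   records$position[i] + nchar(ref) - 1L)
    if (!identical(span, ref)) {
      abort(sprintf(
        "ref allele mismatch at %s:%d: VCF says '%s' but consensus has '%s'",
        ctg, records$position[i], ref, span
      ))
    }
  }
  invisible(records)
}

#' Rank candidate barcode windows by polymorphism density
#'
#' Slides a window of `window_length` bp along the consensus and counts, for
#' every start position, the polymorphisms whose full reference-allele span
#' lies inside the window. Windows overlapping an excluded interval (e.g.
#' homologous-repeat or other unsuitable regions, supplied as 1-based closed
#' intervals or read from BED via [read_excluded_bed()]) are removed.
#'
#' @param polymorphisms Tibble of (filtered) polymorphisms with `position`
#'   and `ref_allele`.
#' @param consensus_length Length of the consensus sequence in bp.
#' @param window_length Window span in bp (e.g. 325 or 365).
#' @param excluded_intervals Optional tibble with `start`, `end` (1-based
#'   closed) intervals to avoid.
#' @return A tibble with `window_start`, `window_end`, `n_polymorphisms`,
#'   sorted by descending count then ascending start.
#' @export
scan_barcode_windows <- function(polymorphisms, consensus_length,
                                 window_length,
                                 excluded_intervals = NULL) {
  if (!is_scalar_number(window_length) || window_length <= 0) {
    abort("`window_length` must be a positive number")
  }
  if (window_length > consensus_length) {
    abort("`window_length` exceeds the consensus length")
  }
  n_windows <- as.integer(consensus_length - window_length + 1L)
  acc <- integer(n_windows + 1L)
  if (nrow(polymorphisms) > 0) {
    span_end <- polymorphisms$position + nchar(polymorphisms$ref_allele) - 1L
    lo <- pmax(1L, span_end - as.integer(window_length) + 1L)
    hi <- pmin(polymorphisms$position, n_windows)
    ok <- lo <= hi & span_end - polymorphisms$position + 1L <= window_length
    for (i in which(ok)) {
      acc[lo[i]] <- acc[lo[i]] + 1L
      acc[hi[i] + 1L] <- acc[hi[i] + 1L] - 1L
    }
  }
  counts <- cumsum(acc[seq_len(n_windows)])
  keep <- rep(TRUE, n_windows)
  if (!is.null(excluded_intervals) && nrow(excluded_intervals) > 0) {
    for (i in seq_len(nrow(excluded_intervals))) {
      a <- excluded_intervals$start[i]
      b <- excluded_intervals$end[i]
      # window [s, s+w-1] overlaps [a, b]  <=>  s in [a-w+1, b]
      lo <- max(1L, as.integer(a - window_length + 1L))
      hi <- min(n_windows, as.integer(b))
      if (lo <= hi) keep[lo:hi] <- FALSE
    }
  }
  out <- tibble(
    window_start = seq_len(n_windows)[keep],
    window_end = seq_len(n_windows)[keep] + as.integer(window_length) - 1L,
    n_polymorphisms = counts[keep]
  )
  arrange(out, desc(.data$n_polymorphisms), .data$window_start)
}
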