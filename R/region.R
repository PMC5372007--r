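#' Define a barcode region
#'
#' A barcode region is a short consensus subsequence (typically well under
#' 400 bp, less than one sequencing read) together with the y polymorphisms
#' it carries. Polymorphisms are ordered by ascending position, ties broken
#' by ref then alt allele, and given 0-based indices 0..y-1; index i is bit
#' i of every genotype bitmask derived from the region.
#'
#' @param consensus Full contig sequence (single uppercase string, as from
#'   [read_consensus_fasta()]).
#' @param polymorphisms Tibble of filtered polymorphisms (from
#'   [filter_variants()]); only rows on `contig` whose ref span lies within
#'   `[start, end]` are expected — rows outside are an error, since a
#'   barcode's polymorphism set must be exactly what the caller filtered.
#' @param start,end 1-based inclusive contig coordinates of the region.
#' @param label Region label used in genotype names (e.g. an ORF name).
#' @param contig Contig identifier; defaults to the consensus name or the
#'   polymorphisms' single contig.
#' @return An object of class `barcode_region`.
#' @examples
#' region <- barcode_region(
#'   consensus = "ACGTACGTACGT",
#'   polymorphisms = tibble::tibble(
#'     contig = "chr", position = 5L, ref_allele = "A", alt_allele = "G",
#'     genotype_quality = 99, depth = 100, kind = "substitution"
#'   ),
#'   start = 1, end = 12, label = "demo", contig = "chr"
#' )
#' region
#' @export
barcode_region <- function(consensus, polymorphisms, start, end,
                           label = "region", contig = NULL) {
  if (is.null(contig)) {
    contig <- names(consensus) %||%
      (if (nrow(polymorphisms) > 0) unique(polymorphisms$contig)[1] else "contig")
  }
  consensus <- unname(consensus)
  if (!is_scalar_number(start) || !is_scalar_number(end) ||
      start < 1 || end > nchar(consensus) || start > end) {
    abort("`start`/`end` must satisfy 1 <= start <= end <= nchar(consensus)")
  }
  start <- as.integer(start)
  end <- as.integer(end)
  polys <- as_tibble(polymorphisms)
  if (nrow(polys) > 0) {
    if (!all(polys$contig == contig)) {
      abort("all polymorphisms must lie on the region's contig")
    }
    span_end <- polys$position + nchar(polys$ref_allele) - 1L
    outside <- polys$position < start | span_end > end
    if (any(outside)) {
      abort(sprintf(
        "polymorphism ref span at position %d extends outside [%d, %d]",
        polys$position[which(outside)[1]], start, end
      ))
    }
  }
  if (!("kind" %in% names(polys))) {
    polys$kind <- if (nrow(polys)) classify_variant(polys$ref_allele, polys$alt_allele) else character(0)
  }
  polys <- arrange(polys, .data$position, .data$ref_allele, .data$alt_allele)
  polys$index <- seq_len(nrow(polys)) - 1L
  polys$local_pos <- polys$position - start + 1L
  region <- structure(
    list(
      label = label,
      contig = contig,
      start = start,
      end = end,
      consensus_seq = substr(consensus, start, end),
      polymorphisms = polys
    ),
    class = "barcode_region"
  )
  # ref-allele validation against the extracted subsequence
  if (nrow(polys) > 0) {
    local <- polys
    local$contig <- contig
    local$position <- local$local_pos
    validate_ref_alleles(local, setNames(region$consensus_seq, contig))
  }
  region
}

#' Number of polymorphisms in a barcode region
#' @param region A `barcode_region`.
#' @return Integer y.
#' @export
n_polymorphisms <- function(region) {
  nrow(region$polymorphisms)
}

#' @export
print.barcode_region <- function(x, ...) {
  y <- n_polymorphisms(x)
  cat(sprintf(
    "<barcode_region> %s  %s:%d-%d (%d bp), y = %d polymorphism(s), %s genotypes\n",
    x$label, x$contig, x$start, x$end, nchar(x$consensus_seq), y,
    format_mask(2^y)
  ))
  if (y > 0) {
    tab <- table(x$polymorphisms$kind)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a barcode region into its polymorphism table
#'
#' @param x A `barcode_region`.
#' @param ... Unused.
#' @return A tibble with one row per polymorphism (index, position,
#'   local_pos, alleles, kind, quality annotations).
#' @method tidy barcode_region
#' @export
tidy.barcode_region <- function(x, ...) {
  dplyr::relocate(x$polymorphisms, "index", "position", "local_pos",
                  "ref_allele", "alt_allele", "kind")
}

#' One-row summary of a barcode region
#'
#' @param x A `barcode_region`.
#' @param ... Unused.
#' @return A tibble with label, span, length, y and the 2^y genotype count.
#' @method glance barcode_region
#' @export
glance.barcode_region <- function(x, ...) {
  y <- n_polymorphisms(x)
  tibble(
    label = x$label, contig = x$contig, start = x$start, end = x$end,
    length = nchar(x$consensus_seq), n_polymorphisms = y,
    n_genotypes = 2^y
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
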