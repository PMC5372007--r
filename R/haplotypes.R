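# --- combinatorial haplotype construction ----------------------------------
#
# A barcode with y polymorphisms implies 2^y candidate haplotypes: every
# subset of alternate alleles applied to the consensus. The subset is the
# genotype's bitmask ID. Edits are applied in strictly descending position
# order so that indels never shift the coordinates of edits still to come.

# raw sequence for one bitmask; `region` validated by barcode_region()
build_haplotype_seq <- function(region, bitmask) {
  polys <- region$polymorphisms
  y <- nrow(polys)
  sel <- set_bits(bitmask, y)
  if (length(sel) > 1) {
    p <- polys$local_pos[sel]
    e <- p + nchar(polys$ref_allele[sel]) - 1L
    clash <- which(p[-1] <= e[-length(e)])
    if (length(clash) > 0) {
      abort(sprintf(
        "cannot apply both polymorphisms at positions %d and %d: their reference spans overlap",
        polys$position[sel][clash[1]], polys$position[sel][clash[1] + 1]
      ))
    }
  }
  s <- region$consensus_seq
  for (j in rev(sel)) {
    lp <- polys$local_pos[j]
    rl <- nchar(polys$ref_allele[j])
    s <- paste0(substr(s, 1L, lp - 1L), polys$alt_allele[j],
                substr(s, lp + rl, nchar(s)))
  }
  s
}

#' Construct one haplotype of a barcode region
#'
#' Applies, for every set bit i of `bitmask`, the alternate allele of the
#' polymorphism with index i to the region consensus. Bitmask 0 is the
#' consensus itself. Two applied polymorphisms with overlapping reference
#' spans have no well-defined joint sequence and raise an error.
#'
#' @param region A [barcode_region()].
#' @param bitmask Genotype ID in `[0, 2^y)`.
#' @return A one-row tibble with `bitmask`, `name`
#'   (`"<label>_G_<bitmask>"`) and `sequence`.
#' @examples
#' region <- barcode_region(
#'   consensus = "ACGTACGT",
#'   polymorphisms = tibble::tibble(
#'     contig = "c", position = c(4L, 7L), ref_allele = c("TA", "G"),
#'     alt_allele = c("T", "C"), genotype_quality = 99, depth = 100
#'   ),
#'   start = 1, end = 8, label = "demo", contig = "c"
#' )
#' build_haplotype(region, 3)$sequence # "ACGTCCT"
#' @export
build_haplotype <- function(region, bitmask) {
  y <- n_polymorphisms(region)
  if (!is_scalar_number(bitmask) || bitmask < 0 || bitmask >= 2^y ||
      bitmask != floor(bitmask)) {
    abort(sprintf("`bitmask` must be an integer in [0, 2^%d)", y))
  }
  tibble(
    bitmask = as.numeric(bitmask),
    name = genotype_name(region$label, bitmask),
    sequence = build_haplotype_seq(region, bitmask)
  )
}

# shared guard: refuse enumeration-scale work beyond the configured y
check_enumeration_guard <- function(region, config) {
  y <- n_polymorphisms(region)
  if (y > config$max_polymorphisms) {
    abort(sprintf(
      paste0("region '%s' carries %d polymorphisms; the candidate database grows as 2^y ",
             "(here 2^%d = %s sequences), so regions with more than %d polymorphisms are refused"),
      region$label, y, y, format_mask(2^y), config$max_polymorphisms
    ))
  }
  invisible(y)
}

#' Number of genotypes implied by a barcode region
#'
#' Computed arithmetically as 2^y; no sequences are materialised.
#'
#' @param region A [barcode_region()], or an integer y.
#' @return 2^y as a double (exact for y <= 52).
#' @export
haplotype_count <- function(region) {
  y <- if (inherits(region, "barcode_region")) n_polymorphisms(region) else as.integer(region)
  if (y > 52) abort("2^y exceeds exact double precision for y > 52")
  2^y
}

#' Enumerate haplotypes of a barcode region
#'
#' Materialises haplotype records for the requested bitmasks (default: all
#' 2^y of them, in ascending bitmask order). Materialising every record is
#' only sensible for small y; the guard refuses y beyond
#' `config$max_polymorphisms`, and `write_haplotype_fasta()` streams records
#' to disk in chunks so a full database never has to fit in memory.
#'
#' @param region A [barcode_region()].
#' @param bitmasks Optional vector of bitmasks; defaults to `0:(2^y - 1)`.
#' @param config A [pipeline_config()]; supplies the y guard.
#' @return A tibble with `bitmask`, `name`, `sequence`, one row per
#'   requested genotype.
#' @export
enumerate_haplotypes <- function(region, bitmasks = NULL,
                                 config = pipeline_config()) {
  y <- check_enumeration_guard(region, config)
  if (is.null(bitmasks)) {
    if (y > 24) {
      abort(sprintf(
        "refusing to materialise 2^%d records in memory; use write_haplotype_fasta() or iterate_haplotypes()", y
      ))
    }
    bitmasks <- seq(0, 2^y - 1)
  }
  seqs <- vapply(bitmasks, function(m) build_haplotype_seq(region, m),
                 character(1))
  tibble(
    bitmask = as.numeric(bitmasks),
    name = genotype_name(region$label, bitmasks),
    sequence = seqs
  )
}

#' Stream haplotypes through a callback in chunks
#'
#' Visits all 2^y haplotype records in ascending bitmask order without ever
#' holding more than `chunk_size` of them in memory.
#'
#' @param region A [barcode_region()].
#' @param fn Function called once per chunk with a tibble like the result of
#'   [enumerate_haplotypes()].
#' @param chunk_size Records per chunk.
#' @param config A [pipeline_config()]; supplies the y guard.
#' @return Total number of records visited (2^y), invisibly.
#' @export
iterate_haplotypes <- function(region, fn, chunk_size = 1024L,
                               config = pipeline_config()) {
  y <- check_enumeration_guard(region, config)
  total <- 2^y
  done <- 0
  while (done < total) {
    n <- min(chunk_size, total - done)
    masks <- seq(done, length.out = n)
    fn(enumerate_haplotypes(region, bitmasks = masks, config = config))
    done <- done + n
  }
  invisible(total)
}

#' Write the full haplotype database as FASTA
#'
#' Streams every one of the 2^y haplotype records to a FASTA file (gzip
#' compression is chosen from the file extension), chunk by chunk.
#'
#' @param region A [barcode_region()].
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @param chunk_size Records built per write.
#' @param config A [pipeline_config()]; supplies the y guard.
#' @return Number of records written (2^y).
#' @export
write_haplotype_fasta <- function(region, path, chunk_size = 1024L,
                                  config = pipeline_config()) {
  check_enumeration_guard(region, config)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con), add = TRUE)
  n <- iterate_haplotypes(region, function(chunk) {
    write_fasta_chunk(con, chunk$name, chunk$sequence)
  }, chunk_size = chunk_size, config = config)
  n
}
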