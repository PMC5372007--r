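# Bitmask helpers.
#
# Genotype IDs are bitmasks over a barcode's polymorphisms: bit i set means
# polymorphism with index i (0-based, ordered by position) carries its
# alternate allele. Masks are stored as doubles so that up to 52 bits are
# represented exactly; the practical enumeration guard is far lower.

# 0-based bit test, vectorised over `mask`
bit_is_set <- function(mask, bit) {
  (mask %/% 2^bit) %% 2 == 1
}

# indices (1-based, into the polymorphism table) of the set bits of one mask
set_bits <- function(mask, y) {
  if (y == 0L) return(integer(0))
  which(bit_is_set(mask, seq_len(y) - 1))
}

popcount <- function(mask, y) {
  vapply(mask, function(m) length(set_bits(m, y)), integer(1))
}

# format a bitmask double as a plain integer string (no scientific notation)
format_mask <- function(mask) {
  format(mask, scientific = FALSE, trim = TRUE)
}

genotype_name <- function(label, mask) {
  paste0(label, "_G_", format_mask(mask))
}

# mean Phred quality of Sanger-encoded (Phred+33) quality strings
mean_phred <- function(quality) {
  vapply(quality, function(q) {
    if (!nzchar(q)) return(NA_real_)
    mean(as.integer(charToRaw(q))) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

phred_char <- function(q) {
  intToUtf8(min(max(round(q), 0), 93) + 33)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

check_dna <- function(x, what = "allele", allow_empty = FALSE) {
  bad <- !grepl(if (allow_empty) "^[ACGT]*$" else "^[ACGT]+$", x)
  if (any(bad)) {
    abort(sprintf(
      "%s must be a non-empty string over A/C/G/T; offending value(s): %s",
      what, paste(unique(x[bad])[seq_len(min(3, length(unique(x[bad]))))],
                  collapse = ", ")
    ))
  }
  invisible(x)
}
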