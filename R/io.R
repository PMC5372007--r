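#' Read a consensus sequence from FASTA
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @param contig Optional record name; defaults to the first record.
#' @return A single uppercase nucleotide string, named by its contig.
#' @export
read_consensus_fasta <- function(path, contig = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) abort(sprintf("no FASTA records in '%s'", path))
  nm <- sub("\\s.*$", "", names(x))
  if (is.null(contig)) contig <- nm[[1]]
  i <- match(contig, nm)
  if (is.na(i)) abort(sprintf("contig '%s' not found in '%s'", contig, path))
  setNames(toupper(as.character(x[[i]])), contig)
}

#' Read raw variant records from a VCF file
#'
#' Parses a plain (non-genomic) VCF 4.x with per-sample GQ and DP
#' annotations into one row per (site, alternate allele). Multi-allelic
#' records are split into one row per alternate allele so that every row is
#' biallelic; GQ and DP are taken from the first sample.
#'
#' @param path VCF file (optionally gzip/bgzip-compressed).
#' @return A tibble with columns `contig`, `position` (1-based),
#'   `ref_allele`, `alt_allele`, `genotype_quality`, `depth`, `record`
#'   (ordinal of the VCF data line, for error messages).
#' @seealso [filter_variants()] for hard filtering and classification.
#' @export
read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(v@fix)
  if (n == 0L) {
    return(tibble(
      contig = character(), position = integer(), ref_allele = character(),
      alt_allele = character(), genotype_quality = numeric(),
      depth = numeric(), record = integer()
    ))
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    abort(sprintf("malformed VCF record %d: non-integer POS '%s'",
                  which(is.na(pos))[1], fix$POS[which(is.na(pos))[1]]))
  }
  if (ncol(v@gt) < 2L) {
    abort(sprintf("VCF '%s' carries no sample columns; GQ/DP annotations are required", path))
  }
  gq <- suppressWarnings(as.numeric(vcfR::extract.gt(v, "GQ")[, 1]))
  dp <- suppressWarnings(as.numeric(vcfR::extract.gt(v, "DP")[, 1]))
  raw <- tibble(
    contig = fix$CHROM,
    position = pos,
    ref_allele = toupper(fix$REF),
    alt_allele = toupper(fix$ALT),
    genotype_quality = gq,
    depth = dp,
    record = seq_len(n)
  )
  # split multi-allelic sites: one biallelic row per alternate allele
  tidyr::separate_rows(raw, "alt_allele", sep = ",")
}

#' Read excluded intervals from a BED file
#'
#' BED is 0-based half-open on disk; the returned intervals are 1-based
#' closed, the convention used everywhere at this package's interface.
#'
#' @param path BED file.
#' @return A tibble with columns `contig`, `start`, `end` (1-based closed).
#' @export
read_excluded_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading BED files requires the rtracklayer package")
  }
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  tibble(
    contig = as.character(gr$seqnames),
    start = as.integer(gr$start),
    end = as.integer(gr$end)
  )
}

#' Write a filtered-variant report as TSV
#'
#' @param variants Tibble of classified polymorphisms from
#'   [filter_variants()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_report <- function(variants, path) {
  out <- dplyr::select(
    variants,
    Contig = "contig", Position = "position", Ref = "ref_allele",
    Alt = "alt_allele", Kind = "kind", GQ = "genotype_quality",
    Depth = "depth"
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read amplicon reads from FASTQ (or FASTA)
#'
#' FASTQ qualities are taken as Sanger Phred+33. FASTA input is accepted for
#' testing convenience, with a uniform assumed quality.
#'
#' @param path FASTQ or FASTA file.
#' @param format `"fastq"` (default) or `"fasta"`.
#' @param assumed_quality Phred value assigned to every base of FASTA input.
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_amplicon_reads <- function(path, format = c("fastq", "fasta"),
                                assumed_quality = 30) {
  format <- match.arg(format)
  if (format == "fastq") {
    # Biostrings warns (cosmetically) about dropped mcols on the quality set
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    tibble(
      read_id = sub("\\s.*$", "", names(x)),
      sequence = unname(toupper(as.character(x))),
      quality = unname(as.character(Biostrings::quality(x)))
    )
  } else {
    x <- Biostrings::readDNAStringSet(path)
    seqs <- unname(toupper(as.character(x)))
    tibble(
      read_id = sub("\\s.*$", "", names(x)),
      sequence = seqs,
      quality = strrep(phred_char(assumed_quality), nchar(seqs))
    )
  }
}

#' Write amplicon reads to FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_amplicon_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  xs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(reads$quality)
  )
  names(xs) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(xs, path)
  invisible(path)
}

#' Read a haplotype database written by [write_haplotype_fasta()]
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @return A tibble with columns `name`, `sequence`.
#' @export
read_haplotype_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(name = names(x), sequence = unname(as.character(x)))
}

# minimal FASTA writer used for streamed database output; `con` is an open
# text connection so chunks can be appended under one (optionally gzip) file
write_fasta_chunk <- function(con, names, seqs, width = 70L) {
  wrapped <- vapply(seqs, function(s) {
    n <- nchar(s)
    if (n <= width) return(s)
    paste(substring(s, seq(1L, n, width), pmin(seq(1L, n, width) + width - 1L, n)),
          collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
  writeLines(paste0(">", names, "\n", wrapped), con, sep = "\n")
}

# Minimal VCF 4.2 formatter for simulator output (GT:GQ:DP on one sample).
# Reading always goes through vcfR; this writer only materialises records
# the simulator itself constructed.
write_sim_vcf <- function(variants, path, contig, contig_length,
                          sample_name = "sim_sample") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haplotally-simulator",
    sprintf("##contig=<ID=%s,length=%d>", contig, contig_length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  rows <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:GQ:DP\t0/1:%d:%d",
    contig, variants$position, variants$ref_allele, variants$alt_allele,
    as.integer(variants$genotype_quality), as.integer(variants$depth)
  )
  writeLines(c(header, rows), path)
  invisible(path)
}
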