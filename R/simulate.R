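# --- synthetic community simulator -----------------------------------------
#
# Emulates the study conditions every other stage is validated against: a
# short AT-rich barcode (<= 400 bp) carrying up to 30 well-separated
# biallelic polymorphisms, a genotype frequency vector (one dominant
# genotype near 97% plus a tail of minor genotypes, or a 54/46 two-genotype
# mix), and i.i.d. per-base substitution sequencing error.

BASES <- c("A", "C", "G", "T")

# default base composition: AT-rich, as in the baculovirus hotspot regions
# where polymorphism-dense barcodes are found
AT_RICH <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)

# default variant-class mix: the genome-wide class proportions of the
# validation isolate (46 substitutions, 53 insertions, 339 deletions)
DEFAULT_KINDS_MIX <- c(substitution = 46, insertion = 53, deletion = 339) / 438

# largest-remainder apportionment of y among the classes
apportion_kinds <- function(y, kinds_mix) {
  kinds_mix <- kinds_mix / sum(kinds_mix)
  raw <- y * kinds_mix
  n <- floor(raw)
  left <- y - sum(n)
  if (left > 0) {
    extra <- order(raw - n, decreasing = TRUE)[seq_len(left)]
    n[extra] <- n[extra] + 1
  }
  n
}

#' Simulate a consensus, its variant calls and a barcode region
#'
#' Generates a random consensus sequence and plants `y` non-overlapping
#' biallelic polymorphisms inside `[region_start, region_end]`, spaced so
#' that no two reference spans can touch. Planted records carry GQ/DP
#' values above the default hard filters. Deterministic under `seed`.
#'
#' @param consensus_length Consensus length in bp (>= 10 * y within the
#'   region span).
#' @param y Number of polymorphisms to plant (0..30).
#' @param kinds_mix Named proportions over
#'   `c("substitution", "insertion", "deletion")`; the default is the
#'   genome-wide class mix of the validation isolate.
#' @param seed Integer seed.
#' @param region_start,region_end Span that receives the polymorphisms and
#'   defines the returned barcode region; defaults to the whole consensus.
#' @param label Region label.
#' @param contig Contig name.
#' @param base_probs Base composition of the consensus (default AT-rich).
#' @return A list with `consensus` (named string), `variants` (raw variant
#'   tibble, as from [read_vcf_variants()]) and `region` (a
#'   [barcode_region()]).
#' @export
simulate_region <- function(consensus_length, y,
                            kinds_mix = DEFAULT_KINDS_MIX,
                            seed = 1L,
                            region_start = 1L,
                            region_end = consensus_length,
                            label = "sim",
                            contig = "sim_contig",
                            base_probs = AT_RICH) {
  if (y > 30) abort("`y` must be <= 30 for simulated barcode regions")
  span <- region_end - region_start + 1L
  if (y > 0 && span < 10L * y) {
    abort(sprintf(
      "cannot place %d non-overlapping polymorphisms in a %d bp span; need >= %d bp",
      y, span, 10L * y
    ))
  }
  withr::with_seed(seed, {
    consensus <- paste(sample(BASES, consensus_length, replace = TRUE,
                              prob = base_probs[BASES]), collapse = "")
    variants <- tibble(
      contig = character(), position = integer(), ref_allele = character(),
      alt_allele = character(), genotype_quality = numeric(),
      depth = numeric(), record = integer()
    )
    if (y > 0) {
      slot_w <- span %/% y
      # one site per slot, away from the slot edge so spans never touch
      offsets <- sample.int(max(slot_w - 8L, 1L), y, replace = TRUE)
      pos <- region_start + (seq_len(y) - 1L) * slot_w + offsets - 1L
      kinds <- sample(rep(names(kinds_mix), apportion_kinds(y, kinds_mix)))
      ref <- alt <- character(y)
      for (i in seq_len(y)) {
        anchor <- substr(consensus, pos[i], pos[i])
        if (kinds[i] == "substitution") {
          ref[i] <- anchor
          alt[i] <- sample(setdiff(BASES, anchor), 1)
        } else if (kinds[i] == "insertion") {
          ref[i] <- anchor
          alt[i] <- paste0(anchor, paste(sample(BASES, sample(1:3, 1),
                                                replace = TRUE), collapse = ""))
        } else {
          k <- sample(1:3, 1)
          ref[i] <- substr(consensus, pos[i], pos[i] + k)
          alt[i] <- anchor
        }
      }
      variants <- tibble(
        contig = contig, position = as.integer(pos), ref_allele = ref,
        alt_allele = alt,
        genotype_quality = sample(70:99, y, replace = TRUE),
        depth = sample(50:500, y, replace = TRUE),
        record = seq_len(y)
      )
    }
    consensus <- setNames(consensus, contig)
    region <- barcode_region(
      consensus, dplyr::select(variants, -"record"),
      start = region_start, end = region_end,
      label = label, contig = contig
    )
    list(consensus = consensus, variants = variants, region = region)
  })
}

#' Write a simulated region to standard files
#'
#' Materialises the simulation as consensus FASTA + VCF under `dir`.
#'
#' @param sim Result of [simulate_region()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "consensus.fa")
  vcf <- file.path(dir, "variants.vcf")
  xs <- Biostrings::DNAStringSet(unname(sim$consensus))
  names(xs) <- names(sim$consensus)
  Biostrings::writeXStringSet(xs, fa)
  write_sim_vcf(sim$variants, vcf, contig = names(sim$consensus),
                contig_length = nchar(sim$consensus))
  c(consensus = fa, vcf = vcf)
}

#' Describe a synthetic community with known truth
#'
#' @param region A [barcode_region()].
#' @param genotype_frequencies Tibble with `bitmask` and `frequency`
#'   columns, or a named numeric vector (names = bitmasks). Frequencies
#'   must sum to 1 (tolerance 1e-9) and all bitmasks must be < 2^y.
#' @param n_reads Number of reads to draw.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return An object of class `community_truth`.
#' @export
community_truth <- function(region, genotype_frequencies, n_reads,
                            error_rate = 0, seed = 1L) {
  if (!is.data.frame(genotype_frequencies)) {
    genotype_frequencies <- tibble(
      bitmask = as.numeric(names(genotype_frequencies)),
      frequency = as.numeric(genotype_frequencies)
    )
  }
  gf <- as_tibble(genotype_frequencies)
  if (abs(sum(gf$frequency) - 1) > 1e-9) {
    abort("genotype frequencies must sum to 1 (tolerance 1e-9)")
  }
  y <- n_polymorphisms(region)
  if (any(gf$bitmask < 0 | gf$bitmask >= 2^y)) {
    abort(sprintf("all bitmasks must lie in [0, 2^%d)", y))
  }
  if (!is_scalar_number(n_reads) || n_reads <= 0) {
    abort("`n_reads` must be a positive number")
  }
  structure(
    list(region = region, genotype_frequencies = gf,
         n_reads = as.integer(n_reads), error_rate = error_rate,
         seed = as.integer(seed)),
    class = "community_truth"
  )
}

# replace k random bases of s with a different random base
mutate_bases <- function(s, k) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(v), k)
  v[pos] <- vapply(v[pos], function(b) sample(setdiff(BASES, b), 1),
                   character(1), USE.NAMES = FALSE)
  paste(v, collapse = "")
}

#' Simulate amplicon reads from a known genotype mixture
#'
#' Draws each read's genotype i.i.d. from the truth frequencies, emits that
#' genotype's haplotype sequence with i.i.d. per-base substitution errors at
#' `error_rate`, and assigns every base the Phred quality implied by the
#' error rate (Q40 when the error rate is 0). Deterministic under the
#' truth's seed.
#'
#' @param truth A [community_truth()].
#' @return A tibble with `read_id`, `sequence`, `quality` and the
#'   truth-table column `true_bitmask`.
#' @export
simulate_reads <- function(truth) {
  stopifnot(inherits(truth, "community_truth"))
  gf <- truth$genotype_frequencies
  haps <- vapply(gf$bitmask,
                 function(m) build_haplotype_seq(truth$region, m),
                 character(1))
  withr::with_seed(truth$seed, {
    idx <- sample.int(nrow(gf), truth$n_reads, replace = TRUE,
                      prob = gf$frequency)
    seqs <- haps[idx]
    if (truth$error_rate > 0) {
      n_err <- rbinom(truth$n_reads, nchar(seqs), truth$error_rate)
      hit <- which(n_err > 0)
      for (i in hit) seqs[i] <- mutate_bases(seqs[i], n_err[i])
    }
    q <- if (truth$error_rate > 0) -10 * log10(truth$error_rate) else 40
    tibble(
      read_id = sprintf("read_%07d", seq_len(truth$n_reads)),
      sequence = seqs,
      quality = strrep(phred_char(q), nchar(seqs)),
      true_bitmask = gf$bitmask[idx]
    )
  })
}

#' Write simulated reads as FASTQ plus a truth table
#'
#' @param reads Tibble from [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths (`fastq`, `truth`).
#' @export
write_simulated_reads <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(dir, "reads.fq")
  truth <- file.path(dir, "truth.tsv")
  write_amplicon_fastq(reads, fq)
  readr::write_tsv(
    dplyr::transmute(reads, read_id = .data$read_id,
                     true_bitmask = format_mask(.data$true_bitmask)),
    truth
  )
  c(fastq = fq, truth = truth)
}

#' Published genotype mixtures of the HaSNPV-AC53 validation system
#'
#' Read-count tables for the BRO-A barcode of the wild-type HaSNPV-AC53
#' isolate (28 genotypes at or above 20x coverage, dominant genotype near
#' 97%) and of the tissue-culture-derived strain AC53-T2 (two genotypes at
#' 54.27% / 45.73%). Shipped as plain TSVs under `inst/extdata/` and used
#' as simulation truth for end-to-end validation.
#'
#' @param which `"ac53_broa"` or `"ac53_t2"`.
#' @return A tibble with `genotype`, `bitmask`, `reads`.
#' @export
reference_mixture <- function(which = c("ac53_broa", "ac53_t2")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("hasnpv_", which, "_genotypes.tsv"),
                      package = "haplotally", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
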