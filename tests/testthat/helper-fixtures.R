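# Fixture builders and independent oracles used across the suite.

BASES4 <- c("A", "C", "G", "T")

random_dna <- function(n, prob = NULL) {
  paste(sample(BASES4, n, replace = TRUE, prob = prob), collapse = "")
}

# quick region constructor: substitutions (or explicit alleles) on a random
# or supplied consensus, bypassing VCF I/O
make_region <- function(consensus, positions, ref = NULL, alt = NULL,
                        label = "fix", contig = "ctg", start = 1,
                        end = nchar(consensus)) {
  positions <- as.integer(positions)
  if (is.null(ref)) {
    ref <- if (length(positions)) substring(consensus, positions, positions) else character(0)
  }
  if (is.null(alt)) {
    alt <- if (length(ref)) vapply(ref, function(b) sample(setdiff(BASES4, substr(b, 1, 1)), 1),
                  character(1), USE.NAMES = FALSE) else character(0)
  }
  polys <- tibble::tibble(
    contig = contig, position = as.integer(positions), ref_allele = ref,
    alt_allele = alt, genotype_quality = 99, depth = 100
  )
  barcode_region(stats::setNames(consensus, contig), polys,
                 start = start, end = end, label = label, contig = contig)
}

# a region with y well-spaced random substitutions
make_sub_region <- function(len, y, label = "fix") {
  consensus <- random_dna(len)
  positions <- sort(sample(seq(5, len - 5), y))
  while (y > 1 && any(diff(positions) < 2)) {
    positions <- sort(sample(seq(5, len - 5), y))
  }
  make_region(consensus, positions, label = label)
}

# O(n * w) brute-force window-count oracle
brute_force_windows <- function(positions, ref_len, consensus_length,
                                window_length) {
  n_windows <- consensus_length - window_length + 1
  vapply(seq_len(n_windows), function(s) {
    sum(positions >= s & positions + ref_len - 1 <= s + window_length - 1)
  }, numeric(1))
}

# character-level edit oracle: applies alt alleles cell-wise, in any order,
# independent of build_haplotype's descending-position string surgery
oracle_apply_edits <- function(consensus, polys_local) {
  cells <- as.list(strsplit(consensus, "", fixed = TRUE)[[1]])
  for (i in seq_len(nrow(polys_local))) {
    p <- polys_local$local_pos[i]
    rl <- nchar(polys_local$ref_allele[i])
    cells[[p]] <- polys_local$alt_allele[i]
    if (rl > 1) for (j in (p + 1):(p + rl - 1)) cells[[j]] <- ""
  }
  paste(unlist(cells), collapse = "")
}

# raw variant records with exact class counts, planted on a fresh consensus;
# returns list(consensus, records)
make_classified_records <- function(n_sub, n_ins, n_del, gq = 99, depth = 100) {
  n <- n_sub + n_ins + n_del
  len <- 10 * n + 20
  consensus <- random_dna(len)
  pos <- seq(5, by = 10, length.out = n)
  kinds <- sample(rep(c("substitution", "insertion", "deletion"),
                      c(n_sub, n_ins, n_del)))
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    anchor <- substr(consensus, pos[i], pos[i])
    if (kinds[i] == "substitution") {
      ref[i] <- anchor
      alt[i] <- sample(setdiff(BASES4, anchor), 1)
    } else if (kinds[i] == "insertion") {
      ref[i] <- anchor
      alt[i] <- paste0(anchor, random_dna(sample(1:3, 1)))
    } else {
      k <- sample(1:3, 1)
      ref[i] <- substr(consensus, pos[i], pos[i] + k)
      alt[i] <- anchor
    }
  }
  list(
    consensus = stats::setNames(consensus, "ctg"),
    records = tibble::tibble(
      contig = "ctg", position = as.integer(pos), ref_allele = ref,
      alt_allele = alt, genotype_quality = gq, depth = depth,
      record = seq_len(n)
    )
  )
}

# reads tibble from bare sequences
as_reads <- function(sequences, q = 35) {
  tibble::tibble(
    read_id = sprintf("r%04d", seq_along(sequences)),
    sequence = sequences,
    quality = strrep(rawToChar(as.raw(q + 33)), nchar(sequences))
  )
}
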