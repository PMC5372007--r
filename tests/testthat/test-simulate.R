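test_that("simulated regions honour y, class mix and the default filters", {
  # negative control: a region with no polymorphisms at all
  neg <- simulate_region(325, 0, seed = 1, label = "polh-neg")
  expect_equal(nrow(neg$variants), 0)
  expect_equal(n_polymorphisms(neg$region), 0)

  sim <- simulate_region(365, 25, seed = 2,
                         kinds_mix = c(substitution = 0.4, insertion = 0.3,
                                       deletion = 0.3))
  expect_equal(n_polymorphisms(sim$region), 25)
  kinds <- table(sim$region$polymorphisms$kind)
  expect_equal(as.vector(kinds[c("substitution", "insertion", "deletion")]),
               c(10, 8, 7))
  # planted records pass the default hard filters and validate against the
  # emitted consensus
  passed <- filter_variants(sim$variants, pipeline_config(),
                            consensus = sim$consensus)
  expect_equal(nrow(passed), 25)
  # reference spans never overlap
  p <- sim$region$polymorphisms
  expect_true(all(p$position[-1] >
                    (p$position + nchar(p$ref_allele) - 1)[-nrow(p)]))

  expect_error(simulate_region(100, 25, seed = 1), "non-overlapping")
  expect_error(simulate_region(1000, 31, seed = 1), "<= 30")
})

test_that("the same seed reproduces byte-identical simulation outputs", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  for (d in c(dir_a, dir_b)) {
    sim <- simulate_region(200, 6, seed = 99)
    write_simulation(sim, d)
    truth <- community_truth(
      sim$region,
      tibble::tibble(bitmask = c(0, 63), frequency = c(0.5, 0.5)),
      n_reads = 500, error_rate = 0.003, seed = 99
    )
    write_simulated_reads(simulate_reads(truth), d)
  }
  for (f in c("consensus.fa", "variants.vcf", "reads.fq", "truth.tsv")) {
    expect_equal(unname(tools::md5sum(file.path(dir_a, f))),
                 unname(tools::md5sum(file.path(dir_b, f))),
                 label = f)
  }
})

test_that("error-free reads from a known mixture recover the truth exactly", {
  sim <- simulate_region(365, 1, seed = 293, label = "BRO-A",
                         kinds_mix = c(substitution = 1))
  truth <- community_truth(
    sim$region,
    tibble::tibble(bitmask = c(1, 0), frequency = c(0.5427, 0.4573)),
    n_reads = 191754, error_rate = 0, seed = 54
  )
  reads <- simulate_reads(truth)
  expect_equal(nrow(reads), 191754)
  res <- quantify(assign_reads(reads, sim$region), sim$region,
                  pipeline_config())
  rows <- tidy(res)
  expect_equal(res$total_rejected, 0)
  # each recovered frequency within 3 binomial SE of its truth
  for (i in seq_len(2)) {
    p <- truth$genotype_frequencies$frequency[
      match(rows$bitmask[i], truth$genotype_frequencies$bitmask)]
    se <- sqrt(p * (1 - p) / 191754)
    expect_lt(abs(rows$reads[i] / 191754 - p), 3 * se)
  }
})

test_that("a pure consensus community quantifies to one genotype at 100%", {
  sim <- simulate_region(120, 3, seed = 8)
  truth <- community_truth(sim$region,
                           tibble::tibble(bitmask = 0, frequency = 1),
                           n_reads = 100, error_rate = 0, seed = 8)
  reads <- simulate_reads(truth)
  expect_true(all(reads$sequence == sim$region$consensus_seq))
  res <- quantify(assign_reads(reads, sim$region), sim$region,
                  pipeline_config())
  expect_equal(tidy(res)$relative_abundance, 100)
})

test_that("end-to-end recovery holds for every genotype above 0.5%", {
  sim <- simulate_region(365, 10, seed = 17)
  freqs <- tibble::tibble(
    bitmask = c(1023, 1022, 512, 7, 0),
    frequency = c(0.90, 0.05, 0.025, 0.015, 0.01)
  )
  n <- 1e5
  truth <- community_truth(sim$region, freqs, n_reads = n, error_rate = 0,
                           seed = 18)
  res <- quantify(assign_reads(simulate_reads(truth), sim$region),
                  sim$region, pipeline_config())
  rows <- tidy(res, all = TRUE)
  expect_equal(sort(rows$bitmask), sort(freqs$bitmask))
  for (i in seq_len(nrow(freqs))) {
    got <- rows$reads[match(freqs$bitmask[i], rows$bitmask)] / n
    se <- sqrt(freqs$frequency[i] * (1 - freqs$frequency[i]) / n)
    expect_lt(abs(got - freqs$frequency[i]), 3 * se)
  }
})

test_that("per-base errors reject reads at the closed-form rate", {
  # substitution-only region so every haplotype has the consensus length
  sim <- simulate_region(365, 5, seed = 23,
                         kinds_mix = c(substitution = 1))
  eps <- 0.005
  n <- 4000
  truth <- community_truth(sim$region,
                           tibble::tibble(bitmask = c(0, 31),
                                          frequency = c(0.5, 0.5)),
                           n_reads = n, error_rate = eps, seed = 24)
  res <- assign_reads(simulate_reads(truth), sim$region)
  observed <- mean(res$outcome == "rejected")
  expected <- 1 - (1 - eps)^365
  expect_lt(abs(observed - expected) / expected, 0.10)

  # conditional on assignment, abundance estimates stay unbiased (errors hit
  # both equal-length genotypes uniformly); checked at a smaller epsilon
  truth2 <- community_truth(sim$region,
                            tibble::tibble(bitmask = c(0, 31),
                                           frequency = c(0.7, 0.3)),
                            n_reads = 5000, error_rate = 0.002, seed = 25)
  res2 <- quantify(assign_reads(simulate_reads(truth2), sim$region),
                   sim$region, pipeline_config())
  rows2 <- tidy(res2)
  n_assigned <- res2$total_assigned
  p_hat <- rows2$reads[rows2$bitmask == 0] / n_assigned
  expect_lt(abs(p_hat - 0.7), 4 * sqrt(0.7 * 0.3 / n_assigned))
})
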