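test_that("variant classification follows the allele-length rule", {
  expect_equal(classify_variant("T", "A"), "substitution")
  expect_equal(classify_variant("A", "AT"), "insertion")
  expect_equal(classify_variant("AT", "A"), "deletion")
  expect_error(classify_variant("", "A"), "A/C/G/T")
  expect_error(classify_variant("A", "AX"), "A/C/G/T")

  # property: total over valid inputs and consistent with the length rule
  withr::with_seed(11, {
    for (i in 1:200) {
      ref <- random_dna(sample(1:5, 1))
      alt <- random_dna(sample(1:5, 1))
      kind <- classify_variant(ref, alt)
      expect_equal(
        kind,
        if (nchar(alt) == nchar(ref)) "substitution"
        else if (nchar(alt) > nchar(ref)) "insertion" else "deletion"
      )
    }
  })
})

test_that("hard filtering keeps GQ >= 60 and depth >= 20, with validation", {
  cfg <- pipeline_config()
  recs <- tibble::tibble(
    contig = "ctg",
    position = c(5L, 15L, 25L, 35L),
    ref_allele = c("A", "A", "A", "A"),
    alt_allele = c("G", "G", "G", "G"),
    genotype_quality = c(59, 60, 99, 99),
    depth = c(100, 20, 19, 300)
  )
  consensus <- c(ctg = paste(rep("A", 40), collapse = ""))
  out <- filter_variants(recs, cfg, consensus = consensus)
  # GQ 59 excluded, GQ 60 at depth 20 kept (boundary), depth 19 excluded
  expect_equal(out$position, c(15L, 35L))
  expect_true(all(out$kind == "substitution"))

  # idempotence and subset
  expect_equal(filter_variants(out, cfg, consensus = consensus), out)
  expect_true(all(out$position %in% recs$position))

  # ref mismatch is an error naming the position, not a silent drop
  bad <- recs
  bad$ref_allele[4] <- "C"
  expect_error(filter_variants(bad, cfg, consensus = consensus), "35")

  # malformed alleles are a parse error naming the record
  mal <- recs
  mal$alt_allele[2] <- "NX"
  expect_error(filter_variants(mal, cfg), "malformed")
})

test_that("a 438-variant set keeps its 53/339/46 class composition", {
  withr::with_seed(438, {
    fix <- make_classified_records(n_sub = 46, n_ins = 53, n_del = 339)
  })
  out <- filter_variants(fix$records, pipeline_config(),
                         consensus = fix$consensus)
  expect_equal(nrow(out), 438)
  expect_equal(sum(out$kind == "insertion"), 53)
  expect_equal(sum(out$kind == "deletion"), 339)
  expect_equal(sum(out$kind == "substitution"), 46)
})

test_that("VCF records round-trip through the standard parser", {
  withr::with_seed(9, {
    fix <- make_classified_records(n_sub = 4, n_ins = 3, n_del = 3)
  })
  vcf <- withr::local_tempfile(fileext = ".vcf")
  haplotally:::write_sim_vcf(fix$records, vcf, contig = "ctg",
                             contig_length = nchar(fix$consensus))
  back <- read_vcf_variants(vcf)
  expect_equal(back$position, fix$records$position)
  expect_equal(back$ref_allele, fix$records$ref_allele)
  expect_equal(back$alt_allele, fix$records$alt_allele)
  expect_equal(back$genotype_quality, fix$records$genotype_quality)
  expect_equal(back$depth, fix$records$depth)
})

test_that("multi-allelic VCF records split into biallelic rows", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "ctg\t7\t.\tA\tC,G\t.\tPASS\t.\tGT:GQ:DP\t1/2:80:120"
  ), vcf)
  out <- read_vcf_variants(vcf)
  expect_equal(nrow(out), 2)
  expect_equal(out$alt_allele, c("C", "G"))
  expect_equal(out$position, c(7L, 7L))
  expect_equal(out$genotype_quality, c(80, 80))
})

test_that("window scan matches the brute-force oracle and ranks correctly", {
  # worked example: best 50 bp window holds the 3 clustered polymorphisms
  polys <- tibble::tibble(position = c(10L, 20L, 30L, 200L, 210L),
                          ref_allele = "A")
  top <- scan_barcode_windows(polys, consensus_length = 300,
                              window_length = 50)[1, ]
  expect_equal(top$n_polymorphisms, 3)
  expect_true(top$window_start <= 10 && top$window_end >= 30)

  # no polymorphisms: every window counts zero
  none <- scan_barcode_windows(polys[0, ], 100, 20)
  expect_equal(nrow(none), 81)
  expect_true(all(none$n_polymorphisms == 0))

  expect_error(scan_barcode_windows(polys, 300, 0), "positive")
  expect_error(scan_barcode_windows(polys, 300, 400), "exceeds")

  # property: agreement with O(n*w) brute force on random instances,
  # including multi-base ref spans
  withr::with_seed(21, {
    for (i in 1:20) {
      L <- sample(200:5000, 1)
      w <- sample(20:min(400, L), 1)
      n <- sample(0:50, 1)
      pos <- sort(sample(seq_len(L - 5), n))
      rl <- sample(1:4, n, replace = TRUE)
      p <- tibble::tibble(position = pos, ref_allele = strrep("A", rl))
      got <- scan_barcode_windows(p, L, w) |> dplyr::arrange(window_start)
      want <- brute_force_windows(pos, rl, L, w)
      expect_equal(got$n_polymorphisms, want)
    }
  })
})

test_that("windows overlapping excluded intervals are removed", {
  polys <- tibble::tibble(position = c(10L, 40L), ref_allele = "A")
  all_win <- scan_barcode_windows(polys, 100, 10)
  excl <- tibble::tibble(contig = "ctg", start = 30L, end = 60L)
  kept <- scan_barcode_windows(polys, 100, 10, excluded_intervals = excl)
  # windows [s, s+9] overlapping [30, 60] start in [21, 60]
  expect_true(all(kept$window_start < 21 | kept$window_start > 60))
  expect_equal(nrow(kept), nrow(all_win) - 40)
})

test_that("a planted 365 bp hotspot of 30 polymorphisms tops the scan", {
  sim <- simulate_region(3000, 30, seed = 30, region_start = 1201,
                         region_end = 1565, label = "hotspot")
  got <- scan_barcode_windows(sim$region$polymorphisms, 3000, 365)
  expect_equal(got$n_polymorphisms[1], 30)
})

test_that("BED intervals convert to 1-based closed coordinates", {
  skip_if_not_installed("rtracklayer")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("ctg\t99\t200\thr1", "ctg\t999\t1200\thr2"), bed)
  got <- read_excluded_bed(bed)
  expect_equal(got$start, c(100L, 1000L))
  expect_equal(got$end, c(200L, 1200L))
})
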