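#' Pipeline configuration
#'
#' Collects every tunable threshold of the barcode genotyping pipeline in one
#' validated object. Defaults follow the hard filters used throughout the
#' package's intended workflow: variant sites are kept at genotype quality
#' >= 60 (Phred; 0.0001% error) and depth >= 20x; reads are kept at mean
#' quality >= Q20; genotypes are reported at >= 20 supporting reads
#' (about a 1% Phred-scale error); enumeration is refused beyond 30
#' polymorphisms because the database grows as 2^y.
#'
#' @param min_genotype_quality Minimum Phred-scaled genotype quality (GQ) for
#'   a variant site to pass hard filtering. Sites with GQ below this are
#'   excluded (the boundary itself is kept).
#' @param min_site_depth Minimum read depth (DP) at a variant site.
#' @param min_read_quality Minimum mean per-base Phred quality of an amplicon
#'   read.
#' @param min_genotype_coverage Minimum number of assigned reads for a
#'   genotype to appear in the reported abundance table.
#' @param max_polymorphisms Refuse to enumerate (or assign against) barcode
#'   regions with more polymorphisms than this; the database size is 2^y.
#'   Must be <= 52 so bitmask IDs remain exact.
#' @param window_length Barcode window span in bp for the polymorphism
#'   density scan (e.g. 325 or 365, less than one sequencing read).
#' @param error_rate Per-base substitution error rate used by the read
#'   simulator.
#' @param seed Integer seed for all randomised steps.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' pipeline_config()
#' pipeline_config(min_genotype_coverage = 50, window_length = 325)
#' @export
pipeline_config <- function(min_genotype_quality = 60,
                            min_site_depth = 20,
                            min_read_quality = 20,
                            min_genotype_coverage = 20,
                            max_polymorphisms = 30,
                            window_length = 365,
                            error_rate = 0,
                            seed = 1L) {
  cfg <- list(
    min_genotype_quality = min_genotype_quality,
    min_site_depth = min_site_depth,
    min_read_quality = min_read_quality,
    min_genotype_coverage = min_genotype_coverage,
    max_polymorphisms = max_polymorphisms,
    window_length = window_length,
    error_rate = error_rate,
    seed = as.integer(seed)
  )
  for (nm in setdiff(names(cfg), "seed")) {
    if (!is_scalar_number(cfg[[nm]]) || cfg[[nm]] < 0) {
      abort(sprintf("`%s` must be a single non-negative number", nm))
    }
  }
  if (cfg$window_length < 1) abort("`window_length` must be >= 1")
  if (cfg$max_polymorphisms > 52) {
    abort("`max_polymorphisms` must be <= 52: bitmask genotype IDs are exact only up to 52 bits")
  }
  if (cfg$error_rate >= 1) abort("`error_rate` must be < 1")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
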