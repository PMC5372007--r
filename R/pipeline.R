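#' Run the full barcode genotyping pipeline
#'
#' Ties the stages together: hard-filter variants against the consensus,
#' build the barcode region, quality-filter (and, when primers are given,
#' trim) the reads, assign every read to a genotype, and quantify relative
#' abundances. Writes `abundance.tsv`, `rejections.tsv`, `assignments.tsv`
#' and a self-contained `manifest.json` (tool version, config snapshot,
#' input digests, per-stage record counts) under `out_dir`.
#'
#' @param config Path to a flat key-value YAML file, or an equivalent named
#'   list. Required keys: `consensus_fasta`, `vcf`, `reads_fastq`,
#'   `region_start`, `region_end`, `out_dir`. Optional keys: `contig`,
#'   `region_label`, `forward_primer`, `reverse_primer`, `amplicon_length`,
#'   `reads_format`, plus any [pipeline_config()] threshold by name.
#' @return The `abundance_table`, invisibly, with the manifest attached as
#'   attribute `"manifest"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  required <- c("consensus_fasta", "vcf", "reads_fastq", "region_start",
                "region_end", "out_dir")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys) > 0) {
    abort(paste0("pipeline config lacks key(s): ",
                 paste(missing_keys, collapse = ", ")))
  }
  inputs <- c(consensus_fasta = config$consensus_fasta, vcf = config$vcf,
              reads_fastq = config$reads_fastq)
  absent <- inputs[!file.exists(inputs)]
  if (length(absent) > 0) {
    abort(paste0("missing input file(s): ", paste(absent, collapse = ", ")))
  }

  cfg_keys <- intersect(names(config), names(formals(pipeline_config)))
  cfg <- do.call(pipeline_config, config[cfg_keys])
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  stages <- list()

  consensus <- read_consensus_fasta(config$consensus_fasta,
                                    contig = config$contig)
  raw <- read_vcf_variants(config$vcf)
  stages$variants_in <- nrow(raw)
  polys <- filter_variants(raw, cfg, consensus = consensus)
  stages$variants_passing <- nrow(polys)

  region <- barcode_region(
    consensus,
    polys[polys$position >= config$region_start &
            polys$position + nchar(polys$ref_allele) - 1 <= config$region_end, ,
          drop = FALSE],
    start = config$region_start, end = config$region_end,
    label = config$region_label %||% "region",
    contig = names(consensus)
  )
  stages$region_polymorphisms <- n_polymorphisms(region)

  reads <- read_amplicon_reads(config$reads_fastq,
                               format = config$reads_format %||% "fastq")
  stages$reads_in <- nrow(reads)
  reads <- quality_filter(reads, cfg)
  stages$reads_after_quality <- nrow(reads)
  if (!is.null(config$forward_primer)) {
    reads <- trim_to_amplicon(
      reads,
      forward_primer = config$forward_primer,
      reverse_primer = config$reverse_primer,
      expected_length = config$amplicon_length %||%
        (region$end - region$start + 1)
    )
    stages$reads_after_trim <- nrow(reads)
  }

  assignments <- assign_reads(reads, region, cfg)
  stages$reads_assigned <- sum(assignments$outcome == "assigned")
  stages$reads_rejected <- sum(assignments$outcome == "rejected")
  result <- quantify(assignments, region, cfg)
  stages$genotypes_observed <- nrow(result$table)
  stages$genotypes_reported <- sum(result$table$retained)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_tsv(result, file.path(config$out_dir, "abundance.tsv"))
  write_rejection_tsv(result, file.path(config$out_dir, "rejections.tsv"))
  readr::write_tsv(
    dplyr::mutate(
      dplyr::select(assignments, "read_id", "outcome", "bitmask", "reason"),
      bitmask = ifelse(is.na(.data$bitmask), NA_character_,
                       format_mask(.data$bitmask))
    ),
    file.path(config$out_dir, "assignments.tsv")
  )

  manifest <- list(
    tool = "haplotally",
    version = as.character(packageVersion("haplotally")),
    config = c(config[setdiff(names(config), cfg_keys)], unclass(cfg)),
    input_md5 = as.list(tools::md5sum(inputs)),
    stages = stages,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(result, "manifest") <- manifest
  invisible(result)
}
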