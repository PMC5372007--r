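#' Per-genotype read counts and relative abundances
#'
#' Tallies assigned reads per genotype bitmask and computes each genotype's
#' relative abundance as `count / total_assigned * 100`, where
#' `total_assigned` counts every assigned read — including reads assigned to
#' genotypes that fall below the reporting threshold. Genotypes with fewer
#' than `min_genotype_coverage` supporting reads are excluded from the
#' reported table but their reads stay in the denominator.
#'
#' @param assignments Tibble from [assign_reads()] (columns `outcome`,
#'   `bitmask`, `reason`).
#' @param region A [barcode_region()]; supplies the genotype name label.
#' @param config A [pipeline_config()]; supplies the coverage threshold.
#' @return An object of class `abundance_table`. Use [tidy()] for the
#'   reported rows, `tidy(x, all = TRUE)` to include sub-threshold
#'   genotypes, and [glance()] for totals.
#' @examples
#' cfg <- pipeline_config(min_genotype_coverage = 1)
#' quantify_counts(tibble::tibble(bitmask = c(1, 0), reads = c(104065, 87689)),
#'                 label = "BRO-A", config = cfg)
#' @export
quantify <- function(assignments, region, config = pipeline_config()) {
  assigned <- assignments[assignments$outcome == "assigned", , drop = FALSE]
  counts <- count(assigned, .data$bitmask, name = "reads")
  rejected <- assignments[assignments$outcome == "rejected", , drop = FALSE]
  rejection_summary <- count(rejected, .data$reason, name = "n_reads")
  quantify_counts(
    counts,
    label = region$label,
    config = config,
    total_rejected = nrow(rejected),
    rejection_summary = rejection_summary
  )
}

#' @rdname quantify
#' @param counts Tibble with `bitmask` and `reads` columns — e.g. re-ingested
#'   from a per-read assignment TSV, or a published count table.
#' @param label Genotype name prefix.
#' @param total_rejected,rejection_summary Optional rejection bookkeeping to
#'   carry into the result.
#' @export
quantify_counts <- function(counts, label = "region",
                            config = pipeline_config(),
                            total_rejected = 0L,
                            rejection_summary = NULL) {
  total_assigned <- sum(counts$reads)
  if (total_assigned == 0) {
    warn("no reads were assigned to any genotype; the abundance table is empty")
    tab <- tibble(
      genotype = character(), bitmask = numeric(), reads = numeric(),
      relative_abundance = numeric(), retained = logical()
    )
  } else {
    tab <- counts |>
      mutate(
        genotype = genotype_name(label, .data$bitmask),
        relative_abundance = round(.data$reads / total_assigned * 100, 2),
        retained = .data$reads >= config$min_genotype_coverage
      ) |>
      arrange(desc(.data$reads), .data$bitmask) |>
      dplyr::relocate("genotype", "bitmask", "reads", "relative_abundance",
                      "retained")
  }
  structure(
    list(
      table = tab,
      label = label,
      total_assigned = total_assigned,
      total_rejected = as.integer(total_rejected),
      rejection_summary = rejection_summary %||%
        tibble(reason = character(), n_reads = integer()),
      threshold_used = config$min_genotype_coverage
    ),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf(
    "<abundance_table> %s: %d genotype(s) reported at >= %dx coverage (%s of %s assigned reads; %s rejected)\n",
    x$label, sum(x$table$retained),
    as.integer(x$threshold_used),
    format(sum(x$table$reads[x$table$retained]), big.mark = ","),
    format(x$total_assigned, big.mark = ","),
    format(x$total_rejected, big.mark = ",")
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' Reported abundance rows of an `abundance_table`
#'
#' @param x An `abundance_table` from [quantify()].
#' @param all If `TRUE`, include genotypes below the coverage threshold
#'   (these never contribute rows to the reported table but always
#'   contribute reads to the denominator).
#' @param ... Unused.
#' @return A tibble with `genotype`, `bitmask`, `reads`,
#'   `relative_abundance` (percent, 2 decimals), sorted by descending reads.
#' @method tidy abundance_table
#' @export
tidy.abundance_table <- function(x, all = FALSE, ...) {
  tab <- if (all) x$table else x$table[x$table$retained, , drop = FALSE]
  dplyr::select(tab, -"retained")
}

#' One-row summary of an `abundance_table`
#'
#' @param x An `abundance_table`.
#' @param ... Unused.
#' @return A tibble with totals, the coverage threshold, and the number of
#'   genotypes observed and reported.
#' @method glance abundance_table
#' @export
glance.abundance_table <- function(x, ...) {
  tibble(
    label = x$label,
    total_assigned = x$total_assigned,
    total_rejected = x$total_rejected,
    n_genotypes_observed = nrow(x$table),
    n_genotypes_reported = sum(x$table$retained),
    threshold_used = x$threshold_used
  )
}

#' Write an abundance table as TSV
#'
#' Columns `Genotype`, `Reads`, `RelativeAbundancePct`, reported rows only.
#'
#' @param x An `abundance_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  out <- tidy(x) |>
    dplyr::select(Genotype = "genotype", Reads = "reads",
                  RelativeAbundancePct = "relative_abundance")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write the per-reason rejection summary as TSV
#'
#' @param x An `abundance_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rejection_tsv <- function(x, path) {
  readr::write_tsv(x$rejection_summary, path)
  invisible(path)
}
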