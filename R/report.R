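# Comparison reporting between two masking runs (e.g. two decontamination
# tools over the same database) and run manifests for reproducibility.

#' Compare two mask reports over the same database
#'
#' Tabulates per-genome cumulative masked lengths for each report, counts
#' genomes flagged (at least one masked base) by A only, B only, and both,
#' and builds the paired table of cumulative lengths restricted to genomes
#' flagged by both tools. Optionally adds a Wilcoxon signed-rank test on
#' the paired lengths.
#'
#' @param report_a,report_b \code{mask_report} objects (see
#'   [mask_database()]) over the same genome set.
#' @param wilcoxon add a paired Wilcoxon signed-rank test.
#' @return object of class \code{mask_comparison}: list with
#'   \code{per_genome} (genome, masked_a, masked_b), \code{n_both},
#'   \code{n_a_only}, \code{n_b_only}, \code{paired} (rows for genomes
#'   flagged by both), and optionally \code{wilcoxon_p}.
#' @export
compare_mask_reports <- function(report_a, report_b, wilcoxon = FALSE) {
  ga <- report_a$masked_bases_per_genome
  gb <- report_b$masked_bases_per_genome
  if (!setequal(names(ga), names(gb)))
    stop_contract("mask reports cover different genome sets")
  gb <- gb[names(ga)]
  per_genome <- data.frame(genome = names(ga), masked_a = as.numeric(ga),
                           masked_b = as.numeric(gb),
                           stringsAsFactors = FALSE, row.names = NULL)
  fa <- per_genome$masked_a > 0
  fb <- per_genome$masked_b > 0
  paired <- per_genome[fa & fb, , drop = FALSE]
  rownames(paired) <- NULL
  out <- list(per_genome = per_genome,
              n_both = sum(fa & fb),
              n_a_only = sum(fa & !fb),
              n_b_only = sum(fb & !fa),
              paired = paired)
  if (wilcoxon) {
    out$wilcoxon_p <- if (nrow(paired) > 0 &&
                          any(paired$masked_a != paired$masked_b)) {
      suppressWarnings(
        stats::wilcox.test(paired$masked_a, paired$masked_b,
                           paired = TRUE)$p.value)
    } else NA_real_
  }
  class(out) <- "mask_comparison"
  out
}

#' @export
print.mask_comparison <- function(x, ...) {
  cat("mask_comparison:", x$n_both, "genome(s) flagged by both,",
      x$n_a_only, "by A only,", x$n_b_only, "by B only\n")
  if (!is.null(x$wilcoxon_p))
    cat("paired Wilcoxon signed-rank p =", format(x$wilcoxon_p), "\n")
  invisible(x)
}

#' Write a run manifest
#'
#' Records the subcommand, its full argument vector, parameters, seeds,
#' MD5 digests of the input and output files, and a timestamp, as JSON.
#' A run can be reproduced byte-for-byte from its manifest with
#' [rerun_manifest()].
#'
#' @param path manifest output path.
#' @param subcommand subcommand name.
#' @param argv full CLI argument vector of the run.
#' @param params named list of parameters.
#' @param seeds named list or vector of the seeds used.
#' @param inputs,outputs character vectors of file paths to digest.
#' @return the manifest (a list), invisibly.
#' @export
write_manifest <- function(path, subcommand, argv = character(0),
                           params = list(), seeds = list(),
                           inputs = character(0), outputs = character(0)) {
  digest <- function(files) {
    files <- files[file.exists(files)]
    as.list(tools::md5sum(files))
  }
  manifest <- list(subcommand = subcommand, argv = as.character(argv),
                   params = params, seeds = seeds,
                   input_digests = digest(inputs),
                   output_digests = digest(outputs),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Re-run a CLI invocation from its manifest
#'
#' Re-dispatches the recorded argument vector through [mbrobust_main()] and
#' verifies that every recorded output digest is reproduced, returning the
#' comparison.
#'
#' @param path path to a manifest written by [write_manifest()].
#' @return data frame with columns \code{file}, \code{recorded},
#'   \code{reproduced}, \code{identical}.
#' @export
rerun_manifest <- function(path) {
  if (!file.exists(path)) stop_format("manifest not found: ", path)
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  status <- mbrobust_main(manifest$argv)
  if (status != 0L) stop_contract("rerun failed with status ", status)
  rec <- unlist(manifest$output_digests)
  now <- tools::md5sum(names(rec))
  data.frame(file = names(rec), recorded = unname(rec),
             reproduced = unname(now),
             identical = unname(rec == now),
             stringsAsFactors = FALSE, row.names = NULL)
}
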