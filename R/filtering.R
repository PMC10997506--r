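# Two-step conservative taxonomic filtering: (i) restrict to
# human-associated taxa via a whitelist, (ii) remove residual false
# positives with read/unique-k-mer thresholds (KrakenUniq-style output) or
# aggregate genome-coverage thresholds (direct genome alignments).

#' Normalise taxon labels
#'
#' Trims, collapses internal whitespace and lowercases, so membership tests
#' are robust to formatting differences between catalogues.
#'
#' @param x character vector of labels.
#' @return normalised character vector.
#' @export
normalize_taxon_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Build a human-association whitelist
#'
#' @param taxa character vector of human-associated taxon labels.
#' @param source optional character vector of the same length tagging where
#'   each taxon came from (e.g. an assembly catalogue, a decontaminated
#'   cohort, a pathogen list).
#' @return an object of class \code{whitelist}.
#' @export
whitelist <- function(taxa, source = NULL) {
  norm <- normalize_taxon_label(taxa)
  if (is.null(source)) source <- rep(NA_character_, length(taxa))
  keep <- !duplicated(norm)
  structure(list(taxa = norm[keep], label = taxa[keep], source = source[keep]),
            class = "whitelist")
}

#' Read a whitelist from TSV (taxon, optional source column)
#' @param path path to a headerless tab-separated file.
#' @return a \code{whitelist}.
#' @export
read_whitelist <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          colClasses = "character")
  whitelist(df[[1L]], if (ncol(df) >= 2L) df[[2L]] else NULL)
}

#' Intersect observed taxa with a human-association whitelist
#'
#' Labels are normalised before membership testing. Viral taxa can bypass
#' the whitelist (human-association catalogues are biased towards bacteria
#' and typically omit viruses and phages); bypassed taxa are flagged so that
#' downstream coverage filtering is understood to carry the full burden of
#' proof for them.
#'
#' @param taxa character vector of observed taxon labels.
#' @param wl a [whitelist()].
#' @param viral labels (subset of \code{taxa}) that are viral.
#' @param bypass_viral keep viral taxa regardless of whitelist membership.
#' @return list with \code{kept} (original labels), \code{viral_bypassed}
#'   (subset of kept retained only via the bypass) and \code{dropped}
#'   (data frame of taxon and reason).
#' @export
intersect_whitelist <- function(taxa, wl, viral = character(0),
                                bypass_viral = FALSE) {
  norm <- normalize_taxon_label(taxa)
  in_wl <- norm %in% wl$taxa
  is_viral <- norm %in% normalize_taxon_label(viral)
  keep <- in_wl | (bypass_viral & is_viral)
  dropped <- data.frame(
    taxon = taxa[!keep],
    reason = ifelse(is_viral[!keep], "viral, bypass disabled",
                    "not in whitelist"),
    stringsAsFactors = FALSE)
  list(kept = taxa[keep],
       viral_bypassed = taxa[keep & !in_wl],
       dropped = dropped)
}

#' Filter taxa by read and unique-k-mer thresholds
#'
#' A taxon passes if its read count and unique-k-mer count both meet their
#' thresholds (inclusive: the boundary values pass), under the chosen
#' aggregation over samples: \code{"any-sample"} (default) requires some
#' single sample to meet both thresholds; \code{"summed"} first sums counts
#' over samples.
#'
#' @param records data frame with columns \code{taxon}, \code{sample},
#'   \code{reads}, \code{unique_kmers}.
#' @param read_min minimum read count (default 10).
#' @param kmer_min minimum unique-k-mer count (default 1000).
#' @param aggregate aggregation mode, see above.
#' @return character vector of kept taxa, with the per-taxon decision table
#'   attached as attribute \code{"table"}.
#' @export
filter_krakenuniq <- function(records, read_min = 10, kmer_min = 1000,
                              aggregate = c("any-sample", "summed")) {
  aggregate <- match.arg(aggregate)
  if (!nrow(records)) stop_contract("empty taxon count table")
  if (any(records$reads < 0) || any(records$unique_kmers < 0))
    stop_contract("negative counts in taxon table")
  pass <- if (aggregate == "any-sample") {
    ok <- records$reads >= read_min & records$unique_kmers >= kmer_min
    tapply(ok, records$taxon, any)
  } else {
    r <- tapply(records$reads, records$taxon, sum)
    k <- tapply(records$unique_kmers, records$taxon, sum)
    r >= read_min & k >= kmer_min
  }
  tab <- data.frame(taxon = names(pass), pass = as.logical(pass),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(tab$taxon[tab$pass], table = tab)
}

#' Aggregate genome coverage across samples
#'
#' Per genome, takes the union of per-sample covered intervals over the
#' selected sample set and reports the fraction of the genome covered by at
#' least one read in at least one sample. Because per-sample interval sets
#' are simply unioned, per-subset coverages (e.g. by sample type) can be
#' recomputed from cached intervals without revisiting the alignments.
#'
#' @param hits data frame with columns \code{genome}, \code{start},
#'   \code{end} (0-based half-open) and optionally \code{sample}.
#' @param genome_lengths named numeric vector of genome lengths, or a
#'   [genome_set()] whose per-genome contig lengths are summed (genomes must
#'   then be single-contig for coordinates to be meaningful).
#' @param samples optional subset of samples to aggregate over.
#' @return data frame of class \code{coverage_table} with columns
#'   \code{genome_id}, \code{genome_length}, \code{covered_bases},
#'   \code{aggregate_fraction}; the union intervals are attached as
#'   attribute \code{"intervals"} (list keyed by genome).
#' @export
aggregate_coverage <- function(hits, genome_lengths, samples = NULL) {
  if (inherits(genome_lengths, "genome_set")) {
    gl <- tapply(nchar(genome_lengths$seqs), genome_lengths$genome, sum)
    genome_lengths <- stats::setNames(as.numeric(gl), names(gl))
  }
  if (!is.null(samples) && "sample" %in% names(hits))
    hits <- hits[hits$sample %in% samples, , drop = FALSE]
  unknown <- setdiff(unique(hits$genome), names(genome_lengths))
  if (length(unknown))
    stop_contract("hits refer to unknown genome(s): ",
                  paste(unknown, collapse = ", "))
  if (nrow(hits) &&
      (any(hits$start < 0) || any(hits$end > genome_lengths[hits$genome]) ||
       any(hits$end <= hits$start)))
    stop_contract("coverage interval out of bounds for its genome")
  ivs <- list()
  covered <- stats::setNames(numeric(length(genome_lengths)),
                             names(genome_lengths))
  for (g in unique(hits$genome)) {
    d <- hits[hits$genome == g, , drop = FALSE]
    u <- interval_union(d$start, d$end)
    ivs[[g]] <- u
    covered[[g]] <- sum(u$end - u$start)
  }
  out <- data.frame(genome_id = names(genome_lengths),
                    genome_length = as.numeric(genome_lengths),
                    covered_bases = as.numeric(covered),
                    aggregate_fraction = as.numeric(covered / genome_lengths),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("coverage_table", "data.frame")
  attr(out, "intervals") <- ivs
  out
}

#' Filter genomes and species by aggregate coverage
#'
#' A genome is kept iff its aggregate coverage fraction is at least
#' \code{threshold} (inclusive, so exactly 50\% passes the default 0.50
#' threshold). A species is kept if any of its constituent genomes passes
#' (databases occasionally carry more than one genome per species). An
#' exclusion list of species labels is applied after filtering, mirroring
#' manual curation steps.
#'
#' @param covs a \code{coverage_table} (see [aggregate_coverage()]),
#'   optionally with a \code{species} column; without one, each genome is
#'   its own species.
#' @param threshold coverage fraction in \code{(0, 1]}.
#' @param exclude species labels to drop after filtering (normalised before
#'   matching).
#' @return list with \code{genomes} (kept genome ids) and \code{species}
#'   (kept species labels, post-exclusion).
#' @export
filter_by_coverage <- function(covs, threshold = 0.50, exclude = character(0)) {
  if (!(threshold > 0 && threshold <= 1))
    stop_contract("threshold must be in (0, 1]")
  species <- if ("species" %in% names(covs)) covs$species else covs$genome_id
  pass <- covs$aggregate_fraction >= threshold
  sp_pass <- tapply(pass, species, any)
  kept_sp <- names(sp_pass)[as.logical(sp_pass)]
  kept_sp <- kept_sp[!(normalize_taxon_label(kept_sp) %in%
                         normalize_taxon_label(exclude))]
  kept_gen <- covs$genome_id[pass & !(normalize_taxon_label(species) %in%
                                        normalize_taxon_label(exclude))]
  list(genomes = kept_gen, species = kept_sp)
}
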