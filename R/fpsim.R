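# Simulation harness for estimating how many host-only reads leak through a
# host-depletion + database-mapping pipeline as false-positive microbial
# signal: paired-end read simulation from a host genome, subsampling,
# sequential depletion against host references, and mapping of the survivors
# against a (possibly contaminated) microbial database.

#' Read-simulation configuration
#'
#' Defaults mirror a 2 x 150 bp Illumina paired-end run with normally
#' distributed fragment lengths (mean 270 bp, sd 27 bp) at 1x fold coverage
#' and no sequencing error, seeded at 42; replicate samples increment the
#' seed by one.
#'
#' @param read_len read length in bases.
#' @param frag_mean,frag_sd fragment-length normal distribution, bases.
#' @param fold_coverage fold coverage; pairs per contig =
#'   \code{floor(fold_coverage * contig_len / (2 * read_len))}.
#' @param base_error_rate per-base substitution probability in \code{[0,1)};
#'   0 (default) gives error-free reads.
#' @param seed integer RNG seed.
#' @return an object of class \code{read_sim_config}.
#' @export
read_sim_config <- function(read_len = 150L, frag_mean = 270, frag_sd = 27,
                            fold_coverage = 1, base_error_rate = 0,
                            seed = 42L) {
  if (frag_sd < 0) stop_contract("frag_sd must be >= 0")
  if (base_error_rate < 0 || base_error_rate >= 1)
    stop_contract("base_error_rate must be in [0, 1)")
  if (frag_mean < read_len)
    warning("frag_mean < read_len: mates will overlap past full length")
  structure(list(read_len = as.integer(read_len), frag_mean = frag_mean,
                 frag_sd = frag_sd, fold_coverage = fold_coverage,
                 base_error_rate = base_error_rate, seed = as.integer(seed)),
            class = "read_sim_config")
}

apply_base_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    chars <- strsplit(reads[i], "")[[1L]]
    for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate paired-end reads from a genome
#'
#' For each contig, draws \code{floor(fold_coverage * len / (2 * read_len))}
#' fragments with uniformly random start positions and normally distributed
#' lengths (rounded, then truncated to \code{[read_len, contig_len - start]}).
#' The forward mate is the fragment prefix of \code{read_len} bases and the
#' reverse mate is the reverse complement of the fragment suffix.
#' Reproducible from \code{cfg$seed}.
#'
#' @param genome a [genome_set()]; contigs shorter than \code{read_len} are
#'   skipped with a warning.
#' @param cfg a [read_sim_config()].
#' @return data frame of class \code{read_pairs} with columns \code{id},
#'   \code{r1}, \code{r2}, \code{contig}, \code{frag_start} (0-based),
#'   \code{frag_end} (exclusive).
#' @export
simulate_read_pairs <- function(genome, cfg = read_sim_config()) {
  set.seed(cfg$seed)
  rl <- cfg$read_len
  lens <- contig_lengths(genome)
  short <- lens < rl
  if (any(short))
    warning("skipping ", sum(short), " contig(s) shorter than read_len")
  if (all(short)) stop_contract("no contig is at least read_len bases long")
  out <- list()
  for (ctg in names(lens)[!short]) {
    len <- lens[[ctg]]
    n_pairs <- floor(cfg$fold_coverage * len / (2 * rl))
    if (n_pairs < 1) next
    starts <- sample.int(len - rl + 1L, n_pairs, replace = TRUE) - 1L
    frag <- as.integer(round(stats::rnorm(n_pairs, cfg$frag_mean, cfg$frag_sd)))
    frag <- pmax(rl, pmin(frag, len - starts))
    seq <- genome$seqs[[ctg]]
    r1 <- substring(seq, starts + 1L, starts + rl)
    r2 <- revcomp(substring(seq, starts + frag - rl + 1L, starts + frag))
    r1 <- apply_base_errors(r1, cfg$base_error_rate)
    r2 <- apply_base_errors(r2, cfg$base_error_rate)
    out[[ctg]] <- data.frame(
      id = paste0(ctg, ":", starts, "-", starts + frag, ":", seq_len(n_pairs)),
      r1 = r1, r2 = r2, contig = ctg,
      frag_start = starts, frag_end = starts + frag,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop_contract("no contig long enough to yield a read pair")
  pairs <- do.call(rbind, out)
  rownames(pairs) <- NULL
  class(pairs) <- c("read_pairs", "data.frame")
  pairs
}

#' Subsample read pairs without replacement
#'
#' Uniform sample of \code{min(n, total)} pairs; mates are never split and
#' the original input order of the selected pairs is preserved.
#'
#' @param pairs a \code{read_pairs} data frame.
#' @param n number of pairs to keep.
#' @param seed integer RNG seed.
#' @return subsampled \code{read_pairs}.
#' @export
subsample_reads <- function(pairs, n, seed = 42L) {
  if (n < 0) stop_contract("n must be >= 0")
  set.seed(seed)
  keep <- sort(sample.int(nrow(pairs), min(n, nrow(pairs))))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact substring matcher for fixed-length reads
#'
#' Returns, for each read, whether it (or its reverse complement) occurs as
#' an exact substring of any contig in \code{gs}. This is the deterministic
#' built-in stand-in for a read aligner.
#'
#' @param reads character vector of reads.
#' @param gs a [genome_set()].
#' @return logical vector, one element per read.
#' @export
match_reads <- function(reads, gs) {
  hit <- logical(length(reads))
  if (!length(reads)) return(hit)
  rc <- revcomp(reads)
  for (k in unique(nchar(reads))) {
    subs <- unlist(lapply(gs$seqs, substrings_of, k = k), use.names = FALSE)
    sel <- nchar(reads) == k
    hit[sel] <- reads[sel] %in% subs | rc[sel] %in% subs
  }
  hit
}

#' Sequential host depletion of read pairs
#'
#' Applies each host reference in turn; after each reference a pair survives
#' only if neither mate matches that reference (the both-mates-unmapped
#' retention rule). Output order is stable.
#'
#' @param pairs a \code{read_pairs} data frame.
#' @param host_refs a [genome_set()] or list of them, applied sequentially.
#' @param matcher function \code{(reads, genome_set) -> logical}; defaults
#'   to the exact matcher [match_reads()].
#' @return the surviving \code{read_pairs}.
#' @export
host_deplete <- function(pairs, host_refs, matcher = match_reads) {
  if (inherits(host_refs, "genome_set")) host_refs <- list(host_refs)
  if (!length(host_refs)) {
    warning("no host references given; returning input unchanged")
    return(pairs)
  }
  for (ref in host_refs) {
    if (!nrow(pairs)) break
    drop <- matcher(pairs$r1, ref) | matcher(pairs$r2, ref)
    pairs <- pairs[!drop, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

#' Estimate the false-positive mapping rate of surviving reads
#'
#' Maps surviving (nominally host-only) read pairs against a microbial
#' database: a pair counts as mapped if either mate matches any database
#' contig, and the taxa hit are the distinct taxon labels of the genomes
#' with at least one matching read. With \code{per_read = TRUE} the
#' denominator becomes individual mates (2n) instead of pairs.
#'
#' @param pairs surviving \code{read_pairs}.
#' @param db microbial database [genome_set()].
#' @param taxon_of_genome named character vector mapping every genome id in
#'   \code{db} to a taxon label (typically genus).
#' @param matcher see [host_deplete()].
#' @param per_read count mapped mates over 2n instead of mapped pairs over n.
#' @return an object of class \code{fp_estimate}.
#' @export
estimate_fp_rate <- function(pairs, db, taxon_of_genome,
                             matcher = match_reads, per_read = FALSE) {
  if (!nrow(pairs)) stop_contract("no reads to evaluate")
  genomes <- unique(db$genome)
  missing <- setdiff(genomes, names(taxon_of_genome))
  if (length(missing))
    stop_contract("taxon_of_genome missing genome(s): ",
                  paste(missing, collapse = ", "))
  m1g <- m2g <- matrix(FALSE, nrow(pairs), length(genomes),
                       dimnames = list(NULL, genomes))
  for (g in genomes) {
    sub <- genome_set(db$seqs[db$genome == g])
    m1g[, g] <- matcher(pairs$r1, sub)
    m2g[, g] <- matcher(pairs$r2, sub)
  }
  m1 <- rowSums(m1g) > 0; m2 <- rowSums(m2g) > 0
  genome_hit <- colSums(m1g) + colSums(m2g) > 0
  taxa <- sort(unique(taxon_of_genome[genomes[genome_hit]]))
  n_total <- if (per_read) 2L * nrow(pairs) else nrow(pairs)
  n_mapped <- if (per_read) sum(m1) + sum(m2) else sum(m1 | m2)
  frac <- n_mapped / n_total
  structure(list(
    n_total = n_total, n_mapped = n_mapped, frac_mapped = frac,
    taxa_hit = taxa, n_taxa = length(taxa),
    per_replicate = data.frame(frac_mapped = frac, n_taxa = length(taxa)),
    mean_frac = frac, sd_frac = 0, mean_taxa = length(taxa), sd_taxa = 0
  ), class = "fp_estimate")
}

#' @export
print.fp_estimate <- function(x, ...) {
  cat(sprintf(
    "fp_estimate: %.6g%% of %s mapped (%d replicate(s)); %.3g +/- %.3g taxa\n",
    100 * x$mean_frac, format(x$n_total, big.mark = ","),
    nrow(x$per_replicate), x$mean_taxa, x$sd_taxa))
  invisible(x)
}

#' Run the full false-positive leakage experiment
#'
#' For each replicate: simulate host-only pairs (seed = \code{seed_start} +
#' replicate - 1), optionally subsample to \code{n_subsample} pairs (same
#' seed), sequentially deplete against \code{host_refs}, then map survivors
#' against \code{db} and record the mapped fraction and taxa hit. Pairs
#' removed by depletion still count in the denominator, mirroring a pipeline
#' that reports leakage per simulated read.
#'
#' @param host genome the reads are simulated from.
#' @param db microbial database to map against.
#' @param taxon_of_genome genome id -> taxon label map.
#' @param cfg a [read_sim_config()]; its seed is overridden per replicate.
#' @param host_refs references for sequential depletion (may be empty list).
#' @param n_subsample pairs to subsample per replicate (\code{Inf} = keep
#'   all).
#' @param replicates number of replicate samples.
#' @param seed_start seed of the first replicate; increments by 1 per
#'   sample.
#' @param per_read see [estimate_fp_rate()].
#' @return an \code{fp_estimate} aggregated over replicates.
#' @export
run_fp_simulation <- function(host, db, taxon_of_genome,
                              cfg = read_sim_config(), host_refs = list(),
                              n_subsample = Inf, replicates = 10L,
                              seed_start = 42L, per_read = FALSE) {
  per <- vector("list", replicates)
  all_taxa <- character(0)
  tot_total <- tot_mapped <- 0
  for (i in seq_len(replicates)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(seed_start + i - 1L)
    pairs <- simulate_read_pairs(host, cfg_i)
    if (is.finite(n_subsample))
      pairs <- subsample_reads(pairs, n_subsample, seed = cfg_i$seed)
    denom <- if (per_read) 2L * nrow(pairs) else nrow(pairs)
    surv <- if (length(host_refs)) host_deplete(pairs, host_refs) else pairs
    if (nrow(surv)) {
      est <- estimate_fp_rate(surv, db, taxon_of_genome, per_read = per_read)
      n_mapped <- est$n_mapped
      taxa <- est$taxa_hit
    } else {
      n_mapped <- 0L
      taxa <- character(0)
    }
    per[[i]] <- data.frame(frac_mapped = n_mapped / denom,
                           n_taxa = length(taxa))
    all_taxa <- union(all_taxa, taxa)
    tot_total <- tot_total + denom
    tot_mapped <- tot_mapped + n_mapped
  }
  per <- do.call(rbind, per)
  structure(list(
    n_total = tot_total, n_mapped = tot_mapped,
    frac_mapped = tot_mapped / tot_total,
    taxa_hit = sort(all_taxa), n_taxa = length(all_taxa),
    per_replicate = per,
    mean_frac = mean(per$frac_mapped),
    sd_frac = if (nrow(per) > 1L) stats::sd(per$frac_mapped) else 0,
    mean_taxa = mean(per$n_taxa),
    sd_taxa = if (nrow(per) > 1L) stats::sd(per$n_taxa) else 0
  ), class = "fp_estimate")
}

#' Write read pairs as a pair of FASTQ files
#'
#' Four-line records with a constant quality string of \code{I} (Phred 40),
#' the convention used for the simulator's error-free reads.
#'
#' @param pairs a \code{read_pairs} data frame.
#' @param r1_path,r2_path output paths for the forward and reverse mates.
#' @return invisibly, \code{c(r1_path, r2_path)}.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  fq <- function(ids, seqs, path) {
    qual <- strrep("I", nchar(seqs))
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  }
  fq(paste0(pairs$id, "/1"), pairs$r1, r1_path)
  fq(paste0(pairs$id, "/2"), pairs$r2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files back into a read-pair table
#'
#' @param r1_path,r2_path FASTQ paths for forward and reverse mates.
#' @return a \code{read_pairs} data frame (ground-truth origin columns are
#'   \code{NA}: FASTQ does not carry them).
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  rd <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
      stop_format("FASTQ file ", path, " is not made of 4-line records")
    list(id = sub("^@", "", sub("/[12]$", "", lines[c(TRUE, FALSE, FALSE, FALSE)])),
         seq = toupper(lines[c(FALSE, TRUE, FALSE, FALSE)]))
  }
  a <- rd(r1_path); b <- rd(r2_path)
  if (!identical(a$id, b$id))
    stop_format("mate files disagree on read ids or order")
  out <- data.frame(id = a$id, r1 = a$seq, r2 = b$seq,
                    contig = NA_character_, frag_start = NA_integer_,
                    frag_end = NA_integer_, stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Exact expected mapped fraction for a planted shared segment
#'
#' Closed-form companion to [run_fp_simulation()]: enumerates every fragment
#' placement the simulator can draw from a single-contig host and computes
#' the exact probability that at least one sampled mate lies wholly inside
#' the host interval \code{[seg_start, seg_end)} that was copied into the
#' database. Fragment lengths follow the simulator's rounded, truncated
#' normal exactly (probability mass of the clamps included).
#'
#' @param host_len host contig length.
#' @param seg_start,seg_end 0-based half-open host coordinates of the shared
#'   segment.
#' @param cfg a [read_sim_config()].
#' @return expected mapped fraction of pairs (a probability).
#' @export
expected_fp_fraction <- function(host_len, seg_start, seg_end,
                                 cfg = read_sim_config()) {
  rl <- cfg$read_len
  starts <- 0:(host_len - rl)       # uniform fragment starts
  p_total <- 0
  for (s in starts) {
    r1_in <- (s >= seg_start) && (s + rl <= seg_end)
    if (r1_in) { p_total <- p_total + 1; next }
    # r2 spans [s + frag - rl, s + frag); in segment iff frag in a range
    lo <- max(rl, seg_start + rl - s)
    hi <- min(host_len - s, seg_end - s)
    if (lo > hi) next
    p_total <- p_total + frag_len_prob_range(lo, hi, rl, host_len - s, cfg)
  }
  p_total / length(starts)
}

# P(fragment length lands in [lo, hi]) where the length is a rounded
# normal clamped to [rl, max_len]. The clamped variable's CDF is piecewise
# pnorm: F(k) = 0 for k < rl, pnorm(k + 0.5) for rl <= k < max_len, and 1
# for k >= max_len (clamp mass absorbed at the boundaries).
frag_len_prob_range <- function(lo, hi, rl, max_len, cfg) {
  cdf <- function(k) {
    if (k < rl) return(0)
    if (k >= max_len) return(1)
    stats::pnorm(k + 0.5, cfg$frag_mean, cfg$frag_sd)
  }
  max(0, cdf(hi) - cdf(lo - 1L))
}
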