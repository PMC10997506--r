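# Synthetic fixtures with known ground truth: planted-contamination
# databases for the masking pipeline, importance-vector pairs with
# controlled concordance for the statistics, and taxon tables straddling
# the filtering thresholds. Everything is reproducible from its seed.

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a database with planted host-identical segments
#'
#' Builds a uniform-random host genome and a uniform-random multi-genome
#' database, then copies \code{n_segments} host segments into the database
#' at recorded positions. Generation guarantees (by substring checking,
#' with regeneration on collision) that database sequence outside the
#' planted segments shares no substring of length \code{min_len} or more
#' with the host, so every masked base is attributable to a planted
#' segment. Directly at segment junctions a planted match may chance-extend
#' by a few bases (each flank base agrees with the host's continuation with
#' probability 1/4); such extensions are orders of magnitude below the
#' window scale and cannot create or move window-level matches. With
#' \code{grid_aligned = TRUE}, segment host positions are multiples of the
#' window step and segment lengths are multiples of the step and at least
#' \code{window_len}, which guarantees the overlapping window tiling
#' recovers each planted span exactly.
#'
#' @param n_genomes number of database genomes (one contig each).
#' @param genome_length length of each database genome, bases.
#' @param host_length host genome length, bases.
#' @param n_segments number of planted segments.
#' @param segment_length planted segment length (scalar or vector of length
#'   \code{n_segments}).
#' @param grid_aligned align segments to the window grid (see above).
#' @param window_len,step,min_len window geometry the fixture is built for.
#' @param seed integer RNG seed.
#' @param max_tries regeneration attempts before giving up.
#' @return object of class \code{planted_database}: list with \code{db} and
#'   \code{host} ([genome_set()]s), \code{truth} (data frame of db-coordinate
#'   intervals with the host provenance), and \code{params}.
#' @export
make_planted_database <- function(n_genomes = 3L, genome_length = 5000L,
                                  host_length = 10000L, n_segments = 2L,
                                  segment_length = 300L,
                                  grid_aligned = FALSE, window_len = 150L,
                                  step = 75L, min_len = 75L, seed = 1L,
                                  max_tries = 20L) {
  if (any(segment_length < 1L)) stop_contract("segment lengths must be >= 1")
  segment_length <- rep_len(as.integer(segment_length), max(n_segments, 1L))
  if (grid_aligned) {
    bad <- segment_length %% step != 0L | segment_length < window_len
    if (any(bad))
      stop_contract("grid-aligned segments need length >= window_len and a multiple of step")
  }
  if (any(segment_length > genome_length) || any(segment_length > host_length))
    stop_contract("segments must fit inside both host and database genomes")
  set.seed(seed)
  margin <- window_len  # keep planted copies clear of ends and of each other
  for (try in seq_len(max_tries)) {
    host <- genome_set(stats::setNames(random_sequence(host_length), "host1"))
    db_ids <- sprintf("g%02d", seq_len(n_genomes))
    db_seqs <- stats::setNames(
      vapply(db_ids, function(i) random_sequence(genome_length), ""), db_ids)
    truth <- data.frame(contig = character(0), start = integer(0),
                        end = integer(0), host_start = integer(0),
                        stringsAsFactors = FALSE)
    ok <- TRUE
    if (n_segments > 0L) {
      host_used <- db_used <- list()
      for (j in seq_len(n_segments)) {
        len <- segment_length[j]
        placed <- FALSE
        for (attempt in 1:200) {
          hs <- if (grid_aligned) {
            step * sample.int((host_length - len - margin) %/% step, 1L)
          } else {
            sample.int(host_length - len - 2L * margin, 1L) + margin
          }
          ctg <- sample(db_ids, 1L)
          ds <- sample.int(genome_length - len - 2L * margin, 1L) + margin
          clash <- any(vapply(host_used, function(iv)
            hs < iv[2L] + margin && iv[1L] < hs + len + margin, TRUE)) ||
            any(vapply(db_used, function(iv)
              iv[3L] == ctg && ds < as.integer(iv[2L]) + margin &&
                as.integer(iv[1L]) < ds + len + margin, TRUE))
          if (!clash) {
            host_used[[j]] <- c(hs, hs + len)
            db_used[[j]] <- c(ds, ds + len, ctg)
            seg <- substr(host$seqs[["host1"]], hs + 1L, hs + len)
            substr(db_seqs[[ctg]], ds + 1L, ds + len) <- seg
            truth <- rbind(truth, data.frame(
              contig = ctg, start = ds, end = ds + len, host_start = hs,
              stringsAsFactors = FALSE))
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    truth <- truth[order(truth$contig, truth$start, method = "radix"), ,
                   drop = FALSE]
    rownames(truth) <- NULL
    db <- genome_set(db_seqs)
    if (planted_db_clean(db, host, truth, min_len)) {
      return(structure(list(
        db = db, host = host, truth = truth,
        params = list(n_genomes = n_genomes, genome_length = genome_length,
                      host_length = host_length, n_segments = n_segments,
                      segment_length = segment_length,
                      grid_aligned = grid_aligned, window_len = window_len,
                      step = step, min_len = min_len, seed = seed)
      ), class = "planted_database"))
    }
  }
  stop_contract("could not generate a collision-free fixture in ", max_tries,
                " tries at the requested sizes")
}

# Invariant check: every db k-mer (k = min_len) lying wholly outside the
# planted segments must be absent from the host (both strands), so
# background sequence cannot create unplanted matches. K-mers overlapping a
# segment are exempt: a random flank base agrees with the host's
# continuation with probability 1/4, so planted matches routinely chance-
# extend by a few bases, which is far below the window scale (extending a
# window-level match would need >= min_len consecutive chance agreements).
planted_db_clean <- function(db, host, truth, min_len) {
  host_k <- unlist(lapply(host$seqs, substrings_of, k = min_len),
                   use.names = FALSE)
  host_k <- unique(c(host_k, revcomp(host_k)))
  for (ctg in names(db$seqs)) {
    kmers <- substrings_of(db$seqs[[ctg]], min_len)
    if (!length(kmers)) next
    pos <- seq_along(kmers) - 1L
    outside <- rep(TRUE, length(kmers))
    tr <- truth[truth$contig == ctg, , drop = FALSE]
    for (j in seq_len(nrow(tr)))
      outside <- outside & (pos + min_len <= tr$start[j] | pos >= tr$end[j])
    if (any(kmers[outside] %in% host_k)) return(FALSE)
  }
  TRUE
}

#' Generate a pair of importance vectors with controlled concordance
#'
#' Model A uses \code{k_used[1]} features with strictly decreasing scores.
#' Model B uses \code{overlap} of A's features plus fresh ones; B's ranking
#' of the shared features is A's, perturbed by one pass of adjacent swaps
#' each applied with probability \code{rank_noise}, with fresh features
#' interleaved at random ranks. \code{overlap = NULL} draws B's feature set
#' independently of A (the null configuration for type-I-error studies).
#'
#' Defaults reflect a genus-level cancer-microbiome feature space: a shared
#' universe of 428 features with 50 used per model.
#'
#' @param n_features size of the shared feature universe.
#' @param k_used features used per model (scalar, or length 2 for A and B).
#' @param overlap number of jointly used features, or \code{NULL} for
#'   independent draws.
#' @param rank_noise adjacent-swap probability for B's shared-feature
#'   ranking.
#' @param seed integer RNG seed.
#' @return list with named score vectors \code{a} and \code{b} over the
#'   full universe (unused features score 0).
#' @export
make_importance_pair <- function(n_features = 428L, k_used = 50L,
                                 overlap = NULL, rank_noise = 0,
                                 seed = 1L) {
  k_used <- rep_len(as.integer(k_used), 2L)
  if (any(k_used > n_features) || any(k_used < 1L))
    stop_contract("k_used must be in [1, n_features]")
  if (!is.null(overlap) && (overlap > min(k_used) || overlap < 0L))
    stop_contract("overlap must be in [0, min(k_used)]")
  set.seed(seed)
  features <- sprintf("f%04d", seq_len(n_features))
  a_used <- sample(features, k_used[1L])   # order = A's ranking
  if (is.null(overlap)) {
    b_draw <- sample(features, k_used[2L])
    shared <- intersect(b_draw, a_used)
    fresh <- setdiff(b_draw, a_used)
  } else {
    shared <- if (overlap > 0L) sample(a_used, overlap) else character(0)
    fresh <- if (k_used[2L] > overlap)
      sample(setdiff(features, a_used), k_used[2L] - overlap)
    else character(0)
  }
  # B's shared ranking: A's relative order with adjacent swaps
  b_shared <- a_used[a_used %in% shared]
  if (length(b_shared) > 1L && rank_noise > 0) {
    for (i in seq_len(length(b_shared) - 1L)) {
      if (stats::runif(1L) < rank_noise) {
        tmp <- b_shared[i]; b_shared[i] <- b_shared[i + 1L]; b_shared[i + 1L] <- tmp
      }
    }
  }
  b_order <- b_shared
  if (length(fresh)) {
    slots <- sort(sample.int(length(b_shared) + length(fresh), length(fresh)))
    b_order <- character(length(b_shared) + length(fresh))
    b_order[slots] <- sample(fresh)
    b_order[-slots] <- b_shared
  }
  mk <- function(order_used) {
    v <- stats::setNames(numeric(n_features), features)
    v[order_used] <- rev(seq_along(order_used))  # decreasing scores
    v
  }
  list(a = mk(a_used), b = mk(b_order))
}

#' Generate a taxon count table and coverage truth straddling thresholds
#'
#' Builds a KrakenUniq-style count table with taxa placed deliberately on
#' both sides of the read (10) and unique-k-mer (1000) thresholds,
#' including the exact boundary, and a per-genome coverage interval set
#' with known aggregate fractions around the 0.50 / 0.75 / 0.90 coverage
#' thresholds. The expected pass sets are recorded at construction.
#'
#' @param n_background additional random taxa comfortably above or below
#'   both thresholds.
#' @param read_min,kmer_min thresholds the table straddles.
#' @param genome_length length of each synthetic genome in the coverage
#'   table.
#' @param seed integer RNG seed.
#' @return list with \code{counts} (taxon, sample, reads, unique_kmers),
#'   \code{coverage_hits} (genome, start, end, sample),
#'   \code{genome_lengths}, and \code{expected}: \code{kraken_pass} plus
#'   \code{coverage_pass} (a list keyed by threshold).
#' @export
make_taxon_table <- function(n_background = 10L, read_min = 10L,
                             kmer_min = 1000L, genome_length = 1000L,
                             seed = 1L) {
  set.seed(seed)
  fixed <- data.frame(
    taxon = c("t_boundary", "t_low_reads", "t_low_kmers", "t_high",
              "t_low_both"),
    reads = c(read_min, read_min - 1L, read_min * 10L, read_min * 50L, 1L),
    unique_kmers = c(kmer_min, kmer_min * 10L, kmer_min - 1L,
                     kmer_min * 5L, 10L),
    pass = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  bg_pass <- stats::runif(n_background) < 0.5
  bg <- data.frame(
    taxon = sprintf("bg%03d", seq_len(n_background)),
    reads = ifelse(bg_pass, read_min + sample.int(200L, n_background, TRUE),
                   sample.int(read_min - 1L, n_background, TRUE)),
    unique_kmers = ifelse(bg_pass,
                          kmer_min + sample.int(5000L, n_background, TRUE),
                          sample.int(kmer_min - 1L, n_background, TRUE)),
    pass = bg_pass, stringsAsFactors = FALSE)
  tab <- rbind(fixed, bg)
  counts <- data.frame(taxon = tab$taxon, sample = "s1", reads = tab$reads,
                       unique_kmers = tab$unique_kmers,
                       stringsAsFactors = FALSE)
  # Coverage truth: single interval per (genome, sample) giving exact
  # fractions on both sides of each threshold.
  frac <- c(g_cov_050 = 0.50, g_cov_0499 = 0.499, g_cov_075 = 0.75,
            g_cov_0749 = 0.749, g_cov_090 = 0.90, g_cov_0899 = 0.899,
            g_cov_full = 1.00, g_cov_zero = 0)
  hits <- do.call(rbind, lapply(names(frac)[frac > 0], function(g) {
    covered <- round(frac[[g]] * genome_length)
    # split across two samples with an overlap so the union is exercised
    a_end <- ceiling(covered * 0.6)
    b_start <- max(0L, a_end - round(covered * 0.1))
    data.frame(genome = g,
               start = c(0L, b_start), end = c(a_end, covered),
               sample = c("sA", "sB"), stringsAsFactors = FALSE)
  }))
  genome_lengths <- stats::setNames(rep(genome_length, length(frac)),
                                    names(frac))
  coverage_pass <- lapply(c(0.50, 0.75, 0.90), function(th)
    names(frac)[frac >= th])
  names(coverage_pass) <- c("0.5", "0.75", "0.9")
  list(counts = counts, coverage_hits = hits,
       genome_lengths = genome_lengths,
       expected = list(kraken_pass = sort(tab$taxon[tab$pass]),
                       coverage_pass = coverage_pass))
}
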