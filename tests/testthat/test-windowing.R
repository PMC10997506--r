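test_that("genome ingest uppercases, validates alphabet and contig ids", {
  gs <- genome_set(c(c1 = "acgtn"))
  expect_equal(gs$seqs[["c1"]], "ACGTN")
  expect_error(genome_set(c(c1 = "ACGX")), "non-ACGTN character at offset 4")
  expect_error(genome_set(c(c1 = "ACGT", c1 = "ACGT")), "duplicate contig ids")
  expect_error(genome_set(stats::setNames("ACGT", "")), "nonempty id")
})

test_that("FASTA round-trip preserves sequences and wraps at 60", {
  gs <- random_gs(2, 130)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(gs, path)
  lines <- readLines(path)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  expect_identical(read_fasta(path)$seqs, gs$seqs)
})

test_that("window enumeration follows the 150/75 grid with tail and N rules", {
  gs <- genome_set(c(c1 = strrep("ACGT", 75)))  # 300 bp
  w <- generate_windows(gs)
  expect_equal(w$start, c(0, 75, 150, 225))
  expect_equal(w$end, c(150, 225, 300, 300))
  expect_equal(w$sequence[4], substr(gs$seqs[[1]], 226, 300))
  expect_equal(w$window_id, paste0("c1:", c(0, 75, 150, 225)))

  # below min_len: no windows
  expect_equal(nrow(generate_windows(genome_set(c(c = strrep("A", 74))))), 0)

  # exactly max_n Ns: the full window is dropped; the 75 bp tail window has
  # only 75 Ns and survives both rules
  gsn <- genome_set(c(c = paste0(strrep("A", 50), strrep("N", 100))))
  wn <- generate_windows(gsn)
  expect_equal(wn$start, 75)
  # one fewer N in the full window: kept alongside the tail
  gsn2 <- genome_set(c(c = paste0(strrep("A", 51), strrep("N", 99))))
  expect_equal(nrow(generate_windows(gsn2)), 2)
  # an all-N contig yields no window once max_n binds on every candidate
  gsn3 <- genome_set(c(c = strrep("N", 300)))
  expect_equal(nrow(generate_windows(gsn3, max_n = 75)), 0)
})

test_that("exact matcher reports all occurrences on both strands in order", {
  hit <- find_exact_matches("ACGT", genome_set(c(x = "TTACGTTT")))
  expect_equal(nrow(hit), 1)  # palindromic query: one physical occurrence
  expect_equal(hit$pos, 3)
  expect_equal(hit$strand, "+")

  hit <- find_exact_matches("AAAC", genome_set(c(x = "TTGTTTAA")))
  expect_equal(hit$pos, 3)
  expect_equal(hit$strand, "-")

  expect_equal(nrow(find_exact_matches("GGGG", genome_set(c(x = "AAAA")))), 0)

  # overlapping occurrences all reported
  hit <- find_exact_matches("AAA", genome_set(c(x = "AAAAA")))
  expect_equal(hit$pos[hit$strand == "+"], 1:3)
})

test_that("hit-to-interval conversion, clipping and awk compatibility mode", {
  db <- genome_set(c(long = strrep("A", 400), short = strrep("A", 200)))
  hit <- function(ctg, pos, len) data.frame(
    query_id = "q", ref_contig = ctg, pos = pos, seq_len = len,
    strand = "+", stringsAsFactors = FALSE)

  std <- hits_to_intervals(hit("long", 100, 150), db)
  expect_equal(c(std$start, std$end), c(99, 249))

  clipped <- hits_to_intervals(hit("short", 100, 150), db)
  expect_equal(c(clipped$start, clipped$end), c(99, 200))

  awk <- hits_to_intervals(hit("long", 100, 150), db, awk_compat = TRUE)
  expect_equal(c(awk$start, awk$end), c(100, 250))

  expect_error(hits_to_intervals(hit("nope", 1, 10), db), "unknown contig")
  expect_error(hits_to_intervals(hit("long", 500, 10), db), "beyond contig")
})

test_that("duplicate records are removed and output is sorted", {
  db <- genome_set(c(c = strrep("A", 100)))
  hits <- data.frame(query_id = c("q1", "q1", "q2"),
                     ref_contig = "c", pos = c(10, 10, 5),
                     seq_len = 20, strand = "+", stringsAsFactors = FALSE)
  prec <- hits_to_intervals(hits, db)
  expect_equal(nrow(prec), 2)
  expect_equal(prec$start, c(4, 9))
})

test_that("interval merging is bedtools-like: overlap and book-ended, with support", {
  mk <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(contig = "c", start = m[, 1], end = m[, 2],
               stringsAsFactors = FALSE)
  }
  expect_equal(merge_intervals(mk(0, 10, 5, 15))[, c("start", "end", "support")],
               data.frame(start = 0L, end = 15L, support = 2L))
  expect_equal(merge_intervals(mk(0, 10, 10, 20))[, c("start", "end", "support")],
               data.frame(start = 0L, end = 20L, support = 2L))
  two <- merge_intervals(mk(0, 10, 12, 20))
  expect_equal(nrow(two), 2)
  expect_equal(two$support, c(1L, 1L))
  # containment: a short interval inside a long one
  expect_equal(merge_intervals(mk(0, 50, 10, 20, 30, 60))$end, 60L)

  expect_error(merge_intervals(mk(12, 20, 0, 10)), "not sorted")
})

test_that("merged intervals agree with GenomicRanges reduce on random input", {
  skip_if_not_installed("GenomicRanges")
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    start <- sample(0:500, n, replace = TRUE)
    width <- sample(1:60, n, replace = TRUE)
    prec <- data.frame(contig = sample(c("a", "b"), n, replace = TRUE),
                       start = start, end = start + width,
                       stringsAsFactors = FALSE)
    prec <- prec[order(prec$contig, prec$start, method = "radix"), ]
    got <- merge_intervals(prec)
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      prec$contig, IRanges::IRanges(prec$start + 1, prec$end)))
    gr <- BiocGenerics::sort(gr)
    expect_equal(got$start, BiocGenerics::start(gr) - 1)
    expect_equal(got$end, BiocGenerics::end(gr))
  }
})

test_that("masking replaces exactly the interval bases and reports totals", {
  gs <- genome_set(c(c = "ACGTACGT"))
  rep <- mask_database(gs, data.frame(contig = "c", start = 2, end = 5))
  expect_equal(rep$masked_db$seqs[["c"]], "ACNNNCGT")
  expect_equal(rep$total_masked_bases, 3)
  expect_equal(rep$genomes_affected, 1)

  # identity on empty interval list
  rep0 <- mask_database(gs, data.frame(contig = character(0),
                                       start = integer(0), end = integer(0)))
  expect_identical(rep0$masked_db$seqs, gs$seqs)
  expect_equal(rep0$genomes_affected, 0)

  # whole-contig interval
  repf <- mask_database(gs, data.frame(contig = "c", start = 0, end = 8))
  expect_equal(repf$masked_db$seqs[["c"]], strrep("N", 8))
  expect_equal(repf$total_masked_bases, 8)

  expect_error(mask_database(gs, data.frame(contig = "c", start = 0, end = 9)),
               "out of bounds")

  # idempotence
  rep2 <- mask_database(rep$masked_db, data.frame(contig = "c", start = 2, end = 5))
  expect_identical(rep2$masked_db$seqs, rep$masked_db$seqs)
})

test_that("full pipeline recovers a grid-aligned planted segment exactly", {
  fx <- make_planted_database(n_segments = 1, segment_length = 300,
                              grid_aligned = TRUE, seed = 3)
  rep <- run_exhaustive(fx$host, fx$db)
  expect_equal(rep$intervals[c("contig", "start", "end")],
               fx$truth[c("contig", "start", "end")],
               ignore_attr = TRUE)
  expect_equal(rep$total_masked_bases, 300)
})

test_that("databases with no shared window-length substring are untouched", {
  fx <- make_planted_database(n_segments = 0, seed = 5)
  rep <- run_exhaustive(fx$host, fx$db)
  expect_equal(nrow(rep$intervals), 0)
  expect_equal(rep$total_masked_bases, 0)
  expect_identical(rep$masked_db$seqs, fx$db$seqs)
})

test_that("off-grid planted segments may under-cover edges by up to step-1 per side", {
  # Segments planted off the host window grid: only windows lying fully
  # inside the copied span can match, so the mask is a sub-span of truth
  # with each edge short by at most step - 1 bases.
  for (seed in c(23, 24, 25)) {
    fx <- make_planted_database(n_segments = 1, segment_length = 300,
                                grid_aligned = FALSE, seed = seed)
    rep <- run_exhaustive(fx$host, fx$db)
    tr <- fx$truth
    expect_equal(nrow(rep$intervals), 1)
    expect_gte(rep$intervals$start, tr$start)
    expect_lte(rep$intervals$end, tr$end)
    expect_lt(rep$intervals$start - tr$start, 75)
    expect_lt(tr$end - rep$intervals$end, 75)
  }
})

test_that("masking conserves contig lengths and non-N base count", {
  fx <- make_planted_database(seed = 9)
  rep <- run_exhaustive(fx$host, fx$db)
  expect_identical(nchar(rep$masked_db$seqs), nchar(fx$db$seqs))
  non_n <- function(gs) sum(nchar(gsub("N", "", gs$seqs)))
  expect_equal(non_n(fx$db) - non_n(rep$masked_db), rep$total_masked_bases)
})

test_that("adding reference sequence never decreases the masked-base count", {
  fx <- make_planted_database(n_segments = 2, seed = 13)
  half_host <- genome_set(c(host1 = substr(fx$host$seqs[[1]], 1, 5000)))
  m_half <- run_exhaustive(half_host, fx$db)$total_masked_bases
  m_full <- run_exhaustive(fx$host, fx$db)$total_masked_bases
  expect_gte(m_full, m_half)
})

test_that("pipeline outputs are byte-identical across reruns", {
  fx <- make_planted_database(seed = 17)
  outs <- replicate(2, {
    bed <- tempfile(fileext = ".bed"); fa <- tempfile(fileext = ".fasta")
    run_exhaustive(fx$host, fx$db, bed_out = bed, fasta_out = fa)
    c(bed = unname(tools::md5sum(bed)), fa = unname(tools::md5sum(fa)))
  })
  expect_identical(outs[, 1], outs[, 2])
})

test_that("SAM ingestion consults only the needed columns and flag bits", {
  sam <- c(
    "@HD\tVN:1.6",
    paste("w1", 0, "g01", 11, 60, "20M", "*", 0, 0, strrep("A", 20), "*",
          sep = "\t"),
    paste("w2", 4, "*", 0, 0, "*", "*", 0, 0, strrep("C", 20), "*",
          sep = "\t"),                                     # unmapped: skipped
    paste("w3", 256, "g01", 31, 0, "20M", "*", 0, 0, strrep("G", 20), "*",
          sep = "\t"),                                     # secondary: kept
    paste("w4", 16, "g01", 51, 60, "20M", "*", 0, 0, strrep("T", 20), "*",
          sep = "\t"))
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  hits <- read_sam_hits(path)
  expect_equal(hits$query_id, c("w1", "w3", "w4"))
  expect_equal(hits$pos, c(11, 31, 51))
  expect_equal(hits$strand, c("+", "+", "-"))
  expect_equal(hits$seq_len, rep(20, 3))

  hits2 <- read_sam_hits(path, exclude_secondary = TRUE)
  expect_equal(hits2$query_id, c("w1", "w4"))

  # pipeline consumes external SAM instead of the built-in matcher
  db <- genome_set(c(g01 = strrep("ACGT", 30)))
  rep <- run_exhaustive(NULL, db, sam = path)
  expect_equal(rep$total_masked_bases,
               sum(rep$intervals$end - rep$intervals$start))
})
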