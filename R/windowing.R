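# Exhaustive masking of host-derived sequence in microbial reference
# databases: tile the host reference into overlapping windows, locate every
# exact occurrence of each window in the database, convert hits to intervals,
# merge, and replace the merged spans with Ns.

#' Generate overlapping windows from a reference
#'
#' Tiles every contig of \code{ref} into windows of \code{window_len} bases
#' at a stride of \code{step} bases (defaults: 150/75, giving 2x-overlapping
#' windows). Trailing windows shorter than \code{window_len} are kept down to
#' \code{min_len} bases; windows containing \code{max_n} or more \code{N}
#' characters are dropped. Each window carries a deterministic identifier
#' \code{<contig>:<start>} so provenance and deduplication are stable
#' across runs.
#'
#' @param ref a [genome_set()] (the host/contaminant reference).
#' @param window_len window length in bases.
#' @param step stride between window starts in bases; must satisfy
#'   \code{1 <= step <= window_len}.
#' @param max_n windows with at least this many \code{N}s are omitted.
#' @param min_len windows shorter than this are omitted.
#' @return data frame with columns \code{window_id}, \code{contig},
#'   \code{start} (0-based), \code{end} (exclusive), \code{sequence}.
#' @examples
#' gs <- genome_set(c(c1 = strrep("ACGT", 75)))  # 300 bp
#' nrow(generate_windows(gs))                    # 4 windows
#' @export
generate_windows <- function(ref, window_len = 150L, step = 75L,
                             max_n = 100L, min_len = 75L) {
  if (!(step >= 1L && window_len >= step)) stop_contract("need window_len >= step >= 1")
  if (min_len > window_len) stop_contract("need min_len <= window_len")
  out <- vector("list", length(ref$seqs))
  for (i in seq_along(ref$seqs)) {
    seq <- ref$seqs[[i]]
    len <- nchar(seq)
    if (len < min_len) next
    starts <- seq.int(0L, len - 1L, by = step)
    ends <- pmin(starts + window_len, len)
    keep <- (ends - starts) >= min_len
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) next
    sq <- substring(seq, starts + 1L, ends)
    keep <- count_char(sq, "N") < max_n
    if (!any(keep)) next
    ctg <- names(ref$seqs)[i]
    out[[i]] <- data.frame(
      window_id = paste0(ctg, ":", starts[keep]),
      contig = ctg, start = starts[keep], end = ends[keep],
      sequence = sq[keep], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(window_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Find all exact occurrences of a query in a database
#'
#' Deterministic stand-in for an external aligner: reports every occurrence
#' of \code{query} and of its reverse complement in every contig of
#' \code{db}. Coordinates are always given on the forward strand of the
#' reference; \code{pos} is the 1-based leftmost position (SAM convention).
#' No cap is imposed on the number of hits.
#'
#' @param query nucleotide string.
#' @param db a [genome_set()].
#' @param query_id identifier recorded on each hit.
#' @return data frame with columns \code{query_id}, \code{ref_contig},
#'   \code{pos}, \code{seq_len}, \code{strand}, ordered by
#'   (\code{ref_contig}, \code{pos}).
#' @export
find_exact_matches <- function(query, db, query_id = "query") {
  if (nchar(query) < 1L) stop_contract("query must be nonempty")
  query <- toupper(query)
  rows <- list()
  rc <- revcomp(query)
  strands <- if (identical(rc, query)) "+" else c("+", "-")  # palindromes once
  for (ctg in names(db$seqs)) {
    subj <- Biostrings::DNAString(db$seqs[[ctg]])
    for (strand in strands) {
      pat <- if (strand == "+") query else rc
      m <- Biostrings::matchPattern(pat, subj, fixed = TRUE)
      if (length(m)) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = query_id, ref_contig = ctg,
          pos = BiocGenerics::start(m), seq_len = nchar(query),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(query_id = character(0), ref_contig = character(0),
                      pos = integer(0), seq_len = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  hits <- do.call(rbind, rows)
  hits[order(hits$ref_contig, hits$pos, method = "radix"), , drop = FALSE]
}

# Match a window table against the database with Biostrings preformatted
# dictionaries, grouped by window width (PDict requires constant width and a
# pure ACGT alphabet; windows containing N fall back to matchPattern).
scan_windows <- function(windows, db) {
  if (!nrow(windows))
    return(data.frame(query_id = character(0), ref_contig = character(0),
                      pos = integer(0), seq_len = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  has_n <- grepl("N", windows$sequence, fixed = TRUE)
  rows <- list()
  plain <- windows[!has_n, , drop = FALSE]
  if (nrow(plain)) {
    subjects <- lapply(db$seqs, Biostrings::DNAString)
    for (w in unique(nchar(plain$sequence))) {
      grp <- plain[nchar(plain$sequence) == w, , drop = FALSE]
      rc <- revcomp(grp$sequence)
      for (strand in c("+", "-")) {
        sel <- if (strand == "+") rep(TRUE, nrow(grp)) else rc != grp$sequence
        if (!any(sel)) next  # palindromic windows are reported once
        pats <- if (strand == "+") grp$sequence[sel] else rc[sel]
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
        for (ctg in names(subjects)) {
          mi <- Biostrings::matchPDict(pd, subjects[[ctg]])
          st <- BiocGenerics::start(mi)  # IntegerList, one element per pattern
          nhit <- lengths(st)
          if (sum(nhit) == 0L) next
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = rep(grp$window_id[sel], nhit),
            ref_contig = ctg, pos = unlist(st, use.names = FALSE),
            seq_len = w, strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (any(has_n)) {
    nw <- windows[has_n, , drop = FALSE]
    for (j in seq_len(nrow(nw)))
      rows[[length(rows) + 1L]] <-
        find_exact_matches(nw$sequence[j], db, query_id = nw$window_id[j])
  }
  if (!length(rows))
    return(data.frame(query_id = character(0), ref_contig = character(0),
                      pos = integer(0), seq_len = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  hits <- do.call(rbind, rows)
  hits[order(hits$ref_contig, hits$pos, method = "radix"), , drop = FALSE]
}

#' Convert alignment hits to interval precursors
#'
#' Converts 1-based SAM-style hits to 0-based half-open intervals on the
#' database. In the default mode \code{start = pos - 1} and
#' \code{end = pos - 1 + seq_len}. In \code{awk_compat} mode
#' \code{start = pos} and \code{end = pos + seq_len}, reproducing pipelines
#' that print the 1-based SAM position directly into a BED-like file (a
#' one-base shift relative to BED conventions). In both modes \code{end} is
#' clipped to the contig length, since the interval end is derived from the
#' record's sequence length without consulting the CIGAR and can overrun the
#' contig. Records are sorted by (contig, start) and exact duplicates
#' (contig, start, end, query id) removed, mirroring stream deduplication of
#' sorted alignment output.
#'
#' @param hits data frame with columns \code{query_id}, \code{ref_contig},
#'   \code{pos} (1-based), \code{seq_len}.
#' @param db the [genome_set()] the hits refer to.
#' @param awk_compat logical; use the 1-based start convention described
#'   above.
#' @return data frame with columns \code{contig}, \code{start}, \code{end},
#'   \code{query_id}, sorted and deduplicated.
#' @export
hits_to_intervals <- function(hits, db, awk_compat = FALSE) {
  lens <- contig_lengths(db)
  if (!nrow(hits))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), query_id = character(0),
                      stringsAsFactors = FALSE))
  unknown <- setdiff(unique(hits$ref_contig), names(lens))
  if (length(unknown))
    stop_contract("unknown contig id(s) in hits: ", paste(unknown, collapse = ", "))
  clen <- lens[hits$ref_contig]
  if (any(hits$pos < 1L)) stop_contract("SAM pos must be >= 1")
  if (any(hits$pos > clen))
    stop_contract("hit pos beyond contig length on contig ",
                  hits$ref_contig[which(hits$pos > clen)[1L]])
  off <- if (awk_compat) 0L else -1L
  start0 <- hits$pos + off
  end0 <- pmin(start0 + hits$seq_len, clen)
  prec <- data.frame(contig = hits$ref_contig, start = start0, end = end0,
                     query_id = hits$query_id, stringsAsFactors = FALSE)
  prec <- prec[prec$end > prec$start, , drop = FALSE]
  prec <- prec[order(prec$contig, prec$start, prec$end, prec$query_id,
                     method = "radix"), , drop = FALSE]
  prec <- prec[!duplicated(prec[c("contig", "start", "end", "query_id")]), ,
               drop = FALSE]
  rownames(prec) <- NULL
  prec
}

#' Merge sorted intervals into contiguous blocks
#'
#' Merges overlapping and book-ended (end == next start) spans on the same
#' contig, matching bedtools-merge defaults (distance 0), and counts the
#' constituent records as \code{support}. Input must already be sorted by
#' (contig, start); unsorted input is an error rather than silently
#' re-sorted, so upstream sort/dedup bugs surface.
#'
#' @param precursors data frame with columns \code{contig}, \code{start},
#'   \code{end} (0-based half-open), sorted by (contig, start).
#' @return data frame with columns \code{contig}, \code{start}, \code{end},
#'   \code{support}; disjoint with gaps of at least one base between
#'   consecutive intervals per contig.
#' @export
merge_intervals <- function(precursors) {
  if (!nrow(precursors))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), support = integer(0),
                      stringsAsFactors = FALSE))
  o <- order(precursors$contig, precursors$start, method = "radix")
  if (any(o != seq_along(o)))
    stop_contract("merge_intervals input is not sorted by (contig, start)")
  if (any(precursors$end <= precursors$start))
    stop_contract("intervals must have end > start")
  res <- lapply(split(precursors, precursors$contig), function(d) {
    hi <- cummax(d$end)
    new_block <- c(TRUE, d$start[-1L] > hi[-nrow(d)])  # strict: book-ended merges
    grp <- factor(cumsum(new_block), levels = unique(cumsum(new_block)))
    data.frame(contig = d$contig[1L],
               start = as.integer(tapply(d$start, grp, min)),
               end = as.integer(tapply(d$end, grp, max)),
               support = as.integer(table(grp)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[order(names(res), method = "radix")])
  rownames(out) <- NULL
  out
}

# Union length of possibly-overlapping intervals (start/end 0-based
# half-open), per contig; internal, used for counting masked bases and
# aggregate coverage. Sorts internally.
interval_union <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  hi <- cummax(end)
  grp <- factor(cumsum(c(TRUE, start[-1L] > hi[-length(start)])))
  grp <- factor(grp, levels = unique(as.character(grp)))
  data.frame(start = as.integer(tapply(start, grp, min)),
             end = as.integer(tapply(hi, grp, max)))
}

#' Mask database intervals with Ns
#'
#' Replaces every base in \code{[start, end)} of each interval with
#' \code{N}, leaving all other bases byte-identical, and reports per-genome
#' cumulative masked lengths. Masking is idempotent. Intervals out of bounds
#' are an error: clipping is [hits_to_intervals()]'s job.
#'
#' @param db a [genome_set()].
#' @param intervals data frame with columns \code{contig}, \code{start},
#'   \code{end} (0-based half-open), typically the output of
#'   [merge_intervals()].
#' @return an object of class \code{mask_report}: a list with
#'   \code{masked_db} (a \code{genome_set}), \code{intervals},
#'   \code{genomes_affected}, \code{masked_bases_per_genome} (named numeric
#'   over all genomes) and \code{total_masked_bases}.
#' @examples
#' gs <- genome_set(c(c = "ACGTACGT"))
#' mask_database(gs, data.frame(contig = "c", start = 2, end = 5))$masked_db$seqs
#' @export
mask_database <- function(db, intervals) {
  lens <- contig_lengths(db)
  seqs <- db$seqs
  masked_per_contig <- stats::setNames(numeric(length(seqs)), names(seqs))
  if (nrow(intervals)) {
    unknown <- setdiff(unique(intervals$contig), names(lens))
    if (length(unknown))
      stop_contract("unknown contig id(s): ", paste(unknown, collapse = ", "))
    if (any(intervals$start < 0) || any(intervals$end > lens[intervals$contig]) ||
        any(intervals$end <= intervals$start))
      stop_contract("interval out of bounds for its contig")
    for (ctg in unique(intervals$contig)) {
      d <- intervals[intervals$contig == ctg, , drop = FALSE]
      u <- interval_union(d$start, d$end)
      r <- charToRaw(seqs[[ctg]])
      idx <- unlist(Map(function(s, e) (s + 1L):e, u$start, u$end))
      r[idx] <- charToRaw("N")
      seqs[[ctg]] <- rawToChar(r)
      masked_per_contig[[ctg]] <- sum(u$end - u$start)
    }
  }
  per_genome <- tapply(masked_per_contig, db$genome[names(seqs)], sum)
  per_genome <- stats::setNames(as.numeric(per_genome), names(per_genome))
  structure(list(
    masked_db = genome_set(seqs, db$genome),
    intervals = intervals,
    genomes_affected = sum(per_genome > 0),
    masked_bases_per_genome = per_genome,
    total_masked_bases = sum(per_genome)
  ), class = "mask_report")
}

#' @export
print.mask_report <- function(x, ...) {
  cat("mask_report:", nrow(x$intervals), "interval(s),",
      x$total_masked_bases, "base(s) masked across",
      x$genomes_affected, "of", length(x$masked_bases_per_genome),
      "genome(s)\n")
  invisible(x)
}

#' Run the full window-mask pipeline
#'
#' Composes [generate_windows()] on the host reference, exact matching of
#' every window against the database (or ingest of externally produced SAM
#' alignments via \code{sam}), [hits_to_intervals()], [merge_intervals()]
#' and [mask_database()]. Optionally writes the merged intervals as BED and
#' the masked database as FASTA.
#'
#' @param refs host/contaminant reference [genome_set()].
#' @param db target database [genome_set()] to be masked.
#' @param window_len,step,max_n,min_len see [generate_windows()].
#' @param awk_compat see [hits_to_intervals()].
#' @param sam optional path to a SAM file of window-vs-database alignments
#'   produced by an external aligner; when given, the built-in matcher is
#'   skipped and \code{refs} may be \code{NULL}.
#' @param exclude_secondary when reading SAM, drop records with flag bit
#'   0x100 (secondary alignments). Off by default: the reference awk-based
#'   pipeline did not filter them.
#' @param bed_out,fasta_out optional output paths for the merged intervals
#'   (BED: contig, start, end, support) and the masked database.
#' @return a \code{mask_report} (see [mask_database()]).
#' @export
run_exhaustive <- function(refs, db, window_len = 150L, step = 75L,
                           max_n = 100L, min_len = 75L, awk_compat = FALSE,
                           sam = NULL, exclude_secondary = FALSE,
                           bed_out = NULL, fasta_out = NULL) {
  hits <- if (is.null(sam)) {
    windows <- generate_windows(refs, window_len, step, max_n, min_len)
    scan_windows(windows, db)
  } else {
    read_sam_hits(sam, exclude_secondary = exclude_secondary)
  }
  prec <- hits_to_intervals(hits, db, awk_compat = awk_compat)
  merged <- merge_intervals(prec)
  report <- mask_database(db, merged)
  if (!is.null(bed_out)) write_bed(merged, bed_out)
  if (!is.null(fasta_out)) write_fasta(report$masked_db, fasta_out)
  report
}

#' Read alignment hits from a SAM file
#'
#' Consumes only columns 1 (query), 2 (flag), 3 (reference), 4 (position)
#' and 10 (sequence). Header lines and unmapped records (flag bit 0x4 or
#' reference \code{*}) are skipped. Secondary alignments (flag bit 0x100)
#' are kept by default, matching the reference pipeline, and can be excluded.
#'
#' @param path path to a text SAM file.
#' @param exclude_secondary drop flag-0x100 records.
#' @return hit data frame as produced by [find_exact_matches()].
#' @export
read_sam_hits <- function(path, exclude_secondary = FALSE) {
  if (!file.exists(path)) stop_format("SAM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  empty <- data.frame(query_id = character(0), ref_contig = character(0),
                      pos = integer(0), seq_len = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 10L))
    stop_format("SAM record with fewer than 10 fields at line ",
                which(lengths(fields) < 10L)[1L])
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  rname <- vapply(fields, `[[`, "", 3L)
  keep <- bitwAnd(flag, 4L) == 0L & rname != "*"
  if (exclude_secondary) keep <- keep & bitwAnd(flag, 256L) == 0L
  fields <- fields[keep]; flag <- flag[keep]
  if (!length(fields)) return(empty)
  hits <- data.frame(
    query_id = vapply(fields, `[[`, "", 1L),
    ref_contig = vapply(fields, `[[`, "", 3L),
    pos = as.integer(vapply(fields, `[[`, "", 4L)),
    seq_len = nchar(vapply(fields, `[[`, "", 10L)),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    stringsAsFactors = FALSE)
  hits[order(hits$ref_contig, hits$pos, method = "radix"), , drop = FALSE]
}

#' Write intervals as BED
#'
#' Four tab-separated columns: contig, start (0-based), end (exclusive),
#' support count. No header.
#'
#' @param intervals data frame with columns \code{contig}, \code{start},
#'   \code{end} and optionally \code{support}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("contig", "start", "end",
            if ("support" %in% names(intervals)) "support")
  utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED(-like) interval file
#' @param path path to a tab-separated file: contig, start, end, optional
#'   fourth column (support or sample).
#' @param col4 name to give the fourth column if present.
#' @return data frame of intervals.
#' @export
read_bed <- function(path, col4 = "support") {
  if (!file.exists(path)) stop_format("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          colClasses = NA, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("contig", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- col4
  df
}
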