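# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths of the functions they verify.

# Character positions (1-based) masked by the pipeline, per contig:
# positions that are N in the masked db but were not N in the original.
masked_positions <- function(report, original_db) {
  lapply(names(original_db$seqs), function(ctg) {
    orig <- strsplit(original_db$seqs[[ctg]], "")[[1L]]
    msk <- strsplit(report$masked_db$seqs[[ctg]], "")[[1L]]
    which(msk == "N" & orig != "N")
  })
}

# Brute-force masking oracle: enumerate every window of the reference by
# explicit loops and mark every exact occurrence (forward and reverse
# complement, via gregexpr fixed-string search) in every db contig.
oracle_masked <- function(refs, db, window_len = 150L, step = 75L,
                          max_n = 100L, min_len = 75L) {
  rc1 <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
  }
  marks <- lapply(db$seqs, function(s) logical(nchar(s)))
  for (rseq in refs$seqs) {
    p <- 0L
    while (p < nchar(rseq)) {
      w <- substr(rseq, p + 1L, min(p + window_len, nchar(rseq)))
      p <- p + step
      if (nchar(w) < min_len) next
      if (lengths(regmatches(w, gregexpr("N", w, fixed = TRUE))) >= max_n) next
      pats <- unique(c(w, rc1(w)))
      for (ctg in names(db$seqs)) {
        for (pat in pats) {
          m <- gregexpr(pat, db$seqs[[ctg]], fixed = TRUE)[[1L]]
          if (m[1L] == -1L) next
          for (st in m) marks[[ctg]][st:(st + nchar(pat) - 1L)] <- TRUE
        }
      }
    }
  }
  lapply(marks, which)
}

# Exhaustive 2x2 enumeration using binomial coefficients only.
oracle_fisher <- function(a, b, cc, d, sided) {
  N <- a + b + cc + d; K <- a + b; n <- a + cc
  xs <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  obs <- probs[xs == a]
  if (sided == "greater") sum(probs[xs >= a])
  else sum(probs[probs <= obs * (1 + 1e-7)])
}

# O(n^2) Kendall tau-b with tie-corrected normal-approximation p-value.
oracle_tau <- function(x, y) {
  x <- unname(x); y <- unname(y)
  n <- length(x)
  S <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    S <- S + sign(x[i] - x[j]) * sign(y[i] - y[j])
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5)); vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  v <- (v0 - vt - vu) / 18 + v1 + v2
  p <- 2 * stats::pnorm(-abs(S / sqrt(v)))
  list(tau = tau, p = min(p, 1))
}

# Pairwise-comparison AUROC: fraction of positive-negative pairs ranked
# concordantly, ties half credit.
oracle_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Stepwise AUPR from first principles: walk distinct thresholds, recount
# TP/FP at each by explicit comparison.
oracle_aupr <- function(scores, labels) {
  labels <- as.logical(labels)
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in ths) {
    called <- scores >= t
    tp <- sum(called & labels)
    prec <- tp / sum(called)
    rec <- tp / sum(labels)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Fisher's-method closed form for m even-df inputs:
# exp(-x/2) * sum_{k<m} (x/2)^k / k!  with x = -2 sum(log p).
oracle_combine <- function(p) {
  m <- length(p)
  x <- -2 * sum(log(p))
  exp(-x / 2) * sum((x / 2)^(0:(m - 1)) / factorial(0:(m - 1)))
}

# Hand step-up BH.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Boolean-position coverage union fraction.
oracle_coverage_fraction <- function(starts, ends, genome_length) {
  covered <- logical(genome_length)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1L):ends[i]] <- TRUE
  }
  sum(covered) / genome_length
}

random_gs <- function(n_contigs, len, prefix = "c") {
  seqs <- vapply(seq_len(n_contigs), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
  genome_set(stats::setNames(seqs, paste0(prefix, seq_len(n_contigs))))
}
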