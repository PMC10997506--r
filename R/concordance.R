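# Feature-concordance framework for comparing two classifiers trained on
# variants of the same data: 2x2 Fisher exact tests on used/unused feature
# sets, Kendall tau on importance ranks with unused features tied at k+1,
# Fisher's method for combining p-values across batches, Benjamini-Hochberg
# across classes, and AUROC/AUPR confidence-interval equivalence.

DOUBLE_XMIN <- 2.225074e-308  # smallest normalised double; p-value clamp

#' Build the 2x2 used/unused feature contingency table
#'
#' A feature is "used" by a model iff its importance score is strictly
#' positive. The table counts features used by both models (\code{a}), by
#' the first only (\code{b}), by the second only (\code{c}) and by neither
#' (\code{d}); \code{a + b + c + d} equals the size of the shared feature
#' universe.
#'
#' @param va,vb named nonnegative numeric vectors of importance scores over
#'   the same feature universe (same names, any order).
#' @return object of class \code{contingency_2x2}: named integer vector
#'   \code{(a, b, c, d)}.
#' @export
build_contingency <- function(va, vb) {
  if (any(va < 0) || any(vb < 0))
    stop_contract("importance scores must be nonnegative")
  diff <- c(setdiff(names(va), names(vb)), setdiff(names(vb), names(va)))
  if (length(diff))
    stop_contract("feature universes differ: ", paste(diff, collapse = ", "))
  vb <- vb[names(va)]
  ua <- va > 0; ub <- vb > 0
  structure(c(a = sum(ua & ub), b = sum(ua & !ub),
              c = sum(!ua & ub), d = sum(!ua & !ub)),
            class = "contingency_2x2")
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test. The one-sided \code{"greater"} alternative
#' (default) tests enrichment of joint feature usage; the two-sided test
#' sums the probabilities of all tables no more probable than the observed
#' one. Degenerate margins (a row or column summing to zero) return p = 1
#' with a warning.
#'
#' @param tab a \code{contingency_2x2}, a 2x2 matrix, or a length-4 vector
#'   \code{(a, b, c, d)}.
#' @param sided \code{"greater"} or \code{"two.sided"}.
#' @return list with \code{p} and \code{odds_ratio} (sample cross-product
#'   ratio; \code{Inf} when only the concordant diagonal is populated).
#' @examples
#' fisher_exact(c(a = 2, b = 0, c = 0, d = 2))$p  # 1/6
#' @export
fisher_exact <- function(tab, sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  x <- as.vector(unclass(tab))
  if (length(x) != 4L || any(x < 0) || any(x != round(x)))
    stop_contract("need a 2x2 table of nonnegative counts")
  a <- x[1L]; b <- x[2L]; cc <- x[3L]; d <- x[4L]
  N <- a + b + cc + d
  K <- a + b   # used by model A
  n <- a + cc  # used by model B
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  if (K == 0 || n == 0 || K == N || n == N) {
    warning("degenerate margin in 2x2 table; p = 1")
    return(list(p = 1, odds_ratio = or))
  }
  if (sided == "greater") {
    p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    supp <- max(0, n - (N - K)):min(K, n)
    dens <- stats::dhyper(supp, K, N - K, n)
    p <- sum(dens[dens <= stats::dhyper(a, K, N - K, n) * (1 + 1e-7)])
  }
  list(p = min(p, 1), odds_ratio = or)
}

# Importance scores -> ranks: nonzero features ranked by descending score
# (rank 1 = largest, midranks for ties), all zero-importance features tied
# at rank k + 1 where k is the number of nonzero features.
importance_ranks <- function(v) {
  k <- sum(v > 0)
  r <- rep(k + 1, length(v))
  r[v > 0] <- rank(-v[v > 0], ties.method = "average")
  names(r) <- names(v)
  r
}

#' Rank concordance of two importance vectors
#'
#' Kendall tau-b between the two models' importance rankings, where each
#' model's nonzero features are ranked by descending score and every
#' zero-importance feature is assigned the tied rank k + 1 (k = number of
#' nonzero features in that model). The large tie block this creates makes
#' the tie-corrected tau-b variant and a tie-adjusted normal-approximation
#' p-value the appropriate choices.
#'
#' @param va,vb named importance vectors over the same universe; each must
#'   have at least two nonzero entries.
#' @return list with \code{tau} and \code{p}.
#' @export
rank_concordance <- function(va, vb) {
  diff <- c(setdiff(names(va), names(vb)), setdiff(names(vb), names(va)))
  if (length(diff))
    stop_contract("feature universes differ: ", paste(diff, collapse = ", "))
  vb <- vb[names(va)]
  if (sum(va > 0) < 2 || sum(vb > 0) < 2)
    stop_contract("each vector needs >= 2 nonzero importances (degenerate variance otherwise)")
  ra <- importance_ranks(va)
  rb <- importance_ranks(vb)
  ct <- suppressWarnings(
    stats::cor.test(ra, rb, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Combine p-values with Fisher's method
#'
#' Computes \eqn{X^2 = -2 \sum \ln p} and refers it to a chi-square
#' distribution with 2m degrees of freedom, working in log space throughout
#' so extreme products do not underflow. A single p-value is returned
#' unchanged. The returned value is clamped below at the smallest normalised
#' double (2.2e-308) with the exact log10 p-value retained as attribute
#' \code{"log10"}.
#'
#' @param p numeric vector of p-values in \code{(0, 1]}; zeros are treated
#'   as the clamp value with a warning.
#' @return combined p-value with attribute \code{"log10"}.
#' @examples
#' combine_fisher(c(0.5, 0.5))  # 0.5966
#' @export
combine_fisher <- function(p) {
  if (!length(p)) stop_contract("no p-values to combine")
  if (any(p < 0) || any(p > 1)) stop_contract("p-values must be in (0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 treated as the clamp value 2.2e-308")
    p[p == 0] <- DOUBLE_XMIN
  }
  if (length(p) == 1L) {
    out <- p
    attr(out, "log10") <- log10(p)
    return(out)
  }
  x2 <- -2 * sum(log(p))
  logp <- stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE,
                        log.p = TRUE)
  out <- max(exp(logp), DOUBLE_XMIN)
  attr(out, "log10") <- logp / log(10)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment, returned in input order.
#'
#' @param p numeric vector of p-values.
#' @return q-values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Area under the ROC curve
#'
#' Rank-statistic computation (equivalent to U / (n1 * n0)) with half credit
#' for tied scores.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (logical, or 0/1) with both classes present.
#' @return AUROC in \code{[0, 1]}.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop_contract("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) summation by default: thresholds descend
#' through the distinct score values (tied scores enter together) and each
#' recall increment contributes at the precision attained at that
#' threshold. A trapezoidal variant is also available.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels with both classes present.
#' @param method \code{"step"} or \code{"trapezoid"}.
#' @return AUPR in \code{(0, 1]}.
#' @export
aupr <- function(scores, labels, method = c("step", "trapezoid")) {
  method <- match.arg(method)
  labels <- as.logical(labels)
  P <- sum(labels)
  if (P == 0 || all(labels)) stop_contract("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- !duplicated(s, fromLast = TRUE)  # end of each tied-score group
  tp <- cumsum(y)[last]
  np <- cumsum(!y)[last]
  prec <- tp / (tp + np)
  rec <- tp / P
  drec <- diff(c(0, rec))
  if (method == "step") {
    sum(drec * prec)
  } else {
    prev_prec <- c(prec[1L], prec[-length(prec)])
    sum(drec * (prec + prev_prec) / 2)
  }
}

#' Normal-approximation confidence interval for a metric series
#'
#' Mean and \code{mean +/- z * sd / sqrt(n)} over per-fold or per-batch
#' metric values, truncated to \code{[0, 1]} (z = 2.576 at the default 99\%
#' level, 1.960 at 95\%). Fewer than two values collapse the interval to
#' the point with a warning.
#'
#' @param values numeric metric values in \code{[0, 1]}.
#' @param level confidence level.
#' @return list with \code{mean}, \code{low}, \code{high}, \code{level}.
#' @export
aggregate_ci <- function(values, level = 0.99) {
  if (length(values) < 2L) {
    warning("fewer than 2 values; CI collapses to the point")
    m <- mean(values)
    return(list(mean = m, low = m, high = m, level = level))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- mean(values)
  half <- z * stats::sd(values) / sqrt(length(values))
  list(mean = m, low = max(0, m - half), high = min(1, m + half),
       level = level)
}

#' Are two metric series equivalent by CI overlap?
#'
#' Two classifiers are declared equivalent on a metric when their
#' confidence intervals overlap.
#'
#' @param values_a,values_b numeric metric series.
#' @param level confidence level for both intervals.
#' @return logical flag.
#' @export
equivalent <- function(values_a, values_b, level = 0.99) {
  ca <- aggregate_ci(values_a, level)
  cb <- aggregate_ci(values_b, level)
  ca$low <= cb$high && cb$low <= ca$high
}

#' Per-batch feature-concordance comparison
#'
#' For every (batch, class) cell: builds the used/unused contingency table,
#' runs the one-sided Fisher exact test and the k+1-rule Kendall
#' correlation. Per class, the per-batch p-values are then combined with
#' Fisher's method (a class present in a single batch passes its raw
#' p-value through), and Benjamini-Hochberg adjustment is applied across
#' classes. \code{-log10} columns are computed after flooring q at twice
#' the double-precision minimum, the convention used for plotting values
#' that underflow.
#'
#' @param importances long data frame with columns \code{batch},
#'   \code{class}, \code{model} (two levels), \code{feature}, \code{score}.
#'   Within a (batch, class) cell the universe is the union of features
#'   listed for either model; unlisted features score 0.
#' @param samples optional data frame (\code{batch}, \code{class}, \code{n})
#'   of per-class sample sizes; (batch, class) cells with
#'   \code{n < min_per_class} are excluded.
#' @param min_per_class minimum samples per class per batch (default 20).
#' @param sided sidedness of the Fisher exact test.
#' @return object of class \code{concordance_report}: a data frame with one
#'   row per class (\code{class}, \code{n_batches}, \code{fisher_p},
#'   \code{tau_p}, \code{fisher_q}, \code{tau_q},
#'   \code{neg_log10_fisher_q}, \code{neg_log10_tau_q}); the per-batch
#'   detail table is attached as attribute \code{"per_batch"}.
#' @export
per_batch_compare <- function(importances, samples = NULL,
                              min_per_class = 20,
                              sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  req <- c("batch", "class", "model", "feature", "score")
  if (!all(req %in% names(importances)))
    stop_contract("importances needs columns: ", paste(req, collapse = ", "))
  models <- sort(unique(importances$model))
  if (length(models) != 2L)
    stop_contract("exactly two models are compared; found ", length(models))
  if (!is.null(samples)) {
    small <- samples[samples$n < min_per_class, c("batch", "class")]
    if (nrow(small)) {
      key <- paste(importances$batch, importances$class)
      importances <- importances[!(key %in% paste(small$batch, small$class)), ,
                                 drop = FALSE]
    }
  }
  empty <- data.frame(class = character(0), n_batches = integer(0),
                      fisher_p = numeric(0), tau_p = numeric(0),
                      fisher_q = numeric(0), tau_q = numeric(0),
                      neg_log10_fisher_q = numeric(0),
                      neg_log10_tau_q = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(importances)) {
    class(empty) <- c("concordance_report", "data.frame")
    attr(empty, "per_batch") <- empty[0, 1:2]
    return(empty)
  }
  cells <- unique(importances[c("batch", "class")])
  detail <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    d <- importances[importances$batch == cells$batch[i] &
                       importances$class == cells$class[i], , drop = FALSE]
    universe <- unique(d$feature)
    vec <- function(m) {
      v <- stats::setNames(numeric(length(universe)), universe)
      dm <- d[d$model == m, , drop = FALSE]
      v[dm$feature] <- dm$score
      v
    }
    va <- vec(models[1L]); vb <- vec(models[2L])
    fis <- fisher_exact(build_contingency(va, vb), sided = sided)
    tau <- tryCatch(rank_concordance(va, vb),
                    error = function(e) list(tau = NA_real_, p = NA_real_))
    detail[[i]] <- data.frame(
      batch = cells$batch[i], class = cells$class[i],
      a = unname(build_contingency(va, vb)["a"]),
      fisher_p = fis$p, odds_ratio = fis$odds_ratio,
      tau = tau$tau, tau_p = tau$p, stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, detail)
  classes <- unique(detail$class)
  comb <- lapply(classes, function(cl) {
    d <- detail[detail$class == cl, , drop = FALSE]
    tp <- d$tau_p[!is.na(d$tau_p)]
    data.frame(class = cl, n_batches = nrow(d),
               fisher_p = as.numeric(combine_fisher(d$fisher_p)),
               tau_p = if (length(tp)) as.numeric(combine_fisher(tp))
                       else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, comb)
  out$fisher_q <- bh_adjust(out$fisher_p)
  out$tau_q <- bh_adjust(out$tau_p)
  floor_p <- 2 * DOUBLE_XMIN
  out$neg_log10_fisher_q <- -log10(pmax(out$fisher_q, floor_p))
  out$neg_log10_tau_q <- -log10(pmax(out$tau_q, floor_p))
  class(out) <- c("concordance_report", "data.frame")
  attr(out, "per_batch") <- detail
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report:", nrow(x), "class(es),",
      nrow(attr(x, "per_batch")), "batch-class cell(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}
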