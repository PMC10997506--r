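test_that("contingency table counts used/unused features correctly", {
  u <- c(x = 0, y = 0, z = 0, w = 0)
  va <- replace(u, c("x", "y"), 1); vb <- replace(u, c("x", "y"), 2)
  expect_equal(unclass(build_contingency(va, vb)),
               c(a = 2L, b = 0L, c = 0L, d = 2L))
  expect_equal(unclass(build_contingency(replace(u, names(u), 1), u)),
               c(a = 0L, b = 4L, c = 0L, d = 0L))
  expect_equal(unclass(build_contingency(c(x = 1, y = 0), c(x = 0, y = 1))),
               c(a = 0L, b = 1L, c = 1L, d = 0L))
  expect_error(build_contingency(c(x = 1), c(y = 1)), "universes differ")
})

test_that("fisher exact matches hand-enumerated hypergeometric examples", {
  expect_equal(fisher_exact(c(a = 2, b = 0, c = 0, d = 2))$p, 1 / 6)
  expect_equal(fisher_exact(c(a = 5, b = 5, c = 5, d = 5),
                            sided = "two.sided")$p, 1)
  expect_equal(fisher_exact(c(a = 3, b = 1, c = 1, d = 3),
                            sided = "two.sided")$p, 34 / 70)
  expect_warning(p1 <- fisher_exact(c(a = 0, b = 0, c = 3, d = 3))$p,
                 "degenerate")
  expect_equal(p1, 1)
})

test_that("fisher exact equals enumeration and stats::fisher.test for N <= 30", {
  for (N in c(8, 12, 30)) {
    set.seed(N)
    for (rep in 1:30) {
      x <- as.vector(stats::rmultinom(1, N, prob = c(1, 1, 1, 1)))
      a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
      if ((a + b) %in% c(0, N) || (a + cc) %in% c(0, N)) next
      m <- matrix(c(a, cc, b, d), 2)
      for (sided in c("greater", "two.sided")) {
        got <- fisher_exact(c(a, b, cc, d), sided = sided)$p
        expect_equal(got, oracle_fisher(a, b, cc, d, sided), tolerance = 1e-12)
        expect_equal(got, stats::fisher.test(m, alternative = sided)$p.value,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("k+1 ranking ties all unused features at rank k+1", {
  v <- c(a = 5, b = 5, c = 1, d = 0, e = 0)
  r <- mbrobust:::importance_ranks(v)
  expect_equal(unname(r), c(1.5, 1.5, 3, 4, 4))
})

test_that("rank concordance reproduces the 3-feature discordance example", {
  va <- c(a = 2, b = 1, c = 0)
  vb <- c(a = 0, b = 1, c = 2)
  res <- rank_concordance(va, vb)
  expect_equal(res$tau, -1)
  expect_equal(rank_concordance(va, va)$tau, 1)
  expect_error(rank_concordance(va, c(a = 0, b = 0, c = 0)), "nonzero")
})

test_that("rank concordance equals O(n^2) pair counting on random vectors", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(20:200, 1)
    k1 <- sample(2:(n - 1), 1); k2 <- sample(2:(n - 1), 1)
    va <- stats::setNames(numeric(n), paste0("f", 1:n))
    vb <- va
    va[sample(n, k1)] <- stats::runif(k1)
    vb[sample(n, k2)] <- stats::runif(k2)
    got <- rank_concordance(va, vb)
    want <- oracle_tau(mbrobust:::importance_ranks(va),
                       mbrobust:::importance_ranks(vb))
    expect_equal(got$tau, want$tau, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
})

test_that("Fisher's method matches the even-df closed form and edge rules", {
  expect_equal(as.numeric(combine_fisher(c(1, 1))), 1)
  expect_equal(as.numeric(combine_fisher(c(0.5, 0.5))), 0.5965736,
               tolerance = 1e-6)
  expect_equal(as.numeric(combine_fisher(0.3)), 0.3)  # single-batch rule
  set.seed(31)
  for (rep in 1:20) {
    p <- stats::runif(sample(2:8, 1))
    expect_equal(as.numeric(combine_fisher(p)), oracle_combine(p),
                 tolerance = 1e-9)
  }
})

test_that("combined p-values stay finite in log space and clamp underflow", {
  tiny <- rep(1e-200, 4)
  out <- combine_fisher(tiny)
  expect_equal(as.numeric(out), 2.225074e-308, tolerance = 1e-313)
  expect_lt(attr(out, "log10"), -750)  # true magnitude retained
  expect_warning(z <- combine_fisher(c(0, 0.5)), "clamp")
  expect_gt(as.numeric(z), 0)
})

test_that("BH adjustment equals hand step-up and is permutation-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(41)
  p <- stats::runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  # monotone nondecreasing in sorted-p order
  q <- bh_adjust(p)[order(p)]
  expect_true(all(diff(q) >= 0))
})

test_that("auroc equals U/(n1 n0) pair counting including ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_equal(auroc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  set.seed(51)
  for (rep in 1:40) {
    n <- sample(5:40, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("aupr equals brute-force stepwise summation on small instances", {
  set.seed(61)
  for (rep in 1:40) {
    n <- sample(4:20, 1)
    scores <- round(stats::runif(n), 2)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(aupr(scores, labels), oracle_aupr(scores, labels),
                 tolerance = 1e-12)
  }
  # perfect separation gives area 1 under the step convention
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
})

test_that("metric confidence intervals and equivalence behave as specified", {
  ci <- aggregate_ci(rep(0.8, 10))
  expect_equal(c(ci$mean, ci$low, ci$high), c(0.8, 0.8, 0.8))
  vals <- c(0.7, 0.75, 0.8, 0.85, 0.9)
  ci99 <- aggregate_ci(vals, 0.99)
  ci95 <- aggregate_ci(vals, 0.95)
  expect_equal(ci99$mean, mean(vals))
  expect_gt(ci99$high - ci99$low, ci95$high - ci95$low)
  expect_equal(ci95$high - ci95$mean,
               stats::qnorm(0.975) * stats::sd(vals) / sqrt(5))
  expect_true(equivalent(vals, vals))
  expect_false(equivalent(rep(c(0.99, 0.98), 5), rep(c(0.50, 0.51), 5)))
  expect_warning(one <- aggregate_ci(0.7), "fewer than 2")
  expect_equal(one$low, one$high)
})

test_that("per-batch comparison combines evidence and applies the single-batch rule", {
  set.seed(71)
  mk_long <- function(batch, cls, pair) {
    rbind(
      data.frame(batch = batch, class = cls, model = "A",
                 feature = names(pair$a), score = unname(pair$a)),
      data.frame(batch = batch, class = cls, model = "B",
                 feature = names(pair$b), score = unname(pair$b)))
  }
  pair1 <- make_importance_pair(n_features = 100, k_used = 30, overlap = 30,
                                seed = 1)
  pair2 <- make_importance_pair(n_features = 100, k_used = 30, overlap = 30,
                                seed = 2)
  pair3 <- make_importance_pair(n_features = 100, k_used = 30, overlap = 15,
                                seed = 3)
  imp <- rbind(mk_long("b1", "tumorX", pair1), mk_long("b2", "tumorX", pair2),
               mk_long("b1", "tumorY", pair3))
  rep <- per_batch_compare(imp)
  detail <- attr(rep, "per_batch")
  x <- rep[rep$class == "tumorX", ]
  # two strongly-overlapping batches: combined p below either batch's p
  expect_lt(x$fisher_p, min(detail$fisher_p[detail$class == "tumorX"]))
  expect_equal(x$n_batches, 2)
  # single-batch class passes its raw p through before BH
  y <- rep[rep$class == "tumorY", ]
  expect_equal(y$fisher_p, detail$fisher_p[detail$class == "tumorY"])
  # BH across the two classes
  expect_equal(rep$fisher_q, bh_adjust(rep$fisher_p))
})

test_that("per-batch comparison honours the minimum class size", {
  pair <- make_importance_pair(n_features = 50, k_used = 10, overlap = 10,
                               seed = 4)
  imp <- rbind(
    data.frame(batch = "b1", class = "small", model = "A",
               feature = names(pair$a), score = unname(pair$a)),
    data.frame(batch = "b1", class = "small", model = "B",
               feature = names(pair$b), score = unname(pair$b)))
  samples <- data.frame(batch = "b1", class = "small", n = 12)
  expect_error(per_batch_compare(imp, samples = samples, min_per_class = 20),
               NA)
  rep <- per_batch_compare(imp, samples = samples, min_per_class = 20)
  expect_equal(nrow(rep), 0)
})
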