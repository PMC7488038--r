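test_that("splits honor the 70/15/15 floors with the remainder going to train", {
  s100 <- makeSplits(100L, splitSpec(repeats = 1L, seed = 1L))[[1]]
  expect_equal(lengths(s100)[c("train", "test", "validation")],
               c(train = 70L, test = 15L, validation = 15L))
  s152 <- makeSplits(152L, splitSpec(repeats = 1L, seed = 1L))[[1]]
  expect_equal(lengths(s152)[c("train", "test", "validation")],
               c(train = 108L, test = 22L, validation = 22L))
})

test_that("split partitions are disjoint and exhaustive across cohort sizes", {
  for (n in c(3L, 7L, 20L, 152L, 500L)) {
    parts <- makeSplits(n, splitSpec(repeats = 3L, seed = 11L))
    for (p in parts) {
      all_idx <- c(p$train, p$test, p$validation)
      expect_equal(sort(all_idx), seq_len(n), label = sprintf("n=%d", n))
      expect_equal(anyDuplicated(all_idx), 0L)
    }
  }
  # distinct replicates use distinct derived seeds
  parts <- makeSplits(50L, splitSpec(repeats = 6L, seed = 2L))
  expect_equal(length(unique(lapply(parts, `[[`, "train"))), 6L)
  expect_error(makeSplits(2L, splitSpec()), "at least 3")
})

test_that("splits operate on patient ids when ids are supplied", {
  ids <- sprintf("P%02d", 1:10)
  p <- makeSplits(ids, splitSpec(repeats = 1L, seed = 3L))[[1]]
  expect_true(all(unlist(p) %in% ids))
  expect_equal(sort(unname(unlist(p))), sort(ids))
})

test_that("classification metrics match hand arithmetic, including degenerate cases", {
  # TP=3, FP=1, FN=1, TN=5
  pred <- c(rep("soft", 4), rep("hard", 6))
  truth <- c(rep("soft", 3), "hard", "soft", rep("hard", 5))
  m <- computeMetrics(pred, truth)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 0.8)
  perfect <- computeMetrics(truth, truth)
  expect_true(all(unlist(perfect) == 1))
  expect_warning(z <- computeMetrics(rep("hard", 4), c("soft", "soft", "hard", "hard")),
                 "precision")
  expect_equal(z$precision, 0)
  expect_error(computeMetrics(c("soft", "mystery"), c("soft", "hard")), "labels")
})

test_that("F1 is the harmonic mean and accuracy is invariant to class relabeling", {
  withSeed(5, {
    for (i in 1:10) {
      pred <- sample(c("soft", "hard"), 30, replace = TRUE)
      truth <- sample(c("soft", "hard"), 30, replace = TRUE)
      m <- suppressWarnings(computeMetrics(pred, truth, positive_class = "soft"))
      if (m$precision > 0 && m$recall > 0)
        expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall))
      m2 <- suppressWarnings(computeMetrics(pred, truth, positive_class = "hard"))
      expect_equal(m$accuracy, m2$accuracy)
    }
  })
})

test_that("signed-rank statistics reproduce the analytic all-same-sign values", {
  # six nonzero same-sign differences, second member dominating
  r6 <- wilcoxonSignedRank(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7))
  expect_equal(r6$n_used, 6L)
  expect_equal(r6$W, 0)
  expect_lt(abs(r6$Z - (-2.201)), 1e-3)
  expect_lt(abs(r6$p - 0.028), 5e-4)
  # one zero difference dropped, five same-sign remain
  r5 <- wilcoxonSignedRank(c(1, 2, 3, 4, 5, 9), c(2, 3, 4, 5, 6, 9))
  expect_equal(r5$n_used, 5L)
  expect_lt(abs(r5$Z - (-2.023)), 1e-3)
  expect_lt(abs(r5$p - 0.043), 5e-4)
  # two equal-magnitude opposite-sign differences: W = n(n+1)/4, Z = 0
  r2 <- wilcoxonSignedRank(c(1, 0), c(0, 1))
  expect_equal(r2$W, 1.5)
  expect_equal(r2$Z, 0)
  expect_error(wilcoxonSignedRank(c(1, 2), c(1, 2)), "undefined")
})

test_that("the normal approximation brackets exact enumeration for n <= 10", {
  # exact two-sided tail probabilities by full enumeration of all 2^n sign
  # patterns: inclusive P(W <= w_obs) and strict P(W < w_obs). Without a
  # continuity correction the normal approximation falls between the two
  # (up to a small smoothing slack), and W itself must match brute force.
  exactTails <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    wObs <- min(sum(r[d > 0]), sum(r[d < 0]))
    total <- 2^n
    incl <- strict <- 0
    for (bits in 0:(total - 1)) {
      signs <- as.integer(intToBits(bits))[1:n]
      wPos <- sum(r[signs == 1])
      w <- min(wPos, sum(r) - wPos)
      if (w <= wObs) incl <- incl + 1
      if (w < wObs) strict <- strict + 1
    }
    list(w = wObs, incl = incl / total, strict = strict / total)
  }
  withSeed(77, {
    for (i in 1:12) {
      n <- sample(4:10, 1)
      a <- round(rnorm(n), 2)
      b <- round(rnorm(n), 2)
      if (all(a == b)) next
      res <- wilcoxonSignedRank(a, b)
      ex <- exactTails(a - b)
      expect_equal(res$W, ex$w)
      expect_gte(res$p, ex$strict - 0.02)
      expect_lte(res$p, ex$incl + 0.02)
    }
  })
  # antisymmetry of the directional statistic
  withSeed(78, {
    for (i in 1:10) {
      a <- rnorm(8)
      b <- rnorm(8)
      expect_equal(wilcoxonSignedRank(a, b)$Z, -wilcoxonSignedRank(b, a)$Z)
    }
  })
})

test_that("signed-rank p agrees with the stats package's normal approximation", {
  withSeed(81, {
    for (i in 1:8) {
      a <- rnorm(12)
      b <- rnorm(12)
      ours <- wilcoxonSignedRank(a, b)
      ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                 exact = FALSE, correct = FALSE))
      expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("arm comparison pairs every non-reference arm and skips the reference", {
  withSeed(13, {
    reports <- list(multi = runif(6, 0.9, 0.95),
                    t1 = runif(6, 0.85, 0.9),
                    t2 = runif(6, 0.84, 0.9))
  })
  csv <- tempfile(fileext = ".csv")
  tab <- compareArms(reports, "multi", csv_path = csv)
  expect_equal(nrow(tab), 2L)            # arms - 1 rows
  expect_false("multi" %in% tab$arm)     # self-comparison skipped
  expect_true(all(c("mean_diff", "lo", "hi", "Z", "p") %in% names(tab)))
  exported <- utils::read.csv(csv)
  expect_equal(names(exported), c("arm", "mean_diff", "lo", "hi", "Z", "p"))
  expect_error(compareArms(list(a = 1:6, b = 1:5), "a"), "replicate count")
})

test_that("replicate summaries expose mean, sd and variance consistently", {
  pr <- data.frame(replicate = rep(1:3, each = 2),
                   split = rep(c("train", "test"), 3),
                   accuracy = c(0.9, 0.8, 0.92, 0.82, 0.94, 0.84),
                   precision = 0.5, recall = 0.5, f1 = 0.5)
  s <- summarizeReplicates(pr)
  acc <- s[s$split == "test" & s$metric == "accuracy", ]
  expect_equal(acc$mean, 0.82)
  expect_equal(acc$sd, stats::sd(c(0.8, 0.82, 0.84)))
  expect_equal(acc$var, acc$sd^2)
  expect_true(all(s$metric %in% c("accuracy", "precision", "recall", "f1")))
})
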