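# RENN and instance-hardness-threshold undersampling.

test_that("well-separated clusters are left untouched in one sweep", {
  s <- random_sample_set(15, 15, dims = 3, sep = 50, seed = 2)
  res <- renn_edit(s, target = "all")
  expect_equal(nrow(res$samples$x), 30L)
  expect_equal(res$report$iterations, 1L)
  expect_length(res$report$removed_ids, 0)
})

test_that("a negative planted inside a positive cluster is the only removal", {
  # 11 tight positives around the origin, one negative among them, and
  # far-away negatives that keep each other company
  withr::with_seed(4, {
    xp <- matrix(rnorm(11 * 2, 0, 0.3), 11, 2)
  })
  xn_far <- matrix(c(50, 50, 51, 50, 50, 51, 51, 51), 4, 2, byrow = TRUE)
  x <- rbind(xp, c(0.1, 0.1), xn_far)
  y <- c(rep(1L, 11), 0L, rep(0L, 4))
  s <- sample_set(x, y, data.frame(chain = "X", resno = seq_len(16)))
  res <- renn_edit(s, target = "negatives_only")
  expect_equal(res$report$removed_ids, "X:12:")
  expect_equal(unname(res$report$after_counts), c(11L, 4L))
})

test_that("editing reaches a fixed point and returns a subset", {
  for (seed in 1:3) {
    s <- random_sample_set(20, 40, dims = 3, sep = 1, seed = seed)
    res <- renn_edit(s, target = "all")
    expect_lte(nrow(res$samples$x), nrow(s$x))
    expect_true(all(sample_keys(res$samples) %in% sample_keys(s)))
    again <- renn_edit(res$samples, target = "all")
    expect_length(again$report$removed_ids, 0)
    # minority class untouched under negatives_only
    res_neg <- renn_edit(s, target = "negatives_only")
    expect_equal(res_neg$report$after_counts[["positives"]], 20L)
  }
})

test_that("renn agrees with an exhaustive 3-NN editing oracle on small instances", {
  for (seed in 1:6) {
    withr::with_seed(seed, {
      n_pos <- sample(8:25, 1)
      n_neg <- sample(8:25, 1)
    })
    s <- random_sample_set(n_pos, n_neg, dims = 3, sep = 1.5, seed = seed + 100)
    for (target in c("all", "negatives_only")) {
      keep_oracle <- brute_force_renn(s$x, s$y, k = 3, target = target,
                                      keys = sample_keys(s))
      res <- renn_edit(s, target = target)
      expect_equal(sample_keys(res$samples), sample_keys(s)[keep_oracle])
    }
  }
})

test_that("renn rejects degenerate inputs", {
  s <- random_sample_set(2, 1, dims = 2, seed = 1)
  expect_error(renn_edit(s), "at least 4")
  # one positive amid many negatives: editing would empty the positive class
  x <- rbind(matrix(rnorm(20, 0, 0.5), 10, 2), c(0, 0))
  s2 <- sample_set(x, c(rep(0L, 10), 1L),
                   data.frame(chain = "X", resno = 1:11))
  expect_error(renn_edit(s2, target = "all"), "positive")
})

test_that("separable data give hardness below 0.5, a mislabeled duplicate above", {
  s <- random_sample_set(20, 20, dims = 2, sep = 10, seed = 5)
  ih <- instance_hardness(s, folds = 5, seed = 42)
  expect_true(all(ih >= 0 & ih <= 1))
  expect_true(all(ih < 0.5))

  # plant a mislabeled copy of a deep positive
  x2 <- rbind(s$x, s$x[1, ] + 0.01)
  s2 <- sample_set(x2, c(s$y, 0L), data.frame(chain = "X", resno = 1:41))
  ih2 <- instance_hardness(s2, folds = 5, seed = 42)
  expect_gt(ih2[41], 0.5)
  # cross-check against an independently fitted logistic model on the rest
  fit <- suppressWarnings(stats::glm.fit(cbind(1, scale(s$x)), s$y,
                                         family = stats::binomial()))
  beta <- fit$coefficients; beta[is.na(beta)] <- 0
  znew <- (x2[41, ] - colMeans(s$x)) / apply(s$x, 2, sd)
  p_neg <- 1 - stats::plogis(sum(c(1, znew) * beta))
  expect_gt(1 - p_neg, 0.5)  # the independent model also calls it positive
})

test_that("hardness scores stay in [0,1] on random inputs and are seed-deterministic", {
  for (seed in 1:3) {
    s <- random_sample_set(15, 30, dims = 5, sep = 0.5, seed = seed)
    ih <- instance_hardness(s, seed = 7)
    expect_true(all(ih >= 0 & ih <= 1))
    expect_equal(as.numeric(ih), as.numeric(instance_hardness(s, seed = 7)))
  }
})

test_that("iht removes exactly the hardest negatives down to a 1:1 balance", {
  s <- random_sample_set(10, 30, dims = 4, sep = 1, seed = 9)
  withr::with_seed(10, scores <- runif(40))
  res <- iht_resample(s, scores)
  expect_equal(unname(res$report$after_counts), c(10L, 10L))
  # sort oracle: the 20 highest-score negatives go
  neg <- which(s$y == 0L)
  expected_removed <- sample_keys(s)[neg[order(-scores[neg])][1:20]]
  expect_setequal(res$report$removed_ids, expected_removed)
  # minority untouched
  expect_true(all(sample_keys(s)[s$y == 1L] %in% sample_keys(res$samples)))
})

test_that("iht is a no-op on balanced data and rejects impossible ratios", {
  s <- random_sample_set(12, 12, dims = 3, seed = 11)
  withr::with_seed(12, scores <- runif(24))
  res <- iht_resample(s, scores)
  expect_length(res$report$removed_ids, 0)
  expect_error(iht_resample(s, scores, ratio = 2), "minority")
})

test_that("iht tie-breaking by provenance key makes removal deterministic", {
  s <- random_sample_set(3, 7, dims = 2, seed = 13)
  scores <- rep(0.5, 10)  # all tied: lowest keys removed first
  res <- iht_resample(s, scores)
  neg_keys <- sort(sample_keys(s)[s$y == 0L])
  expect_equal(sort(res$report$removed_ids), neg_keys[1:4])
  expect_equal(res$report$removed_ids,
               iht_resample(s, scores)$report$removed_ids)
})
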