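# Four well-separated Gaussian blobs in a 2-D code space.
blob_codes <- function(n_per_class = 25, sd = 0.05, seed = 1) {
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4), c(4, 4))
  set.seed(seed)
  codes <- NULL; labels <- integer(0)
  for (cl in 1:4) {
    codes <- rbind(codes, cbind(rnorm(n_per_class, centers[cl, 1], sd),
                                rnorm(n_per_class, centers[cl, 2], sd)))
    labels <- c(labels, rep(cl, n_per_class))
  }
  list(codes = codes, labels = labels)
}

test_that("separable pairs are classified with zero training error", {
  b <- blob_codes()
  ens <- train_pairwise(b$codes, b$labels)
  expect_length(ens$members, 6)
  expect_equal(predict(ens, b$codes), b$labels)
  # member S12 separates classes 1 and 2 perfectly
  m12 <- ens$members[[1]]
  d <- b$codes %*% m12$w + m12$b
  expect_true(all(d[b$labels == 1] > 0))
  expect_true(all(d[b$labels == 2] < 0))
})

test_that("sample duplication leaves the decision boundaries unchanged", {
  b <- blob_codes(n_per_class = 15)
  e1 <- train_pairwise(b$codes, b$labels)
  e2 <- train_pairwise(rbind(b$codes, b$codes), c(b$labels, b$labels))
  for (k in 1:6) {
    expect_equal(e2$members[[k]]$w, e1$members[[k]]$w, tolerance = 1e-4)
    expect_equal(e2$members[[k]]$b, e1$members[[k]]$b, tolerance = 1e-4)
  }
})

test_that("relabeling classes permutes predictions consistently", {
  b <- blob_codes(n_per_class = 12, seed = 3)
  perm <- c(3L, 1L, 4L, 2L)   # class i renamed to perm[i]
  e1 <- train_pairwise(b$codes, b$labels)
  e2 <- train_pairwise(b$codes, perm[b$labels])
  set.seed(4)
  probe <- matrix(runif(40, -1, 5), ncol = 2)
  expect_equal(perm[predict(e1, probe)], predict(e2, probe))
})

test_that("a missing class is rejected at training time", {
  b <- blob_codes()
  keep <- b$labels != 3
  expect_error(train_pairwise(b$codes[keep, ], b$labels[keep]),
               class = "rehabband_input_error")
})

test_that("vote tallies always sum to six and never exceed three", {
  b <- blob_codes(seed = 6)
  ens <- train_pairwise(b$codes, b$labels)
  set.seed(8)
  for (i in 1:50) {
    v <- vote(ens, runif(2, -2, 6))
    expect_identical(sum(v$tallies), 6L)
    expect_lte(max(v$tallies), 3L)
    expect_identical(v$tallies[v$winner], max(v$tallies))
  }
})

test_that("pairwise dominance implies victory over all 64 vote patterns", {
  pairs <- rehabband:::class_pairs(4)
  for (bits in 0:63) {
    signs <- ifelse(bitwAnd(bits, 2^(0:5)) > 0, 1, -1)
    ens <- fixed_ensemble(as.list(signs))
    v <- vote(ens, c(0, 0))
    expect_identical(sum(v$tallies), 6L)
    for (cl in 1:4) {
      wins <- vapply(seq_along(pairs), function(k) {
        pr <- pairs[[k]]
        if (pr[1] == cl) signs[k] > 0 else if (pr[2] == cl) signs[k] < 0 else NA
      }, logical(1))
      if (isTRUE(all(wins, na.rm = TRUE)) && sum(!is.na(wins)) == 3) {
        expect_identical(v$tallies[cl], 3L)
        expect_lte(max(v$tallies[-cl]), 2L)
        expect_identical(v$winner, cl)
      }
    }
  }
})

test_that("tally ties break on oriented decision-value sums, then lowest index", {
  # votes: S12->1, S13->3, S14->1, S23->2, S24->2, S34->4: tallies (2,2,1,1)
  ens <- fixed_ensemble(list(0.1, -0.5, 0.2, 0.9, 0.8, -0.3))
  v <- vote(ens, c(0, 0))
  expect_identical(v$tallies, c(2L, 2L, 1L, 1L))
  # score(1) = 0.1 - 0.5 + 0.2 = -0.2 < score(2) = -0.1 + 0.9 + 0.8 = 1.6
  expect_identical(v$winner, 2L)
  expect_identical(vote(ens, c(0, 0))$winner, 2L)   # deterministic

  # all-zero decisions: every member votes its lower class; tallies (3,2,1,0),
  # and an exact zero favours the lower index of the pair
  ens0 <- fixed_ensemble(list(0, 0, 0, 0, 0, 0))
  v0 <- vote(ens0, c(0, 0))
  expect_identical(v0$tallies, c(3L, 2L, 1L, 0L))
  expect_identical(v0$winner, 1L)
})

test_that("code dimension mismatches raise input errors", {
  b <- blob_codes()
  ens <- train_pairwise(b$codes, b$labels)
  expect_error(vote(ens, c(1, 2, 3)), class = "rehabband_input_error")
})
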