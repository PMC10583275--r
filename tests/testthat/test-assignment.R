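# Peak assignment by PCS matching and the PRE proximity screen.

test_that("predicted PCS tables have the right shape and entries", {
  set.seed(1)
  tens <- list(d1 = random_tensor(c(0, 0, 0)), d2 = random_tensor(c(5, 0, 0)))
  X <- matrix(stats::rnorm(9, sd = 10), 3, 3)
  tab <- predict_pcs_table(tens, X, candidate_names = c("a", "b", "c"))
  expect_equal(dim(tab), c(3, 2))
  expect_equal(tab["b", "d2"], pcs_forward(tens$d2, X[2, ]))
  zero <- list(z = chi_tensor(c(0, 0, 0), rep(0, 5)))
  expect_equal(unname(predict_pcs_table(zero, X)[, 1]), rep(0, 3))
})

test_that("the matching equals an exhaustive permutation search for n = 5", {
  set.seed(17)
  for (rep_i in 1:5) {
    pred <- matrix(stats::rnorm(15), 5, 3,
                   dimnames = list(paste0("c", 1:5), paste0("d", 1:3)))
    obs <- matrix(stats::rnorm(15), 5, 3,
                  dimnames = list(paste0("p", 1:5), paste0("d", 1:3)))
    res <- assign_peaks(pred, obs)
    cost <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) cost[i, j] <- mean((pred[j, ] - obs[i, ])^2)
    oracle <- brute_force_assign(cost)
    expect_equal(res$assignment$candidate_index, oracle$assignment)
    expect_equal(res$total_cost, oracle$total, tolerance = 1e-12)
  }
})

test_that("six tryptophan-like peaks are assigned correctly at 0.01 ppm noise", {
  set.seed(29)
  correct <- 0
  for (rep_i in 1:10) {
    tens <- lapply(1:3, function(i) random_tensor(stats::rnorm(3, sd = 12)))
    names(tens) <- paste0("d", 1:3)
    X <- matrix(stats::rnorm(18, sd = 9), 6, 3)
    pred <- predict_pcs_table(tens, X, candidate_names = paste0("W", 1:6))
    perm <- sample(6)
    obs <- pred[perm, ] + stats::rnorm(18, sd = 0.01)
    rownames(obs) <- paste0("peak", 1:6)
    res <- assign_peaks(pred, obs)
    if (all(res$assignment$candidate_index == perm)) correct <- correct + 1
  }
  expect_gte(correct, 9)
})

test_that("identical candidate rows are flagged ambiguous with stable tie-break", {
  pred <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 6))
  colnames(pred) <- c("d1", "d2")
  obs <- rbind(p1 = c(1.01, 2.01), p2 = c(5.02, 5.99))
  colnames(obs) <- c("d1", "d2")
  res <- assign_peaks(pred, obs)
  expect_true(res$ambiguous)
  expect_equal(res$assignment$candidate[1], "a")  # index-order tie-break
})

test_that("missing observations use shared datasets only; disjoint sets error", {
  set.seed(3)
  tens <- list(d1 = random_tensor(c(0, 0, 0)), d2 = random_tensor(c(8, 0, 0)))
  X <- matrix(stats::rnorm(12, sd = 8), 4, 3)
  pred <- predict_pcs_table(tens, X, candidate_names = paste0("c", 1:4))
  obs <- pred + stats::rnorm(8, sd = 0.005)
  obs[1, "d2"] <- NA                   # partially observed peak
  rownames(obs) <- paste0("p", 1:4)
  res <- assign_peaks(pred, obs)
  expect_equal(res$assignment$candidate_index, 1:4)

  bad <- matrix(NA_real_, 1, 2, dimnames = list("p", c("d1", "d2")))
  expect_error(assign_peaks(pred, bad), "no values")
  noshare <- matrix(1, 1, 1, dimnames = list("p", "other"))
  expect_error(assign_peaks(pred, noshare), "share no dataset")
})

test_that("total matching cost is invariant to observation order", {
  set.seed(53)
  pred <- matrix(stats::rnorm(12), 4, 3,
                 dimnames = list(paste0("c", 1:4), paste0("d", 1:3)))
  obs <- matrix(stats::rnorm(12), 4, 3,
                dimnames = list(paste0("p", 1:4), paste0("d", 1:3)))
  r1 <- assign_peaks(pred, obs)
  shuf <- sample(4)
  r2 <- assign_peaks(pred, obs[shuf, ])
  expect_equal(r1$total_cost, r2$total_cost, tolerance = 1e-12)
})

test_that("noise-free assignments are exact for n up to 8", {
  set.seed(61)
  for (n in c(3, 6, 8)) {
    tens <- lapply(1:3, function(i) random_tensor(stats::rnorm(3, sd = 12)))
    names(tens) <- paste0("d", 1:3)
    X <- matrix(stats::rnorm(3 * n, sd = 9), n, 3)
    pred <- predict_pcs_table(tens, X, candidate_names = paste0("c", 1:n))
    perm <- sample(n)
    obs <- pred[perm, ]
    rownames(obs) <- paste0("p", 1:n)
    res <- assign_peaks(pred, obs)
    expect_equal(res$assignment$candidate_index, perm)
  }
})

test_that("assignment accuracy degrades as noise grows", {
  set.seed(71)
  acc <- vapply(c(0.005, 0.03, 0.1), function(sig) {
    hits <- 0; total <- 0
    for (rep_i in 1:15) {
      # PCS patterns on the 0.1-ppm scale where the noise levels matter
      pred <- matrix(stats::rnorm(18, sd = 0.15), 6, 3,
                     dimnames = list(paste0("c", 1:6), paste0("d", 1:3)))
      perm <- sample(6)
      obs <- pred[perm, ] + stats::rnorm(18, sd = sig)
      rownames(obs) <- paste0("p", 1:6)
      res <- assign_peaks(pred, obs)
      hits <- hits + sum(res$assignment$candidate_index == perm)
      total <- total + 6
    }
    hits / total
  }, 0)
  expect_gte(acc[1], acc[2] - 0.02)
  expect_gte(acc[2], acc[3] - 0.02)
  expect_gt(acc[1], acc[3])
})

test_that("the PRE screen flags only candidates within the radius", {
  metal <- c(0, 0, 0)
  X <- rbind(c(5, 0, 0), c(20, 0, 0), c(0, 12.9, 0))
  expect_equal(pre_screen(metal, X, radius = 13), c(TRUE, FALSE, TRUE))
  expect_equal(pre_screen(metal, X, radius = 0.1), rep(FALSE, 3))
  expect_error(pre_screen(metal, X, radius = -1))
})
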