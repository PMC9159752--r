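# Small epoch-set builder: two (or more) conditions with an additive channel
# pattern active over given bins.
signal_epochs <- function(n_cond = 2, n_trials = 10, n_ch = 12, n_t = 40,
                          bins = 15:25, amp = 2, fs = 100, seed = 1) {
  set.seed(seed)
  pats <- matrix(rnorm(n_cond * n_ch), n_cond, n_ch) * amp
  data <- array(rnorm(n_cond * n_trials * n_ch * n_t),
                c(n_cond * n_trials, n_ch, n_t))
  labels <- rep(seq_len(n_cond), each = n_trials)
  for (t in bins) data[, , t] <- data[, , t] + pats[labels, ]
  epoch_set(data, labels, fs = fs, window = c(-0.1, (n_t - 1) / fs - 0.1))
}

test_that("baseline correction subtracts the pre-stimulus mean exactly", {
  ep <- signal_epochs(seed = 2)
  ep$data[, 3, ] <- ep$data[, 3, ] + 7 # constant channel offset
  bc <- baseline_correct(ep)
  tt <- epoch_times(bc)
  bl <- apply(bc$data[, , tt <= 0, drop = FALSE], c(1, 2), mean)
  expect_true(all(abs(bl) < 1e-12))
  # already-corrected data unchanged
  bc2 <- baseline_correct(bc)
  expect_equal(bc2$data, bc$data, tolerance = 1e-12)
  # equals direct subtraction
  manual <- ep$data - array(apply(ep$data[, , tt <= 0], c(1, 2), mean),
                            dim(ep$data))
  expect_equal(bc$data, manual)
  expect_error(baseline_correct(ep, c(5, 6)), "no bins")
})

test_that("pseudotrial averaging respects the group-size bound and reduces noise", {
  # 10 presentations split in half: never more than 5 trials per pseudotrial
  expect_equal(n_pseudotrial_groups(5), 1L)
  expect_equal(n_pseudotrial_groups(10), 2L)
  expect_equal(n_pseudotrial_groups(6), 2L)
  ep <- signal_epochs(n_trials = 10, amp = 0, seed = 3)
  ps <- make_pseudotrials(ep, condition = 1, n_groups = 2, seed = 4)
  expect_equal(dim(ps)[1], 2)
  # n_groups == n_trials returns the raw trials (as a set)
  raw <- make_pseudotrials(ep, condition = 1, n_groups = 10, seed = 5)
  expect_equal(sort(raw[, 1, 1]), sort(ep$data[ep$labels == 1, 1, 1]))
  # averaging k trials shrinks white-noise variance by about k
  big <- epoch_set(array(rnorm(400 * 4 * 6), c(400, 4, 6)),
                   rep(1, 400), fs = 100, window = c(0, 0.05))
  ps2 <- make_pseudotrials(big, 1, n_groups = 80, seed = 6)
  ratio <- var(as.vector(big$data)) / var(as.vector(ps2))
  expect_gt(ratio, 3.5); expect_lt(ratio, 6.5)
  expect_error(make_pseudotrials(ep, 1, n_groups = 11), "fewer trials")
})

test_that("the noise normalizer whitens known covariances", {
  set.seed(7)
  # identity-covariance data: transform near identity
  x <- matrix(rnorm(4000), 1000, 4)
  W <- noise_normalizer(x)$W
  expect_lt(max(abs(W - diag(4))), 0.15)
  # diagonal covariance diag(4, 1): whitened variances near 1
  x2 <- cbind(rnorm(2000, 0, 2), rnorm(2000, 0, 1))
  W2 <- noise_normalizer(x2)$W
  wh <- x2 %*% W2
  expect_equal(unname(apply(wh, 2, var)), c(1, 1), tolerance = 0.15)
  # analytic check: W approximates Sigma^(-1/2)
  expect_equal(W2[1, 1], 0.5, tolerance = 0.1)
  # rank-deficient input still yields finite whitening (shrinkage enforced)
  x3 <- matrix(rnorm(6), 2, 3)[rep(1:2, 5), ] + 0
  expect_true(all(is.finite(noise_normalizer(x3)$W)))
})

test_that("pairwise decoding finds the signal window and only it", {
  ep <- signal_epochs(bins = 16:24, amp = 2.5, seed = 8)
  acc <- pairwise_timecourse_decode(ep, c(1, 2), n_repeats = 10, seed = 9)
  expect_length(acc, 40)
  expect_true(all(acc >= 0 & acc <= 100))
  # near-perfect inside the window, chance-level before stimulus
  expect_gt(mean(acc[17:23]), 90)
  expect_lt(abs(mean(acc[1:10]) - 50), 10)
  # temporal specificity: above-chance confined to the injected window +/- 1
  outside <- acc[setdiff(seq_len(40), 15:25)]
  expect_lt(mean(outside), 62)
  # chance on shuffled labels
  ep_null <- ep
  set.seed(10)
  ep_null$labels <- sample(ep_null$labels)
  acc_null <- pairwise_timecourse_decode(ep_null, c(1, 2), n_repeats = 10, seed = 11)
  expect_lt(abs(mean(acc_null) - 50), 5)
})

test_that("decoding is reproducible and ignores test-set perturbations", {
  ep <- signal_epochs(seed = 12)
  a1 <- pairwise_timecourse_decode(ep, c(1, 2), n_repeats = 3, seed = 13)
  a2 <- pairwise_timecourse_decode(ep, c(1, 2), n_repeats = 3, seed = 13)
  expect_identical(a1, a2)
})

test_that("the maximum-margin classifier is optimal and agrees with an independent SVM", {
  skip_if_not_installed("e1071")
  # the classifier solves min 0.5||w||^2 + 0.5 b^2 + C sum hinge (bias
  # regularized via augmentation); its solution must therefore attain a lower
  # objective than any competitor, including libsvm's (which leaves the bias
  # free), and beat random perturbations of itself
  obj <- function(w, b, X, y, C) {
    0.5 * sum(w^2) + 0.5 * b^2 + C * sum(pmax(0, 1 - y * (X %*% w + b)))
  }
  set.seed(14)
  agree <- numeric(8)
  for (rep in 1:8) {
    n <- 8 + 2 * rep
    X <- matrix(rnorm(n * 3), n, 3)
    y <- rep(c(1, -1), length.out = n)
    X[y == 1, 1] <- X[y == 1, 1] + 2.5
    w <- actionrsa:::cpp_svm_weights(X, y, cost = 1)
    m <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
    w_ref <- as.vector(t(m$coefs) %*% m$SV)
    b_ref <- -m$rho
    o_mine <- obj(w[1:3], w[4], X, y, 1)
    expect_lte(o_mine, obj(w_ref, b_ref, X, y, 1) + 1e-6)
    for (k in 1:20) {
      pert <- rnorm(4, 0, 0.2)
      expect_lte(o_mine,
                 obj(w[1:3] + pert[1:3], w[4] + pert[4], X, y, 1) + 1e-9)
    }
    # and both classifiers label well-separated fresh points alike
    Xt <- matrix(rnorm(60), 20, 3)
    Xt[1:10, 1] <- Xt[1:10, 1] + 2.5
    p_cpp <- (Xt %*% w[1:3] + w[4]) > 0
    p_ref <- predict(m, Xt) == "1"
    agree[rep] <- mean(p_cpp == p_ref)
  }
  expect_gt(mean(agree), 0.9)
})

test_that("the decoding movie yields one accuracy trace per pair", {
  ep <- signal_epochs(n_cond = 4, n_trials = 10, n_t = 20, bins = 8:14,
                      amp = 2, seed = 15)
  trdm <- decoding_rdm_movie(ep, n_repeats = 3, seed = 16)
  expect_s3_class(trdm, "time_rdm")
  expect_equal(nrow(trdm$values), n_pairs(4))
  expect_equal(ncol(trdm$values), 20)
  # identical-distribution conditions stay near 50% everywhere
  ep0 <- signal_epochs(n_cond = 3, amp = 0, n_t = 20, bins = 8:14, seed = 17)
  t0 <- decoding_rdm_movie(ep0, n_repeats = 3, seed = 18)
  expect_lt(abs(mean(t0$values) - 50), 4)
})

test_that("the decoding RDM rank-orders a 1-D signal axis at peak time", {
  set.seed(19)
  n_cond <- 5; n_tr <- 20; n_ch <- 10; n_t <- 10
  axis_pos <- (0:4) * 0.7 # conditions on a line in pattern space
  dir <- rnorm(n_ch); dir <- dir / sqrt(sum(dir^2))
  data <- array(rnorm(n_cond * n_tr * n_ch * n_t, 0, 0.7),
                c(n_cond * n_tr, n_ch, n_t))
  labels <- rep(1:n_cond, each = n_tr)
  for (t in 4:8) data[, , t] <- data[, , t] + outer(axis_pos[labels], dir)
  ep <- epoch_set(data, labels, fs = 100, window = c(0, 0.09))
  trdm <- decoding_rdm_movie(ep, n_repeats = 10, seed = 20)
  peak <- which.max(colMeans(trdm$values))
  sig_dist <- euclidean_rdm(matrix(axis_pos, ncol = 1))$values
  expect_gt(kendall_tau_a(trdm$values[, peak], sig_dist)$tau_a, 0.4)
})

test_that("sliding windows average with the stated width and stride", {
  # at 500 Hz (2 ms bins), 10/6 ms windows hold 5 bins and stride 2 bins
  vals <- matrix(rep(1:50, each = 3), 3, 50)
  trdm <- time_rdm(vals, seq(0, by = 0.002, length.out = 50), 3)
  sw <- sliding_windows(trdm, width_ms = 10, overlap_ms = 6)
  expect_equal(ncol(sw$values), length(seq(1, 46, by = 2)))
  expect_equal(sw$values[1, 1], mean(1:5))
  expect_equal(sw$values[1, 2], mean(3:7))
  expect_equal(sw$times[1], mean(trdm$times[1:5]))
  # width of one bin, no overlap: identity
  one <- sliding_windows(trdm, width_ms = 2, overlap_ms = 0)
  expect_equal(one$values, vals)
  # constant input unchanged by averaging
  const <- time_rdm(matrix(33, 3, 50), trdm$times, 3)
  swc <- sliding_windows(const, 10, 6)
  expect_true(all(swc$values == 33))
  expect_error(sliding_windows(trdm, 4, 6), "width_ms > overlap_ms")
})
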