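make_groups <- function(n, seed = 1) {
  set.seed(seed)
  predictor_groups(
    visual = list(euclidean_rdm(matrix(rnorm(n), n, 1)),
                  euclidean_rdm(matrix(rnorm(n * 2), n, 2))),
    action = list(euclidean_rdm(matrix(rnorm(n), n, 1))),
    social = list(euclidean_rdm(matrix(rnorm(n), n, 1))))
}

test_that("regression predictions match an independent normal-equations solver", {
  set.seed(2)
  n <- 30
  pg <- make_groups(n)
  X <- actionrsa:::predictor_matrix(c(pg$visual, pg$action, pg$social))
  y <- rnorm(nrow(X))
  te <- rnorm(nrow(X))
  fit <- fit_predict_tausq(y, te, X)
  # solve the normal equations directly
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  pred <- as.vector(Xi %*% beta)
  expect_equal(fit$coef, as.vector(beta), tolerance = 1e-10)
  expect_equal(fit$tausq, kendall_tau_a(pred, te)$tau_a^2, tolerance = 1e-12)
  # test == train == single predictor -> tausq = 1
  single <- pg$action[[1]]
  perfect <- fit_predict_tausq(single, single, list(single))
  expect_equal(perfect$tausq, 1)
  # independent test target: tausq near its null expectation
  m <- 200
  null_taus <- replicate(60, {
    fit_predict_tausq(rnorm(m), rnorm(m),
                      matrix(rnorm(m * 2), m, 2))$tausq
  })
  # E[tau^2] under independence ~ 2(2m+5)/(9m(m-1))
  expect_lt(mean(null_taus), 5 * 2 * (2 * m + 5) / (9 * m * (m - 1)))
  # collinear predictors: minimum-norm with warning
  Xc <- cbind(X[, 1], X[, 1])
  expect_warning(fc <- fit_predict_tausq(y, te, Xc), "collinear")
  expect_true(is.finite(fc$tausq))
})

test_that("commonality components obey the inclusion-exclusion identities", {
  # variance carried by V alone
  r <- c(V = 1, A = 0, S = 0, VA = 1, VS = 1, AS = 0, VAS = 1)
  cp <- commonality_partition(r)
  expect_equal(unname(cp["unique_V"]), 1)
  expect_equal(unname(sum(abs(cp[2:7]))), 0)
  # symmetric inputs give equal unique terms
  rs <- c(V = 0.3, A = 0.3, S = 0.3, VA = 0.5, VS = 0.5, AS = 0.5, VAS = 0.6)
  cps <- commonality_partition(rs)
  expect_equal(unname(cps["unique_V"]), unname(cps["unique_A"]))
  expect_equal(unname(cps["unique_A"]), unname(cps["unique_S"]))
  # components re-sum to the full model exactly on random inputs
  set.seed(3)
  for (i in 1:200) {
    x <- runif(7); names(x) <- c("V", "A", "S", "VA", "VS", "AS", "VAS")
    cpx <- commonality_partition(x)
    expect_equal(unname(sum(cpx[1:7])), unname(x["VAS"]), tolerance = 1e-12)
  }
  expect_error(commonality_partition(c(V = 1)), "must contain")
})

test_that("split-subject variance partitioning recovers a planted structure", {
  set.seed(4)
  n <- 40
  pg <- make_groups(n, seed = 5)
  # target built purely from the visual group
  tv <- 2 * scale(pg$visual[[1]]$values)[, 1] + scale(pg$visual[[2]]$values)[, 1]
  subs <- lapply(1:12, function(i) make_rdm(tv + rnorm(length(tv), 0, 0.2), n))
  vp <- crossval_varpart(subs, pg, "split_subjects", n_iter = 40, seed = 6,
                         signif = FALSE)
  m <- colMeans(vp$components)
  expect_gt(m["unique_V"], 0.5)
  expect_lt(abs(m["unique_A"]), 0.05)
  expect_lt(abs(m["unique_S"]), 0.05)
  expect_gt(m["unique_V"], 10 * max(abs(m["unique_A"]), abs(m["unique_S"])))
  # per-iteration algebraic closure
  expect_true(all(abs(rowSums(vp$components[, 1:7]) - vp$components[, 8]) < 1e-12))
  # determinism under a fixed seed
  vp2 <- crossval_varpart(subs, pg, "split_subjects", n_iter = 40, seed = 6,
                          signif = FALSE)
  expect_identical(vp$components, vp2$components)
})

test_that("three equal planted contributions yield symmetric components", {
  # with mutually independent single-feature groups of equal planted weight,
  # the three unique components agree in expectation and no group wins
  # systematically across independent worlds
  winners <- integer(4)
  rel_spread <- numeric(4)
  for (s in 1:4) {
    set.seed(100 * s)
    n <- 60
    pg <- predictor_groups(
      visual = list(euclidean_rdm(matrix(rnorm(n), n, 1))),
      action = list(euclidean_rdm(matrix(rnorm(n), n, 1))),
      social = list(euclidean_rdm(matrix(rnorm(n), n, 1))))
    tv <- scale(pg$visual[[1]]$values)[, 1] + scale(pg$action[[1]]$values)[, 1] +
      scale(pg$social[[1]]$values)[, 1]
    subs <- lapply(1:10, function(i) make_rdm(tv + rnorm(length(tv), 0, 2), n))
    vp <- crossval_varpart(subs, pg, "split_subjects", n_iter = 25, seed = s,
                           signif = FALSE)
    m <- colMeans(vp$components[, 1:3])
    winners[s] <- which.max(m)
    rel_spread[s] <- (max(m) - min(m)) / mean(m)
  }
  expect_lt(mean(rel_spread), 0.12)
  expect_gt(length(unique(winners)), 1)
})

test_that("the estimate-split scheme handles partial coverage", {
  set.seed(9)
  n <- 24
  pg <- make_groups(n, seed = 10)
  tv <- scale(pg$social[[1]]$values)[, 1]
  np <- n_pairs(n)
  # partial-coverage subjects: each covers a random 60% of pairs
  subs <- lapply(1:20, function(i) {
    ev <- as.numeric(runif(np) < 0.6)
    make_rdm(ifelse(ev > 0, tv + rnorm(np, 0, 0.3), 0), n, evidence = ev)
  })
  vp <- crossval_varpart(subs, pg, "split_estimates", n_iter = 30, seed = 11,
                         signif = FALSE)
  m <- colMeans(vp$components)
  expect_gt(m["unique_S"], m["unique_V"])
  expect_gt(m["unique_S"], m["unique_A"])
  expect_true(all(vp$n_masked >= 0))
  expect_true(all(abs(rowSums(vp$components[, 1:7]) - vp$components[, 8]) < 1e-12))
})

test_that("time-resolved partitioning orders staggered injected effects", {
  set.seed(12)
  n <- 16
  pg <- predictor_groups(
    visual = list(euclidean_rdm(matrix(rnorm(n), n, 1))),
    action = list(euclidean_rdm(matrix(rnorm(n), n, 1))),
    social = list(euclidean_rdm(matrix(rnorm(n), n, 1))))
  times <- seq(0, by = 0.01, length.out = 50)
  window_of <- list(visual = 10:45, action = 25:45, social = 40:45)
  zv <- lapply(pg, function(g) scale(g[[1]]$values)[, 1])
  subs <- lapply(1:14, function(i) {
    vals <- matrix(rnorm(n_pairs(n) * 50, 0, 0.6), n_pairs(n), 50)
    for (g in names(window_of)) {
      vals[, window_of[[g]]] <- vals[, window_of[[g]]] + zv[[g]]
    }
    time_rdm(50 + 5 * pmax(pmin(vals, 10), -10), times, n)
  })
  vp <- crossval_varpart(subs, pg, "split_half_neural", n_iter = 30, seed = 13,
                         signif = FALSE)
  od <- onset_distribution_compare(vp, inference_config(n_perm = 1000))
  on <- od$summary$mean
  names(on) <- od$summary$component
  expect_lt(on["unique_V"], on["unique_A"])
  expect_lt(on["unique_A"], on["unique_S"])
  expect_equal(unname(on["unique_V"]), times[10], tolerance = 0.03)
  # identical injections: onset difference not significant
  subs_same <- lapply(1:14, function(i) {
    vals <- matrix(rnorm(n_pairs(n) * 50, 0, 0.6), n_pairs(n), 50)
    for (g in names(window_of)) vals[, 20:45] <- vals[, 20:45] + zv[[g]]
    time_rdm(50 + 5 * pmax(pmin(vals, 10), -10), times, n)
  })
  vps <- crossval_varpart(subs_same, pg, "split_half_neural", n_iter = 30,
                          seed = 14, signif = FALSE)
  ods <- onset_distribution_compare(vps, inference_config(n_perm = 1000))
  expect_true(all(is.na(ods$pairwise$p) | ods$pairwise$p > 0.01))
  # onsets live on the window grid
  expect_true(all(is.na(od$onsets) | od$onsets %in% times))
})
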