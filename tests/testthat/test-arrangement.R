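planar_truth <- function(n, seed = 1) {
  set.seed(seed)
  euclidean_rdm(matrix(rnorm(2 * n), n, 2))
}

test_that("the synthetic arranger reproduces embeddable geometry on screen", {
  # equilateral triangle: all on-screen distances equal
  tri <- make_rdm(c(1, 1, 1), 3)
  tr <- simulate_arranger(tri, 1:3, placement_noise = 0, seed = 1)
  d <- as.vector(dist(tr$coords))
  expect_true(all(abs(d - d[1]) < 1e-9))
  expect_true(all(sqrt(rowSums(tr$coords^2)) <= 1 + 1e-12))
  # 2D-embeddable sub-RDM, no noise: on-screen distances proportional (tau 1)
  truth <- planar_truth(12)
  tr2 <- simulate_arranger(truth, 1:8, placement_noise = 0, seed = 2)
  d2 <- as.vector(dist(tr2$coords))
  sub <- truth$values[condensed_index(all_pairs(8)[, 1], all_pairs(8)[, 2], 12)]
  expect_equal(kendall_tau_a(d2, sub)$tau_a, 1)
  expect_equal(cor(d2, sub), 1, tolerance = 1e-9)
  # heavy placement noise destroys the correspondence on average
  set.seed(3)
  taus <- replicate(30, {
    t3 <- simulate_arranger(truth, 1:8, placement_noise = 5)
    kendall_tau_a(as.vector(dist(t3$coords)), sub)$tau_a
  })
  expect_lt(abs(mean(taus)), 0.15)
  # degenerate all-zero sub-RDM: disk center with warning
  zero <- make_rdm(rep(0, 3), 3)
  expect_warning(tz <- simulate_arranger(zero, 1:3, 0), "degenerate")
  expect_true(all(tz$coords == 0))
})

test_that("evidence accrual follows the distance-squared multiplicative rule", {
  s <- new_session(1:4, criterion = 0.5, max_trial_size = 4)
  # diametrically opposite rim points: w = 1, evidence jumps to 1
  tr <- structure(list(subset = c(1L, 2L),
                       coords = rbind(c(-1, 0), c(1, 0))),
                  class = "arrangement_trial")
  s1 <- update_evidence(tr, s)
  expect_equal(s1$evidence[condensed_index(1, 2, 4)], 1)
  # coincident points: no evidence gained
  tr0 <- structure(list(subset = c(3L, 4L),
                        coords = rbind(c(0.3, 0.3), c(0.3, 0.3))),
                   class = "arrangement_trial")
  s2 <- update_evidence(tr0, s1)
  expect_equal(s2$evidence[condensed_index(3, 4, 4)], 0)
  # two trials at w = 0.3 give evidence 1 - 0.7^2 = 0.51, over criterion
  d_for_w <- 2 * sqrt(0.3)
  trw <- structure(list(subset = c(1L, 3L),
                        coords = rbind(c(0, 0), c(d_for_w / sqrt(2), d_for_w / sqrt(2)))),
                   class = "arrangement_trial")
  s3 <- update_evidence(trw, update_evidence(trw, s2))
  expect_equal(s3$evidence[condensed_index(1, 3, 4)], 1 - 0.7^2, tolerance = 1e-12)
  expect_gte(s3$evidence[condensed_index(1, 3, 4)], 0.5)
  # monotonically nondecreasing over trials
  expect_true(all(s3$evidence >= s2$evidence - 1e-15))
})

test_that("lift-the-weakest covers all items first, targets weak pairs, then stops", {
  truth <- planar_truth(20, seed = 4)
  set.seed(5)
  s <- new_session(1:20, criterion = 0.5, max_trial_size = 6)
  seen <- integer(0)
  # first subsets cover all items before any repeats
  while (length(seen) < 20) {
    sub <- lift_the_weakest(s, est = truth)
    fresh <- setdiff(sub, seen)
    expect_true(length(fresh) > 0)
    tr <- simulate_arranger(truth, s$item_ids[sub], placement_noise = 0.02)
    tr$subset <- sub
    s <- update_evidence(tr, s)
    seen <- union(seen, sub)
  }
  # one pair left below criterion -> next subset contains that pair
  s$evidence[] <- 1
  k_weak <- condensed_index(7, 13, 20)
  s$evidence[k_weak] <- 0.1
  sub <- lift_the_weakest(s, est = truth)
  expect_true(all(c(7, 13) %in% sub))
  # session at criterion -> completion signal
  s$evidence[] <- 1
  expect_null(lift_the_weakest(s))
  expect_true(session_complete(s))
})

test_that("inverse MDS recovers sessions and is scale/rotation invariant", {
  truth <- planar_truth(15, seed = 6)
  # single full-set trial of an exactly 2D-embeddable RDM: tau = 1
  tr <- simulate_arranger(truth, 1:15, placement_noise = 0, seed = 7)
  s <- new_session(1:15, criterion = 0.5, max_trial_size = 15)
  s <- update_evidence(tr, s)
  est <- inverse_mds_estimate(s)
  expect_equal(kendall_tau_a(est$values, truth$values)$tau_a, 1)
  # output normalized to unit RMS
  expect_equal(sqrt(mean(est$values^2)), 1, tolerance = 1e-9)
  # scale invariance: shrinking a trial's coordinates leaves the estimate alone
  s2 <- new_session(1:15, criterion = 0.5, max_trial_size = 15)
  tr_half <- tr; tr_half$coords <- tr$coords * 0.5
  s2 <- update_evidence(tr_half, update_evidence(tr, s2))
  est2 <- inverse_mds_estimate(s2)
  expect_equal(est2$values, est$values, tolerance = 1e-6)
  # rotation/reflection invariance of every trial
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  s3 <- new_session(1:15, criterion = 0.5, max_trial_size = 15)
  tr_rot <- tr; tr_rot$coords <- tr$coords %*% R %*% diag(c(1, -1))
  s3 <- update_evidence(tr_rot, s3)
  expect_equal(inverse_mds_estimate(s3)$values, est$values, tolerance = 1e-9)
  # never co-presented pair -> informative error, masked when allowed
  s4 <- new_session(1:5, criterion = 0.5, max_trial_size = 3)
  tr4 <- simulate_arranger(truth, 1:3, 0, seed = 8); tr4$subset <- 1:3
  s4 <- update_evidence(tr4, s4)
  expect_error(inverse_mds_estimate(s4), "never co-presented")
  masked <- inverse_mds_estimate(s4, allow_missing = TRUE)
  expect_true(all(masked$evidence[condensed_index(c(4, 4), c(5, 5), 5)] == 0))
})

test_that("adaptive sessions at modest noise recover the ground truth order", {
  truth <- planar_truth(20, seed = 9)
  s <- simulate_session(truth, placement_noise = 0.02, criterion = 0.5,
                        max_trial_size = 8, trial_budget = 1200, seed = 10)
  expect_true(session_complete(s))
  est <- inverse_mds_estimate(s)
  expect_gte(kendall_tau_a(est$values, truth$values)$tau_a, 0.9)
  # identical seeds reproduce identical sessions
  s2 <- simulate_session(truth, placement_noise = 0.02, criterion = 0.5,
                         max_trial_size = 8, trial_budget = 1200, seed = 10)
  expect_identical(lapply(s$trials, `[[`, "coords"),
                   lapply(s2$trials, `[[`, "coords"))
})

test_that("end-to-end cohort recovery works for a feature-combination truth", {
  world <- gen_feature_set(gt_config_65(), seed = 11)
  truth <- truth_rdm(world)
  sessions <- gen_behavior_subjects(world, 20, design = "full_65", seed = 12)
  ests <- lapply(sessions, inverse_mds_estimate)
  avg <- average_rdms(ests)
  expect_gte(kendall_tau_a(avg$values, truth$values)$tau_a, 0.85)
})

test_that("leave-one-subject-out reliability tracks shared structure", {
  set.seed(13)
  # identical subjects -> all 1
  base <- random_rdm(12)
  expect_true(all(loo_reliability(list(base, base, base)) == 1))
  # independent random subjects -> mean near 0
  null_subj <- lapply(1:20, function(i) random_rdm(40))
  expect_lt(abs(mean(loo_reliability(null_subj))), 0.05)
  # reliability decreases monotonically with noise
  sig <- runif(n_pairs(25))
  rel_at <- function(noise) {
    subs <- lapply(1:12, function(i)
      make_rdm(sig + abs(rnorm(length(sig), 0, noise)), 25))
    mean(loo_reliability(subs))
  }
  rels <- vapply(c(0.05, 0.2, 0.6, 2), rel_at, 1.0)
  expect_true(all(diff(rels) < 0))
  # training-score outlier rule
  sc <- c(rnorm(20, 0.5, 0.01), 0.1)
  keep <- training_inclusion(sc)
  expect_true(all(keep[1:20]))
  expect_false(keep[21])
})
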