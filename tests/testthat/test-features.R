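test_that("rater exclusion applies the catch and repetitiveness rules", {
  items <- sprintf("i%02d", 1:10)
  tab <- rbind(
    ratings_of("good", items, fun = function(r) rep(1:5, 2)),
    ratings_of("two_vals", items, fun = function(r) rep(c(3L, 4L), 5)),
    ratings_of("three_vals", items, fun = function(r) rep(c(2L, 3L, 4L), length.out = 10)),
    ratings_of("catchfail", items, fun = function(r) rep(1:5, 2), catch_pass = FALSE))
  out <- exclude_raters(tab)
  kept <- unique(out$rater)
  expect_setequal(kept, c("good", "three_vals"))
  log <- attr(out, "exclusions")
  expect_setequal(log$rater, c("two_vals", "catchfail"))
  expect_match(log$reason[log$rater == "two_vals"], "repetitive")
  expect_match(log$reason[log$rater == "catchfail"], "catch")
  # surviving count equals an independent per-rater scan
  by_r <- split(tab, tab$rater)
  manual <- names(by_r)[vapply(by_r, function(d) {
    all(d$catch_pass) && length(unique(d$rating)) >= 3
  }, TRUE)]
  expect_setequal(kept, manual)
  # idempotent: re-running exclusions changes nothing
  out2 <- exclude_raters(out)
  expect_equal(out2$rater, out$rater)
  expect_equal(out2$rating, out$rating)
  expect_equal(nrow(attr(out2, "exclusions")), 0)
  expect_error(exclude_raters(tab[tab$rater == "two_vals", ]), "all raters")
})

test_that("rating aggregation matches group-by means and z-scoring removes offsets", {
  items <- sprintf("i%02d", 1:8)
  set.seed(2)
  base <- sample(1:3, 8, replace = TRUE)
  tab <- rbind(
    ratings_of("r1", items, fun = function(r) base),          # low scale user
    ratings_of("r2", items, fun = function(r) base + 2L))     # high scale user
  raw <- aggregate_ratings(tab, zscore = FALSE)
  expect_equal(unname(raw$means[items, "f"]), base + 1)
  expect_true(all(raw$n_raters == 2))
  # opposite constant offsets vanish under per-rater z-scoring
  z <- aggregate_ratings(tab, zscore = TRUE)
  zr1 <- aggregate_ratings(tab[tab$rater == "r1", ], zscore = TRUE)
  expect_equal(z$means, zr1$means, tolerance = 1e-12)
  # single rater, no z-scoring: means equal raw ratings
  one <- aggregate_ratings(tab[tab$rater == "r1", ], zscore = FALSE)
  expect_equal(unname(one$means[items, "f"]), as.numeric(base))
  # random table equals an independent aggregate()
  tab2 <- rbind(tab, ratings_of("r3", items, fun = function(r) sample(1:5, 8, TRUE)))
  agg <- aggregate_ratings(tab2, zscore = FALSE)
  ref <- aggregate(rating ~ item, data = tab2, FUN = mean)
  expect_equal(unname(agg$means[ref$item, "f"]), ref$rating)
})

test_that("split-half reliability behaves like a reliability coefficient", {
  items <- sprintf("i%02d", 1:20)
  signal <- rnorm(20)
  make_tab <- function(n_raters, noise_sd, seed) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(n_raters), function(r) {
      data.frame(rater = sprintf("r%02d", r), item = items, feature = "f",
                 rating = as.integer(cut(signal + rnorm(20, 0, noise_sd),
                                         c(-Inf, -1, -0.3, 0.3, 1, Inf))),
                 catch_pass = TRUE)
    }))
  }
  # near-duplicated rater pool -> reliability near 1
  hi <- rating_reliability(make_tab(10, 0.05, 1), n_splits = 30, seed = 5)
  expect_gt(hi$summary$mean, 0.95)
  # pure-noise ratings -> reliability near 0
  set.seed(9)
  noise_tab <- do.call(rbind, lapply(1:10, function(r) {
    data.frame(rater = sprintf("r%02d", r), item = items, feature = "f",
               rating = sample(1:5, 20, TRUE), catch_pass = TRUE)
  }))
  null <- rating_reliability(noise_tab, n_splits = 100, seed = 6)
  expect_lt(abs(null$summary$mean), 0.15)
  # reliability increases with rater count at fixed noise
  lo_n <- rating_reliability(make_tab(4, 1.5, 2), n_splits = 50, seed = 7)
  hi_n <- rating_reliability(make_tab(20, 1.5, 3), n_splits = 50, seed = 8)
  expect_gt(hi_n$summary$mean, lo_n$summary$mean)
})

test_that("frame statistics handle gray and pure-color stacks", {
  gray <- matrix(0.5, 8, 8)
  g <- mean_frame_stats(list(gray, gray))
  expect_equal(unname(g["luminance"]), 0.5)
  expect_equal(unname(g["saturation"]), 0)
  red <- array(0, c(4, 4, 3)); red[, , 1] <- 1
  r <- mean_frame_stats(list(red))
  expect_equal(unname(r["hue"]), 0)
  expect_equal(unname(r["saturation"]), 1)
  expect_equal(unname(r["luminance"]), 1 / 3)
  # two-frame stack equals hand-averaged per-frame stats
  f1 <- array(runif(48), c(4, 4, 3)); f2 <- array(runif(48), c(4, 4, 3))
  both <- mean_frame_stats(list(f1, f2))
  s1 <- mean_frame_stats(list(f1)); s2 <- mean_frame_stats(list(f2))
  expect_equal(unname(both["luminance"]),
               unname((s1["luminance"] + s2["luminance"]) / 2))
  expect_error(mean_frame_stats(list()), "at least one")
  expect_error(mean_frame_stats(list(matrix(2, 2, 2))), "\\[0, 1\\]")
})

test_that("optic flow recovers known translations and respects smoothness", {
  # smooth Gaussian blob shifted right by 1 px
  g <- function(cx, cy) {
    outer(1:40, 1:40, function(y, x) exp(-((x - cx)^2 + (y - cy)^2) / 18))
  }
  a <- g(20, 20); b <- g(21, 20)
  expect_equal(horn_schunck_flow(a, a)$mean_magnitude, 0)
  fl <- horn_schunck_flow(a, b, alpha = 0.25, n_iter = 800)
  supp <- a > 0.1
  mag_in <- mean(sqrt(fl$u^2 + fl$v^2)[supp])
  expect_gt(mag_in, 0.8)
  expect_lt(mag_in, 1.2)
  # magnitude scales linearly with sub-pixel to ~2 px displacement
  shifts <- c(0.25, 0.5, 1, 1.5, 2)
  mags <- vapply(shifts, function(s) {
    fb <- g(20 + s, 20)
    f <- horn_schunck_flow(a, fb, alpha = 0.25, n_iter = 800)
    mean(sqrt(f$u^2 + f$v^2)[supp])
  }, 1.0)
  expect_gt(summary(lm(mags ~ shifts))$r.squared, 0.95)
  # very large alpha -> near-constant flow field
  fs <- horn_schunck_flow(a, b, alpha = 100, n_iter = 200)
  expect_lt(var(as.vector(fs$u)), 1e-4 * max(mean(fs$u)^2, 1e-9) + 1e-8)
  expect_error(horn_schunck_flow(a, b[1:20, ]), "shapes")
})

test_that("the feature RDM battery carries tags and correct encodings", {
  items <- sprintf("i%02d", 1:12)
  fs <- feature_set(items)
  fs <- add_feature(fs, "sociality", rnorm(12), group = "social-affective",
                    provenance = "rating")
  fs <- add_feature(fs, "category", rep(c("a", "b", "c"), each = 4),
                    group = "action", type = "categorical")
  fs <- add_feature(fs, "n_agents", c(0, 1, 3, rep(1, 9)),
                    group = "social-affective")
  fs <- add_feature(fs, "effectors", matrix(rbinom(60, 1, 0.5), 12, 5),
                    group = "action")
  fs <- attach_embeddings(fs, list(emb = matrix(rnorm(48), 12, 4)))
  rdms <- build_feature_rdms(fs)
  expect_length(rdms, 5)
  expect_equal(attr(rdms$sociality, "group"), "social-affective")
  expect_equal(attr(rdms$emb, "provenance"), "embedding")
  expect_equal(rdms$category$metric_tag, "categorical")
  # ordinal agents encoding: [0,1,3] -> distances [1,3,2]
  expect_equal(rdms$n_agents$values[condensed_index(c(1, 1, 2), c(2, 3, 3), 12)],
               c(1, 3, 2))
  # effectors distance: vectors differing in 2 bits are sqrt(2) apart
  fs2 <- feature_set(items[1:2])
  fs2 <- add_feature(fs2, "effectors", rbind(c(1, 1, 0, 0, 0), c(1, 0, 0, 0, 1)),
                     group = "action")
  expect_equal(build_feature_rdms(fs2)$effectors$values, sqrt(2))
  expect_error(add_feature(fs, "bad", rnorm(12), group = "nope"), "group")
  expect_error(attach_embeddings(fs, list(e = matrix(0, 5, 2))), "rows")
})

test_that("embedding RDMs are isometry invariant and match brute force", {
  set.seed(13)
  items <- sprintf("i%02d", 1:10)
  emb <- matrix(rnorm(40), 10, 4)
  th <- 0.7
  rot <- diag(4); rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  fs <- attach_embeddings(feature_set(items), list(a = emb, b = emb %*% rot))
  rdms <- build_feature_rdms(fs)
  expect_equal(rdms$a$values, rdms$b$values, tolerance = 1e-12)
  expect_equal(rdms$a$values, as.vector(dist(emb)))
  # one-hot identity embedding: all pairs equally distant
  onehot <- diag(10)
  r1 <- build_feature_rdms(attach_embeddings(feature_set(items),
                                             list(i = onehot)))$i
  expect_true(all(abs(r1$values - sqrt(2)) < 1e-12))
})

test_that("feature intercorrelations recover planted correlation ordering", {
  m <- feature_intercorrelations(list(a = random_rdm(20), b = random_rdm(20)))
  expect_equal(diag(m), c(a = 1, b = 1))
  expect_equal(m[1, 2], m[2, 1])
  # independent random RDMs at 100 items correlate near zero
  set.seed(15)
  r100 <- list(x = random_rdm(100), y = random_rdm(100))
  expect_lt(abs(feature_intercorrelations(r100)[1, 2]), 0.05)
  # planted correlation levels are recovered in rank order
  set.seed(16)
  n <- 80
  base <- rnorm(n)
  levels <- c(0, 0.25, 0.5, 0.75, 0.95)
  feats <- lapply(levels, function(rho) {
    euclidean_rdm(matrix(rho * base + sqrt(1 - rho^2) * rnorm(n), ncol = 1))
  })
  names(feats) <- paste0("f", seq_along(levels))
  ref <- euclidean_rdm(matrix(base, ncol = 1))
  taus <- vapply(feats, function(f) {
    feature_intercorrelations(list(ref = ref, f = f))[1, 2]
  }, 1.0)
  expect_equal(order(taus), seq_along(levels))
  expect_error(feature_intercorrelations(list(random_rdm(5), random_rdm(6))),
               "n_items")
})
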