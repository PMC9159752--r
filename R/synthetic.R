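#' Ground-truth configuration for the synthetic stimulus set
#'
#' Describes the generative world the synthetic data emulate: a stimulus set
#' of activity videos (18 categories with a fixed number of exemplars each,
#' plus agent-free control items), continuous latent features per predictor
#' group, rater noise, arrangement placement noise, and per-feature response
#' latencies for the synthetic recordings.
#'
#' The default battery has two visual features (environment, a scene
#' embedding proxy), two rated action features (transitivity, activity) plus
#' categorical action category and binary effector vectors, and four
#' social-affective features (sociality, valence, arousal, number of agents).
#'
#' @param n_categories number of activity categories (default 18).
#' @param per_category exemplars per category (default 8; may be a vector of
#'   per-category sizes).
#' @param n_control agent-free control items (default 8).
#' @param latent_cor correlation between the continuous latent features
#'   (scalar, compound-symmetric; default 0).
#' @param rating_sd SD of rater noise on the latent scale (default 1).
#' @param n_raters raters per rated feature (default 18, matching the
#'   study-scale rating coverage).
#' @param n_bad_raters planted repetitive raters per feature (use <= 2 unique
#'   values; excluded by the rater-exclusion rule).
#' @param n_catchfail_raters planted raters who fail catch trials.
#' @param placement_noise arrangement coordinate jitter SD (disk units).
#' @param weights named nonnegative weights of the feature RDMs in the
#'   ground-truth behavioral RDM (defaults to equal weights over the three
#'   rated group latents).
#' @param channel_noise_cor inter-channel noise correlation of synthetic
#'   recordings (default 0.3, so noise normalization is exercised).
#' @param latencies data.frame with columns `feature`, `onset_ms`,
#'   `duration_ms`, `amplitude` mapping features to response windows.
#' @return list of class `gt_config`.
#' @export
gt_config <- function(n_categories = 18L, per_category = 8L, n_control = 8L,
                      latent_cor = 0, rating_sd = 1, n_raters = 18L,
                      n_bad_raters = 0L, n_catchfail_raters = 0L,
                      placement_noise = 0.05,
                      weights = c(gist = 1, transitivity = 1, sociality = 1),
                      channel_noise_cor = 0.3,
                      latencies = NULL) {
  sizes <- if (length(per_category) == 1L) rep(per_category, n_categories)
           else per_category
  stopifnot(length(sizes) == n_categories, all(sizes >= 1L),
            latent_cor >= -0.5, latent_cor < 1, all(weights >= 0))
  structure(list(n_categories = as.integer(n_categories),
                 category_sizes = as.integer(sizes),
                 n_control = as.integer(n_control),
                 n_items = sum(sizes) + as.integer(n_control),
                 latent_cor = latent_cor, rating_sd = rating_sd,
                 n_raters = as.integer(n_raters),
                 n_bad_raters = as.integer(n_bad_raters),
                 n_catchfail_raters = as.integer(n_catchfail_raters),
                 placement_noise = placement_noise,
                 weights = weights,
                 channel_noise_cor = channel_noise_cor,
                 latencies = latencies),
            class = "gt_config")
}

#' Configuration for the 65-item full-arrangement stimulus set
#'
#' The smaller set keeps all 18 categories with three or four exemplars each
#' (summing to 65) and no control items.
#'
#' @param ... overrides passed to [gt_config()].
#' @return a `gt_config` with 65 items.
#' @export
gt_config_65 <- function(...) {
  sizes <- rep(3L, 18L); sizes[seq_len(65L - 54L)] <- 4L # 11 x 4 + 7 x 3 = 65
  gt_config(n_categories = 18L, per_category = sizes, n_control = 0L, ...)
}

rated_features <- c("transitivity", "activity", "sociality", "valence", "arousal")
continuous_latents <- c("gist", "environment", "transitivity", "activity",
                        "sociality", "valence", "arousal", "agents")

feature_group_of <- c(gist = "visual", environment = "visual",
                      transitivity = "action", activity = "action",
                      category = "action", effectors = "action",
                      sociality = "social-affective",
                      valence = "social-affective",
                      arousal = "social-affective",
                      n_agents = "social-affective")

#' Generate a synthetic stimulus set with known ground truth
#'
#' Draws item-level continuous latent features (with configurable
#' cross-feature correlation), then derives everything the pipeline
#' ingests: per-rater 1-5 rating tables with rater noise (plus plantable
#' repetitive or catch-failing raters), and experimenter-style annotations
#' (activity category, environment, binary effector 5-vectors, number of
#' agents on the 0-3 scale, control items agent-free).
#'
#' @param config a [gt_config()].
#' @param seed RNG seed (mandatory; generation is bit-reproducible).
#' @return list of class `gt_world`: `items`, `categories`, `latents`
#'   (items x latent matrix), `ratings` (long `rating_table`), `annotations`
#'   (data.frame), `config`.
#' @export
gen_feature_set <- function(config, seed) {
  stopifnot(inherits(config, "gt_config"))
  set.seed(seed)
  n <- config$n_items
  items <- sprintf("item%03d", seq_len(n))
  categories <- c(rep(sprintf("cat%02d", seq_len(config$n_categories)),
                      config$category_sizes),
                  rep("control", config$n_control))
  # correlated continuous latents via compound-symmetric Gaussian
  p <- length(continuous_latents)
  R <- matrix(config$latent_cor, p, p); diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e)
    stop("infeasible latent correlation matrix"))
  latents <- matrix(rnorm(n * p), n, p) %*% ch
  colnames(latents) <- continuous_latents
  # annotations
  proto <- matrix(rbinom(5L * (config$n_categories + 1L), 1L, 0.5),
                  config$n_categories + 1L, 5L) # effector prototype per category
  cat_idx <- match(categories, c(sprintf("cat%02d", seq_len(config$n_categories)),
                                 "control"))
  eff <- proto[cat_idx, , drop = FALSE]
  flip <- matrix(runif(length(eff)) < 0.1, nrow(eff))
  eff <- abs(eff - flip)
  colnames(eff) <- c("face_head", "hands", "arms", "legs", "torso")
  n_agents <- pmin(pmax(round(1.8 + latents[, "agents"]), 0L), 3L)
  n_agents[categories == "control"] <- 0L
  annotations <- data.frame(
    item = items, category = categories,
    environment = ifelse(latents[, "environment"] > 0, "outdoors", "indoors"),
    watermark = rbinom(n, 1L, 0.2),
    n_agents = as.integer(n_agents))
  annotations <- cbind(annotations, eff)
  # rating tables: latent + rater noise, discretized to 1..5
  tables <- list()
  for (f in rated_features) {
    nr <- config$n_raters
    for (r in seq_len(nr)) {
      noisy <- latents[, f] + rnorm(n, sd = config$rating_sd)
      rating <- as.integer(cut(noisy, c(-Inf, -1.2, -0.4, 0.4, 1.2, Inf)))
      tables[[length(tables) + 1L]] <- data.frame(
        rater = sprintf("%s_r%02d", f, r), item = items, feature = f,
        rating = rating, catch_pass = TRUE)
    }
    if (config$n_bad_raters > 0L) for (r in seq_len(config$n_bad_raters)) {
      tables[[length(tables) + 1L]] <- data.frame(
        rater = sprintf("%s_bad%02d", f, r), item = items, feature = f,
        rating = sample(3:4, n, replace = TRUE), catch_pass = TRUE)
    }
    if (config$n_catchfail_raters > 0L) for (r in seq_len(config$n_catchfail_raters)) {
      noisy <- latents[, f] + rnorm(n, sd = config$rating_sd)
      tables[[length(tables) + 1L]] <- data.frame(
        rater = sprintf("%s_cf%02d", f, r), item = items, feature = f,
        rating = as.integer(cut(noisy, c(-Inf, -1.2, -0.4, 0.4, 1.2, Inf))),
        catch_pass = FALSE)
    }
  }
  ratings <- rating_table(do.call(rbind, tables))
  structure(list(items = items, categories = categories, latents = latents,
                 ratings = ratings, annotations = annotations,
                 config = config),
            class = "gt_world")
}

#' Assemble the analysis-side feature set of a synthetic world
#'
#' Runs the same path real data would take: rater exclusion, rating
#' aggregation, then registration of rated features, annotations, and the
#' continuous embedding proxy into a [feature_set()].
#'
#' @param world a `gt_world` from [gen_feature_set()].
#' @param zscore z-score ratings per rater before averaging?
#' @return a `feature_set` covering the full default battery.
#' @export
assemble_features <- function(world, zscore = TRUE) {
  stopifnot(inherits(world, "gt_world"))
  kept <- exclude_raters(world$ratings)
  agg <- aggregate_ratings(kept, zscore = zscore)
  fs <- feature_set(world$items)
  for (f in colnames(agg$means)) {
    fs <- add_feature(fs, f, agg$means[world$items, f],
                      group = feature_group_of[[f]], provenance = "rating")
  }
  an <- world$annotations
  fs <- add_feature(fs, "environment", as.numeric(an$environment == "outdoors"),
                    group = "visual")
  fs <- add_feature(fs, "category", an$category, group = "action",
                    type = "categorical")
  fs <- add_feature(fs, "effectors",
                    as.matrix(an[, c("face_head", "hands", "arms", "legs", "torso")]),
                    group = "action")
  fs <- add_feature(fs, "n_agents", as.numeric(an$n_agents),
                    group = "social-affective")
  fs <- attach_embeddings(fs, list(gist = world$latents[, "gist", drop = FALSE]))
  fs
}

#' Weighted combination of RDMs
#'
#' Each RDM's condensed vector is normalized to unit root-mean-square, then
#' summed with nonnegative weights; a nonnegative combination of metrics is
#' itself a metric, so the result can serve as a ground-truth dissimilarity.
#'
#' @param rdms named list of `rdm`s over the same items.
#' @param weights named nonnegative weights (names must match `rdms`).
#' @return an `rdm`.
#' @export
combine_rdms <- function(rdms, weights) {
  stopifnot(all(names(weights) %in% names(rdms)), all(weights >= 0),
            any(weights > 0))
  n <- rdms[[1L]]$n_items
  vals <- 0
  for (nm in names(weights)) {
    v <- rdms[[nm]]$values
    rms <- sqrt(mean(v^2))
    if (rms > 0) v <- v / rms
    vals <- vals + weights[[nm]] * v
  }
  make_rdm(vals, n, metric_tag = "other")
}

#' Ground-truth behavioral RDM of a synthetic world
#'
#' @param world a `gt_world`.
#' @return an `rdm`: the weighted combination (per the config's `weights`) of
#'   the Euclidean RDMs of the noiseless latent features.
#' @export
truth_rdm <- function(world) {
  stopifnot(inherits(world, "gt_world"))
  w <- world$config$weights
  rdms <- lapply(names(w), function(f)
    euclidean_rdm(world$latents[, f, drop = FALSE]))
  names(rdms) <- names(w)
  combine_rdms(rdms, w)
}

#' Simulate a cohort of multiple-arrangement subjects
#'
#' Each synthetic subject runs a full adaptive session against the world's
#' ground-truth RDM. Two designs: `"full_65"` (every subject arranges all
#' items, trial cap 8) and `"subsets_30_of_152"` (each subject arranges a
#' 30-item subset sampled in a balanced manner across subjects, trial cap 7).
#'
#' @param world a `gt_world` (or any list with a `truth` RDM via
#'   `truth_rdm`).
#' @param n_subjects number of simulated subjects.
#' @param design sampling design.
#' @param placement_noise overrides the config's placement noise if given.
#' @param trial_budget per-session trial cap, standing in for the task's
#'   time-out; defaults mirror the observed session lengths of each design
#'   (450 trials for the full design, 160 for the subset design).
#' @param seed RNG seed (mandatory).
#' @return list of `arrangement_session` objects.
#' @export
gen_behavior_subjects <- function(world, n_subjects,
                                  design = c("full_65", "subsets_30_of_152"),
                                  placement_noise = NULL,
                                  trial_budget = NULL, seed) {
  design <- match.arg(design)
  if (is.null(trial_budget))
    trial_budget <- if (design == "full_65") 1200L else 160L
  truth <- truth_rdm(world)
  sigma <- placement_noise %||% world$config$placement_noise
  set.seed(seed)
  n <- truth$n_items
  usage <- rep(0L, n)
  pair_cover <- matrix(0L, n, n) # balanced sampling tracks pair coverage
  sessions <- vector("list", n_subjects)
  seeds <- sample.int(.Machine$integer.max, n_subjects)
  for (s in seq_len(n_subjects)) {
    if (design == "full_65") {
      ids <- seq_len(n); cap <- 8L
    } else {
      if (n < 30L) stop("subset design needs at least 30 items")
      # balanced sampling: greedily grow the subset with the item whose
      # pairs with the current subset are least covered so far (random
      # tie-break); keeps both item and pair exposure balanced across the
      # cohort so the pooled average covers every pair.
      first <- which.min(usage + runif(n))
      ids <- first
      while (length(ids) < 30L) {
        cand <- setdiff(seq_len(n), ids)
        load <- 1000 * rowSums(pair_cover[cand, ids, drop = FALSE] > 0) +
          rowSums(pair_cover[cand, ids, drop = FALSE]) +
          0.01 * usage[cand] + runif(length(cand))
        ids <- c(ids, cand[which.min(load)])
      }
      ids <- sort(ids)
      usage[ids] <- usage[ids] + 1L
      pair_cover[ids, ids] <- pair_cover[ids, ids] + 1L
      cap <- 7L
    }
    sessions[[s]] <- simulate_session(truth, item_ids = ids,
                                      placement_noise = sigma,
                                      criterion = 0.5, max_trial_size = cap,
                                      trial_budget = trial_budget,
                                      seed = seeds[s])
  }
  sessions
}

#' Default latency specification for synthetic recordings
#'
#' One latency per predictor group, staggering visual, action, and
#' social-affective information at 70, 250, and 420 ms after onset.
#'
#' @param amplitude common pattern amplitude (signal units).
#' @param duration_ms common response duration.
#' @return a data.frame usable as `gt_config(latencies = ...)`.
#' @export
default_latencies <- function(amplitude = 1, duration_ms = 200) {
  data.frame(feature = c("gist", "transitivity", "sociality"),
             group = c("visual", "action", "social-affective"),
             onset_ms = c(70, 250, 420),
             duration_ms = duration_ms,
             amplitude = amplitude)
}

#' Generate synthetic epoched recordings with staggered feature structure
#'
#' Each latency-spec feature's RDM is embedded into a low-dimensional
#' condition geometry (classical MDS); per subject, each embedding dimension
#' projects onto a random orthonormal channel pattern (idiosyncratic
#' topographies), active as a boxcar over the feature's latency window and
#' scaled by its amplitude. Spatially correlated Gaussian noise (compound
#' symmetric across channels, white over time and trials) is added, and each
#' condition is shown `n_trials` times.
#'
#' @param world a `gt_world` whose config carries a `latencies` data.frame
#'   ([default_latencies()] if the config has none).
#' @param n_subjects number of subjects.
#' @param n_channels channels per subject (default 32).
#' @param fs sampling rate in Hz (default 500).
#' @param window epoch window in seconds (default `c(-0.2, 1)`).
#' @param n_trials presentations per condition (default 10).
#' @param noise_sd channel noise SD (default 1).
#' @param embed_dim embedding dimensionality per feature (default 5).
#' @param seed RNG seed (mandatory).
#' @return list of `epoch_set` objects, one per subject; conditions are item
#'   indices.
#' @export
gen_epochs <- function(world, n_subjects, n_channels = 32L, fs = 500,
                       window = c(-0.2, 1), n_trials = 10L, noise_sd = 1,
                       embed_dim = 5L, seed) {
  stopifnot(inherits(world, "gt_world"))
  lat <- world$config$latencies %||% default_latencies()
  set.seed(seed)
  n <- world$config$n_items
  nt <- round((window[2L] - window[1L]) * fs) + 1L
  times <- seq(window[1L], by = 1 / fs, length.out = nt)
  if (any(lat$onset_ms / 1000 < window[1L]) ||
      any((lat$onset_ms + lat$duration_ms) / 1000 > window[2L]))
    stop("latency specification outside the epoch window")
  # per-feature condition geometry (shared across subjects)
  geoms <- lapply(seq_len(nrow(lat)), function(q) {
    r <- euclidean_rdm(world$latents[, lat$feature[q], drop = FALSE])
    d <- matrix(0, n, n)
    d[lower.tri(d)] <- r$values; d <- d + t(d)
    k <- min(embed_dim, n - 1L)
    y <- suppressWarnings(cmdscale(as.dist(d), k = k))
    y <- as.matrix(y)
    sweep(y, 2L, sqrt(colSums(y^2) / n + 1e-12), `/`) # unit-RMS dims
  })
  rho <- world$config$channel_noise_cor
  Sigma <- noise_sd^2 * ((1 - rho) * diag(n_channels) +
                           rho * matrix(1, n_channels, n_channels))
  chS <- chol(Sigma)
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    # idiosyncratic orthonormal channel patterns per feature
    signal <- array(0, c(n, n_channels, nt))
    for (q in seq_len(nrow(lat))) {
      k <- ncol(geoms[[q]])
      P <- qr.Q(qr(matrix(rnorm(n_channels * k), n_channels, k)))
      on <- lat$onset_ms[q] / 1000; off <- on + lat$duration_ms[q] / 1000
      env <- as.numeric(times >= on & times < off)
      cond_pat <- lat$amplitude[q] * geoms[[q]] %*% t(P) # n x channels
      sel <- which(env > 0)
      for (t in sel) signal[, , t] <- signal[, , t] + cond_pat
    }
    n_tr <- n * n_trials
    labels <- rep(seq_len(n), each = n_trials)
    data <- array(0, c(n_tr, n_channels, nt))
    for (t in seq_len(nt)) {
      noise <- matrix(rnorm(n_tr * n_channels), n_tr, n_channels) %*% chS
      data[, , t] <- signal[labels, , t] + noise
    }
    if (!all(is.finite(data))) stop("non-finite synthetic recordings")
    subjects[[s]] <- epoch_set(data, labels, fs, window)
  }
  subjects
}

#' Generate a one-back session design
#'
#' The experimental videos are shown in pseudorandom order in each block
#' with no immediate repetition of the same video (including across block
#' boundaries). Catch pairs — two consecutive presentations of paired videos
#' depicting the same action — are inserted at random positions, each pair
#' repeated `catch_reps` times with half of the repetitions in each order
#' (V1-V2 / V2-V1). Defaults yield 152 x 10 + 25 x 4 x 2 = 1720 trials.
#'
#' @param n_videos experimental videos (default 152).
#' @param n_blocks blocks (default 10).
#' @param n_catch_pairs catch video pairs (default 25).
#' @param catch_reps repetitions per catch pair (default 4; must be even so
#'   orders balance).
#' @param seed RNG seed (mandatory).
#' @param max_tries resampling attempts before giving up on the
#'   no-repetition constraint.
#' @return a data.frame of class `session_design` with columns `trial`,
#'   `video`, `is_catch`; attribute `"n_experimental"`/`"n_catch"`.
#' @export
gen_session_design <- function(n_videos = 152L, n_blocks = 10L,
                               n_catch_pairs = 25L, catch_reps = 4L, seed,
                               max_tries = 100L) {
  stopifnot(n_videos > 1L, n_blocks >= 1L, n_catch_pairs >= 0L,
            catch_reps %% 2L == 0L)
  set.seed(seed)
  vids <- sprintf("v%03d", seq_len(n_videos))
  for (attempt in seq_len(max_tries)) {
    blocks <- list()
    ok <- TRUE
    last <- ""
    for (b in seq_len(n_blocks)) {
      good <- FALSE
      for (k in seq_len(max_tries)) {
        perm <- sample(vids)
        if (perm[1L] != last) { good <- TRUE; break }
      }
      if (!good) { ok <- FALSE; break }
      blocks[[b]] <- perm
      last <- perm[n_videos]
    }
    if (!ok) next
    seq_exp <- unlist(blocks)
    # catch insertions: each is 2 consecutive trials of a catch pair
    ins <- list()
    for (p in seq_len(n_catch_pairs)) {
      a <- sprintf("catch%02da", p); b2 <- sprintf("catch%02db", p)
      orders <- c(rep(list(c(a, b2)), catch_reps / 2L),
                  rep(list(c(b2, a)), catch_reps / 2L))
      ins <- c(ins, orders)
    }
    if (length(ins)) {
      pos <- sort(sample.int(length(seq_exp) + 1L, length(ins),
                             replace = TRUE)) - 1L
      full <- character(0); cursor <- 0L
      ord <- sample.int(length(ins)) # shuffle which insertion goes where
      for (q in seq_along(pos)) {
        full <- c(full, seq_exp[seq_len(pos[q] - cursor) + cursor],
                  ins[[ord[q]]])
        cursor <- pos[q]
      }
      full <- c(full, seq_exp[seq((cursor + 1L), length(seq_exp))])
    } else full <- seq_exp
    if (!any(full[-1L] == full[-length(full)])) {
      df <- data.frame(trial = seq_along(full), video = full,
                       is_catch = startsWith(full, "catch"))
      attr(df, "n_experimental") <- length(seq_exp)
      attr(df, "n_catch") <- length(full) - length(seq_exp)
      class(df) <- c("session_design", "data.frame")
      return(df)
    }
  }
  stop("could not satisfy the no-repetition constraint")
}
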