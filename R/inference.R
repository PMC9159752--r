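#' Inference configuration
#'
#' Bundles the nonparametric-inference settings used throughout: one-tailed
#' sign permutation testing with 5000 iterations, alpha 0.05, cluster-forming
#' alpha 0.05, and 1000 bootstrap resamples with 90% confidence intervals.
#'
#' @param n_perm number of sign permutations (>= 1000).
#' @param alpha significance level.
#' @param cluster_alpha cluster-forming threshold on per-window p-values.
#' @param n_boot bootstrap resamples for onset CIs.
#' @param ci central confidence-interval mass for onsets.
#' @return a list of class `inference_config`.
#' @export
inference_config <- function(n_perm = 5000L, alpha = 0.05,
                             cluster_alpha = 0.05, n_boot = 1000L,
                             ci = 0.90) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 1000L, cluster_alpha > 0,
            cluster_alpha < 1, n_boot >= 1L, ci > 0, ci < 1)
  structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                 cluster_alpha = cluster_alpha, n_boot = as.integer(n_boot),
                 ci = ci),
            class = "inference_config")
}

#' Correlate subject data RDMs with a model RDM
#'
#' Computes the Kendall tau-a between each subject's data RDM and a model
#' RDM. Partial-coverage subjects are handled by restricting each correlation
#' to the pairs that subject covered (evidence > 0 and non-missing values).
#' Time-resolved inputs yield one tau-a per subject and time bin.
#'
#' @param data_rdms list over subjects of `rdm` or `time_rdm` objects.
#' @param model_rdm an `rdm` with matching `n_items`.
#' @return numeric vector (one value per subject) or matrix
#'   (subjects x time, attribute `"times"`). Subjects with fewer than 3
#'   covered pairs get `NA` with a warning.
#' @export
rsa_correlate <- function(data_rdms, model_rdm) {
  stopifnot(inherits(model_rdm, "rdm"), length(data_rdms) >= 1L)
  if (inherits(data_rdms[[1L]], "time_rdm")) {
    nt <- ncol(data_rdms[[1L]]$values)
    out <- matrix(NA_real_, length(data_rdms), nt)
    for (s in seq_along(data_rdms)) {
      tr <- data_rdms[[s]]
      if (tr$n_items != model_rdm$n_items) stop("n_items mismatch")
      for (t in seq_len(nt))
        out[s, t] <- tau_a(tr$values[, t], model_rdm$values)
    }
    attr(out, "times") <- data_rdms[[1L]]$times
    out
  } else {
    vapply(seq_along(data_rdms), function(s) {
      r <- data_rdms[[s]]
      if (r$n_items != model_rdm$n_items) stop("n_items mismatch")
      mask <- r$evidence > 0 & !is.na(r$values)
      if (sum(mask) < 3L) {
        warning(sprintf("subject %d covers < 3 pairs; tau set to NA", s))
        return(NA_real_)
      }
      tau_a(r$values[mask], model_rdm$values[mask])
    }, 1.0)
  }
}

# Permutation-mean matrix (n_perm x K) for subject scores S (n x K), plus the
# sign matrix used. Enumerates all 2^n flips when feasible and requested.
perm_means <- function(S, n_perm) {
  n <- nrow(S)
  if (2^n <= n_perm) {
    message(sprintf("2^%d <= n_perm: enumerating all %d sign patterns", n, 2^n))
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    list(means = (signs %*% S) / n, exact = TRUE)
  } else {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
    list(means = (signs %*% S) / n, exact = FALSE)
  }
}

# One-sided (right) p of obs against null draws; +1 correction unless exact.
mc_p <- function(obs, null, exact) {
  if (exact) colSums(outer(null, obs, `>=`)) / length(null)
  else (1 + colSums(outer(null, obs, `>=`))) / (1 + length(null))
}

# Contiguous runs of TRUE; returns list of index vectors.
runs_of <- function(mask) {
  if (!any(mask)) return(list())
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(function(s, e) s:e, starts[r$values], ends[r$values])
}

#' One-tailed sign permutation test of group-level scores
#'
#' Tests whether the group mean of subject-level statistics (e.g., tau-a
#' values) exceeds zero, building the null by randomly flipping the sign of
#' each subject's values. Three multiple-comparison regimes:
#' `"none"` (per-column p), `"omnibus_max"` (compare each column's mean to
#' the permutation distribution of the maximum mean across columns), and
#' `"cluster_sum"` (columns are consecutive time windows; clusters of windows
#' with permutation p below `cluster_alpha` are scored by the sum of the
#' group-mean statistic and compared to the permutation distribution of the
#' maximum cluster sum).
#'
#' @param scores subjects x columns matrix (columns are models or time
#'   windows) or a vector (one column).
#' @param config an [inference_config()].
#' @param correction `"none"`, `"omnibus_max"`, or `"cluster_sum"`.
#' @return list with `observed` (column means), `p_uncorrected`,
#'   `p_corrected`, `significant` (logical, at `config$alpha`), and for the
#'   cluster regime `clusters` (data.frame: start, end, mass, p).
#' @export
sign_permutation_test <- function(scores, config = inference_config(),
                                  correction = c("none", "omnibus_max",
                                                 "cluster_sum")) {
  correction <- match.arg(correction)
  S <- as.matrix(scores)
  if (anyNA(S)) {
    keep <- complete.cases(S)
    S <- S[keep, , drop = FALSE]
  }
  if (nrow(S) < 5L) stop("need at least 5 subjects")
  obs <- colMeans(S)
  pm <- perm_means(S, config$n_perm)
  K <- ncol(S)
  p_unc <- vapply(seq_len(K), function(k) {
    mc_p(obs[k], pm$means[, k], pm$exact)
  }, 1.0)
  out <- list(observed = obs, p_uncorrected = p_unc, correction = correction)
  if (correction == "none") {
    out$p_corrected <- p_unc
  } else if (correction == "omnibus_max") {
    maxnull <- apply(pm$means, 1L, max)
    out$p_corrected <- vapply(obs, function(o) mc_p(o, maxnull, pm$exact), 1.0)
  } else {
    # per-permutation per-window p by rank within the permutation distribution
    R <- nrow(pm$means)
    p_perm <- apply(pm$means, 2L, function(v) (R - rank(v, ties.method = "min") + 1) / R)
    p_perm <- matrix(p_perm, nrow = R)
    maxmass <- vapply(seq_len(R), function(r) {
      cl <- runs_of(p_perm[r, ] < config$cluster_alpha)
      if (length(cl) == 0L) return(0)
      max(vapply(cl, function(ix) sum(pm$means[r, ix]), 1.0))
    }, 1.0)
    obs_cl <- runs_of(p_unc < config$cluster_alpha)
    cl_df <- data.frame(start = integer(0), end = integer(0),
                        mass = numeric(0), p = numeric(0))
    p_corr <- rep(1, K)
    for (ix in obs_cl) {
      mass <- sum(obs[ix])
      pcl <- mc_p(mass, maxmass, pm$exact)
      cl_df <- rbind(cl_df, data.frame(start = ix[1L], end = ix[length(ix)],
                                       mass = mass, p = pcl))
      p_corr[ix] <- pcl
    }
    out$clusters <- cl_df
    out$p_corrected <- p_corr
  }
  out$significant <- out$p_corrected < config$alpha
  out
}

#' Noise ceiling for RDM model comparisons
#'
#' Bounds the best group-average correlation any model could achieve given
#' between-subject variability: each subject's RDM is correlated (tau-a) with
#' the grand-average RDM including that subject (upper bound) and with the
#' average excluding them (lower bound). Partial-coverage subjects are
#' restricted to their covered pairs.
#'
#' @param subject_rdms list of >= 3 `rdm` objects.
#' @return list with `lower`, `upper` (per-subject vectors) and
#'   `group_lower`, `group_upper` (means over subjects).
#' @export
noise_ceiling <- function(subject_rdms) {
  stopifnot(length(subject_rdms) >= 3L)
  grand <- average_rdms(subject_rdms, allow_missing = TRUE)
  n_sub <- length(subject_rdms)
  lower <- upper <- rep(NA_real_, n_sub)
  for (s in seq_len(n_sub)) {
    rs <- subject_rdms[[s]]
    loo <- average_rdms(subject_rdms[-s], allow_missing = TRUE)
    mu <- rs$evidence > 0 & grand$evidence > 0 & !is.na(grand$values)
    ml <- rs$evidence > 0 & loo$evidence > 0 & !is.na(loo$values)
    if (sum(mu) >= 3L) upper[s] <- tau_a(rs$values[mu], grand$values[mu])
    if (sum(ml) >= 3L) lower[s] <- tau_a(rs$values[ml], loo$values[ml])
  }
  list(lower = lower, upper = upper,
       group_lower = mean(lower, na.rm = TRUE),
       group_upper = mean(upper, na.rm = TRUE))
}

#' Bootstrap distribution of effect onsets
#'
#' Resamples subjects with replacement and, per replicate, reruns the
#' cluster-corrected sign permutation test on the resampled score time
#' courses; the onset is the first window of the earliest significant
#' cluster. Replicates with no significant cluster are recorded as missing
#' and excluded from the confidence interval (their fraction is reported; the
#' CI is flagged unreliable when more than half are missing).
#'
#' @param scores subjects x windows matrix of statistics.
#' @param times window time stamps (s); onsets are reported on this scale.
#' @param config an [inference_config()]; `n_boot` and `ci` control the
#'   bootstrap, `n_perm`/`cluster_alpha`/`alpha` the per-replicate test.
#' @param seed RNG seed (mandatory).
#' @return list with `onsets` (n_boot vector, `NA` = no effect), `mean`,
#'   `sd`, `ci` (central interval), `prop_missing`, `unreliable`.
#' @export
bootstrap_onsets <- function(scores, times = seq_len(ncol(scores)),
                             config = inference_config(), seed) {
  S <- as.matrix(scores)
  stopifnot(ncol(S) == length(times))
  set.seed(seed)
  n <- nrow(S)
  onsets <- rep(NA_real_, config$n_boot)
  for (b in seq_len(config$n_boot)) {
    Sb <- S[sample.int(n, n, replace = TRUE), , drop = FALSE]
    res <- suppressMessages(
      sign_permutation_test(Sb, config, correction = "cluster_sum"))
    if (nrow(res$clusters) > 0L && any(res$clusters$p < config$alpha)) {
      onsets[b] <- times[min(res$clusters$start[res$clusters$p < config$alpha])]
    }
  }
  ok <- !is.na(onsets)
  prop_missing <- mean(!ok)
  list(onsets = onsets,
       mean = if (any(ok)) mean(onsets[ok]) else NA_real_,
       sd = if (sum(ok) > 1L) sd(onsets[ok]) else NA_real_,
       ci = if (any(ok)) unname(quantile(onsets[ok],
                                         c((1 - config$ci) / 2,
                                           1 - (1 - config$ci) / 2)))
            else c(NA_real_, NA_real_),
       prop_missing = prop_missing,
       unreliable = prop_missing > 0.5)
}

#' Two-sided paired comparison (Wilcoxon signed-rank)
#'
#' @param a,b paired numeric vectors of equal length >= 6.
#' @return two-sided p-value. Exact for n <= 25 when no zero differences or
#'   ties are present, normal approximation otherwise. All-zero differences
#'   return p = 1 with a warning.
#' @export
paired_comparison <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 6L)
  d <- a - b
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  exact <- length(a) <= 25L && !any(d == 0) && !anyDuplicated(abs(d[d != 0]))
  suppressWarnings(
    wilcox.test(a, b, paired = TRUE, exact = exact, correct = TRUE)$p.value)
}
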