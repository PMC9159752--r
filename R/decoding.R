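#' Construct an epoched multichannel data set
#'
#' @param data numeric array `trials x channels x time` (arbitrary units).
#' @param labels condition id per trial (length `dim(data)[1]`).
#' @param fs sampling rate in Hz.
#' @param window epoch window in seconds relative to stimulus onset,
#'   `c(t0, t1)`; the time axis is `seq(t0, by = 1/fs, length.out = n_time)`.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, window) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be trials x channels x time")
  if (length(labels) != dim(data)[1L]) stop("one label per trial required")
  if (fs <= 0) stop("fs must be positive")
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  structure(list(data = data, labels = labels, fs = fs,
                 window = as.numeric(window)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d bins, fs = %g Hz, window [%g, %g] s, %d conditions\n",
              d[1L], d[2L], d[3L], x$fs, x$window[1L], x$window[2L],
              length(unique(x$labels))))
  invisible(x)
}

#' Time stamps of an epoch set's bins
#'
#' @param epochs an `epoch_set`.
#' @return numeric vector of bin times in seconds.
#' @export
epoch_times <- function(epochs) {
  seq(epochs$window[1L], by = 1 / epochs$fs, length.out = dim(epochs$data)[3L])
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean signal over the baseline
#' window (default: everything before stimulus onset).
#'
#' @param epochs an `epoch_set`.
#' @param window baseline window `c(t0, t1)` in seconds (must lie within the
#'   epoch).
#' @return the baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(epochs$window[1L], 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  tt <- epoch_times(epochs)
  sel <- which(tt >= window[1L] & tt <= window[2L])
  if (length(sel) == 0L) stop("baseline window contains no bins")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1L, 2L), mean)
  epochs$data <- epochs$data - array(bl, dim(epochs$data))
  epochs
}

#' Average trials of one condition into pseudotrials
#'
#' Randomly partitions the condition's trials into `n_groups` near-equal
#' groups and averages within each, trading trials for signal-to-noise before
#' classification. With 10 presentations per condition and split-half
#' cross-validation the default grouping yields a single pseudotrial of (at
#' most) five averaged trials per half.
#'
#' @param epochs an `epoch_set`.
#' @param condition a condition id present in `epochs$labels`.
#' @param n_groups number of pseudotrials to form (`<=` number of trials).
#' @param seed optional RNG seed.
#' @return array `n_groups x channels x time`.
#' @export
make_pseudotrials <- function(epochs, condition, n_groups, seed = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is.null(seed)) set.seed(seed)
  idx <- which(epochs$labels == condition)
  if (length(idx) < n_groups) stop("condition has fewer trials than n_groups")
  pseudo_average(epochs$data[idx, , , drop = FALSE], n_groups)
}

#' Default pseudotrial count for a training/test half
#'
#' @param n_trials trials available in the half.
#' @param max_per_group maximum trials averaged into one pseudotrial
#'   (default 5).
#' @return number of pseudotrial groups, `ceiling(n_trials / max_per_group)`.
#' @export
n_pseudotrial_groups <- function(n_trials, max_per_group = 5L) {
  as.integer(ceiling(n_trials / max_per_group))
}

# Random near-equal partition + within-group average of a trials x ch x time
# array. Uses the current RNG state.
pseudo_average <- function(x, n_groups) {
  n <- dim(x)[1L]
  assign <- sort(rep_len(seq_len(n_groups), n))[sample.int(n)]
  out <- array(0, c(n_groups, dim(x)[2L], dim(x)[3L]))
  for (g in seq_len(n_groups)) {
    sel <- which(assign == g)
    out[g, , ] <- if (length(sel) == 1L) x[sel, , ] else
      apply(x[sel, , , drop = FALSE], c(2L, 3L), mean)
  }
  out
}

#' Ledoit-Wolf shrinkage covariance
#'
#' Analytic shrinkage of the sample channel covariance toward a scaled
#' identity target, stabilizing estimates when trials are scarce relative to
#' channels.
#'
#' @param x observations x channels matrix.
#' @return list with `sigma` (shrunk covariance), `shrinkage` (intensity in
#'   `[0, 1]`).
#' @export
shrinkage_cov <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("need at least 2 observations")
  xc <- scale(x, center = TRUE, scale = FALSE)
  s <- crossprod(xc) / n
  mu <- sum(diag(s)) / p
  d2 <- sum((s - diag(mu, p))^2) / p
  b2bar <- 0
  for (i in seq_len(n)) {
    xi <- xc[i, ]
    b2bar <- b2bar + sum((tcrossprod(xi) - s)^2) / p
  }
  b2bar <- b2bar / n^2
  b2 <- min(b2bar, d2)
  rho <- if (d2 > 0) b2 / d2 else 1
  list(sigma = rho * diag(mu, p) + (1 - rho) * s, shrinkage = rho)
}

#' Multivariate noise normalization transform
#'
#' Returns the inverse matrix square root of a shrinkage-regularized channel
#' covariance estimated from training data only. Applying the transform to
#' data whose true covariance is the estimated one yields identity covariance
#' in expectation ("whitening").
#'
#' @param train_epochs observations x channels matrix of training samples
#'   (typically per-bin residuals around condition means, pooled over bins).
#' @return list of class `noise_normalizer`: `W` (channels x channels
#'   whitening matrix, symmetric), `sigma`, `shrinkage`.
#' @export
noise_normalizer <- function(train_epochs) {
  sc <- shrinkage_cov(train_epochs)
  if (max(abs(sc$sigma)) == 0) {
    warning("zero training covariance; whitening disabled (identity)")
    p <- ncol(sc$sigma)
    return(structure(list(W = diag(p), sigma = sc$sigma, shrinkage = 1),
                     class = "noise_normalizer"))
  }
  e <- eigen(sc$sigma, symmetric = TRUE)
  vals <- pmax(e$values, max(e$values) * 1e-12)
  W <- e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
  structure(list(W = W, sigma = sc$sigma, shrinkage = sc$shrinkage),
            class = "noise_normalizer")
}

# Residuals around per-condition, per-bin means for a list of raw-trial
# arrays (one per condition); rows pooled over bins.
pooled_residuals <- function(trial_arrays) {
  rows <- list()
  for (arr in trial_arrays) {
    nt <- dim(arr)[3L]
    for (t in seq_len(nt)) {
      m <- matrix(arr[, , t, drop = FALSE], nrow = dim(arr)[1L])
      rows[[length(rows) + 1L]] <- sweep(m, 2L, colMeans(m))
    }
  }
  do.call(rbind, rows)
}

# Apply a whitener to a pseudo x ch x time array.
whiten_array <- function(arr, W) {
  out <- arr
  for (t in seq_len(dim(arr)[3L])) {
    out[, , t] <- matrix(arr[, , t], nrow = dim(arr)[1L]) %*% W
  }
  out
}

# One repeat of the split-half decode over a set of conditions.
# Returns accuracy fraction matrix [n_pairs(cond) x n_time], averaged over
# the two fold directions. Uses the current RNG state.
decode_once <- function(epochs, conds, max_per_group, cost, whiten = TRUE) {
  d <- dim(epochs$data)
  halves <- lapply(conds, function(cc) {
    idx <- which(epochs$labels == cc)
    h <- floor(length(idx) / 2L)
    if (h < 1L) stop(sprintf("condition '%s' has too few trials to split", cc))
    perm <- sample(idx)
    list(a = perm[seq_len(h)], b = perm[h + seq_len(h)])
  })
  pseudo <- lapply(halves, function(hh) {
    ng <- n_pseudotrial_groups(length(hh$a), max_per_group)
    list(a = pseudo_average(epochs$data[hh$a, , , drop = FALSE], ng),
         b = pseudo_average(epochs$data[hh$b, , , drop = FALSE], ng))
  })
  np <- n_pairs(length(conds))
  acc <- matrix(0, np, d[3L])
  for (dir in 1:2) {
    tr <- lapply(pseudo, function(p) if (dir == 1L) p$a else p$b)
    te <- lapply(pseudo, function(p) if (dir == 1L) p$b else p$a)
    if (whiten) {
      # noise covariance from the training half's raw trials only
      raw_tr <- lapply(halves, function(hh) {
        epochs$data[if (dir == 1L) hh$a else hh$b, , , drop = FALSE]
      })
      W <- noise_normalizer(pooled_residuals(raw_tr))$W
      tr <- lapply(tr, whiten_array, W = W)
      te <- lapply(te, whiten_array, W = W)
    }
    pp <- all_pairs(length(conds))
    for (k in seq_len(np)) {
      acc[k, ] <- acc[k, ] + cpp_decode_timecourse(
        tr[[pp[k, 1L]]], tr[[pp[k, 2L]]],
        te[[pp[k, 1L]]], te[[pp[k, 2L]]], cost)
    }
  }
  acc / 2
}

#' Time-resolved pairwise decoding for one condition pair
#'
#' Split-half cross-validated classification of two conditions at every time
#' bin: per repeat, trials are split in half, pseudotrials are formed within
#' each half, both halves are whitened by a noise normalizer estimated from
#' the training half only, and a linear maximum-margin (support vector)
#' classifier is trained per bin and scored on the test half. Both fold
#' directions are scored; accuracies are averaged over directions and
#' repeats. Chance is 50%.
#'
#' @param epochs an `epoch_set`.
#' @param pair length-2 vector of condition ids.
#' @param n_repeats number of random split repeats (default 10).
#' @param max_per_group maximum trials averaged per pseudotrial (default 5).
#' @param cost SVM regularization constant (default 1).
#' @param whiten apply multivariate noise normalization (default TRUE)?
#' @param seed RNG seed (mandatory).
#' @return numeric vector of decoding accuracies in percent, one per time
#'   bin, with attribute `"times"`.
#' @export
pairwise_timecourse_decode <- function(epochs, pair, n_repeats = 10L,
                                       max_per_group = 5L, cost = 1,
                                       whiten = TRUE, seed) {
  stopifnot(inherits(epochs, "epoch_set"), length(pair) == 2L)
  if (!all(pair %in% epochs$labels)) stop("both conditions must be present")
  set.seed(seed)
  acc <- 0
  for (r in seq_len(n_repeats)) {
    acc <- acc + decode_once(epochs, as.list(pair), max_per_group, cost, whiten)
  }
  out <- 100 * as.vector(acc[1L, ]) / n_repeats
  attr(out, "times") <- epoch_times(epochs)
  out
}

#' Time-resolved RDM from all-pairs decoding
#'
#' Runs split-half pairwise decoding between every pair of conditions and
#' assembles, at each time bin, an RDM whose entries are decoding accuracies
#' in percent — higher accuracy meaning greater pattern dissimilarity. The
#' noise normalizer of each repeat/direction is estimated once from the
#' training half across all conditions.
#'
#' @param epochs an `epoch_set`.
#' @param n_repeats random split repeats (default 10).
#' @param max_per_group maximum trials per pseudotrial (default 5).
#' @param cost SVM regularization constant.
#' @param whiten apply multivariate noise normalization?
#' @param seed RNG seed (mandatory).
#' @return an object of class `time_rdm`: list with `values`
#'   (`n_pairs x n_bins` matrix of accuracies in percent), `times` (s),
#'   `n_items`, `conditions`.
#' @export
decoding_rdm_movie <- function(epochs, n_repeats = 10L, max_per_group = 5L,
                               cost = 1, whiten = TRUE, seed) {
  stopifnot(inherits(epochs, "epoch_set"))
  conds <- sort(unique(epochs$labels))
  if (length(conds) < 2L) stop("need at least 2 conditions")
  set.seed(seed)
  acc <- 0
  for (r in seq_len(n_repeats)) {
    acc <- acc + decode_once(epochs, as.list(conds), max_per_group, cost, whiten)
  }
  time_rdm(100 * acc / n_repeats, epoch_times(epochs), length(conds), conds)
}

#' Construct a time-resolved RDM container
#'
#' @param values `n_pairs x n_bins` matrix (accuracy entries must lie in
#'   `[0, 100]`).
#' @param times bin time stamps (s).
#' @param n_items number of conditions.
#' @param conditions optional condition ids.
#' @return an object of class `time_rdm`.
#' @export
time_rdm <- function(values, times, n_items, conditions = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != n_pairs(n_items))
    stop("values must have one row per condition pair")
  if (ncol(values) != length(times)) stop("one column per time bin required")
  if (any(values < 0) || any(values > 100))
    stop("accuracy values must lie in [0, 100]")
  structure(list(values = values, times = as.numeric(times),
                 n_items = as.integer(n_items), conditions = conditions),
            class = "time_rdm")
}

#' @export
print.time_rdm <- function(x, ...) {
  cat(sprintf("<time_rdm> %d items (%d pairs) x %d bins, t in [%g, %g] s\n",
              x$n_items, nrow(x$values), ncol(x$values),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Extract the RDM at one time bin
#'
#' @param trdm a `time_rdm`.
#' @param bin bin index.
#' @return an `rdm` with `metric_tag = "accuracy"`.
#' @export
rdm_at <- function(trdm, bin) {
  make_rdm(trdm$values[, bin], trdm$n_items, metric_tag = "accuracy")
}

#' Average a time-resolved RDM over sliding windows
#'
#' Bin-level RDMs are averaged within sliding windows of `width_ms`
#' milliseconds advancing by `width_ms - overlap_ms` (10 ms windows with 6 ms
#' overlap give a 4 ms stride). Each window is stamped with its center time.
#'
#' @param trdm a `time_rdm` with equally spaced bins.
#' @param width_ms window width (ms).
#' @param overlap_ms overlap between consecutive windows (ms), `< width_ms`.
#' @return a `time_rdm` over windows.
#' @export
sliding_windows <- function(trdm, width_ms = 10, overlap_ms = 6) {
  stopifnot(inherits(trdm, "time_rdm"))
  if (overlap_ms < 0 || width_ms <= overlap_ms)
    stop("need width_ms > overlap_ms >= 0")
  dt_ms <- 1000 * median(diff(trdm$times))
  wbins <- round(width_ms / dt_ms)
  if (wbins < 1L) stop("window shorter than one bin")
  stride <- max(1L, round((width_ms - overlap_ms) / dt_ms))
  nb <- ncol(trdm$values)
  starts <- seq(1L, nb - wbins + 1L, by = stride)
  vals <- vapply(starts, function(s) {
    rowMeans(trdm$values[, s:(s + wbins - 1L), drop = FALSE])
  }, numeric(nrow(trdm$values)))
  vals <- matrix(vals, nrow = nrow(trdm$values))
  centers <- vapply(starts, function(s) mean(trdm$times[s:(s + wbins - 1L)]), 1.0)
  time_rdm(vals, centers, trdm$n_items, trdm$conditions)
}
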