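#' Assemble predictor groups for variance partitioning
#'
#' @param visual,action,social lists of `rdm` objects (model RDMs) for the
#'   three predictor groups (visual, action, social-affective).
#' @return a list of class `predictor_groups`.
#' @export
predictor_groups <- function(visual, action, social) {
  grp <- list(visual = visual, action = action, social = social)
  for (g in names(grp)) {
    stopifnot(length(grp[[g]]) >= 1L)
    for (r in grp[[g]]) stopifnot(inherits(r, "rdm"))
  }
  n <- grp$visual[[1L]]$n_items
  all_r <- c(grp$visual, grp$action, grp$social)
  if (!all(vapply(all_r, function(r) r$n_items, 1L) == n))
    stop("all predictor RDMs must share n_items")
  structure(grp, class = "predictor_groups")
}

# Column-bind condensed vectors of a list of rdms, z-scored for conditioning.
predictor_matrix <- function(rdms) {
  X <- vapply(rdms, function(r) r$values, numeric(length(rdms[[1L]]$values)))
  X <- as.matrix(X)
  s <- apply(X, 2L, sd)
  s[s == 0] <- 1
  scale(X, scale = s)
}

#' Fit a regression on a training RDM and score its prediction on a test RDM
#'
#' Ordinary least squares of the training RDM's condensed vector on the
#' predictor RDMs' condensed vectors (plus intercept); the fitted prediction
#' is then compared to the test RDM's condensed vector by squared Kendall
#' tau-a. Predictor columns are z-scored before fitting; since tau-a is
#' rank-based, predictions are invariant to this up to the intercept. Pairs
#' missing (NA) in train or test are excluded.
#'
#' @param train_rdm,test_rdm `rdm` objects or condensed numeric vectors
#'   (train and test halves of the data).
#' @param predictors list of predictor `rdm`s, or a ready pairs x p numeric
#'   matrix.
#' @return list with `tausq` (the predicted squared tau-a), `tau` (signed),
#'   `coef`, `n_pairs_used`. A rank-deficient predictor set is fit by the
#'   minimum-norm solution with a warning.
#' @export
fit_predict_tausq <- function(train_rdm, test_rdm, predictors) {
  tr <- if (inherits(train_rdm, "rdm")) train_rdm$values else as.numeric(train_rdm)
  te <- if (inherits(test_rdm, "rdm")) test_rdm$values else as.numeric(test_rdm)
  X <- if (is.list(predictors)) predictor_matrix(predictors) else as.matrix(predictors)
  if (length(tr) != length(te) || nrow(X) != length(tr))
    stop("train, test and predictors must cover the same pairs")
  keep <- !is.na(tr) & !is.na(te) & complete.cases(X)
  if (sum(keep) < ncol(X) + 2L) stop("too few complete pairs to fit")
  Xi <- cbind(intercept = 1, X[keep, , drop = FALSE])
  y <- tr[keep]
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    warning("collinear predictor set; using minimum-norm solution")
    beta <- MASS::ginv(Xi) %*% y
  } else {
    beta <- qr.coef(qrx, y)
  }
  pred <- as.vector(Xi %*% beta)
  tau <- tau_a(pred, te[keep])
  list(tausq = tau^2, tau = tau, coef = as.vector(beta),
       n_pairs_used = sum(keep))
}

#' Commonality decomposition of cross-validated explained variance
#'
#' Inclusion-exclusion (commonality analysis) over three predictor groups:
#' given the predicted tau-a^2 of all seven non-empty group subsets, returns
#' the three unique components, three pairwise-shared components, and the
#' triple-shared component. The components sum to the full model's tau-a^2
#' exactly (algebraic identity); individual components may be negative,
#' which is expected behavior of commonality analysis under suppression.
#'
#' @param tausq named numeric vector with entries `V`, `A`, `S`, `VA`, `VS`,
#'   `AS`, `VAS` (the predicted tau-a^2 of each predictor-group subset;
#'   V = visual, A = action, S = social-affective).
#' @return named numeric vector: `unique_V`, `unique_A`, `unique_S`,
#'   `shared_VA`, `shared_VS`, `shared_AS`, `shared_VAS`, `full`.
#' @export
commonality_partition <- function(tausq) {
  need <- c("V", "A", "S", "VA", "VS", "AS", "VAS")
  if (!all(need %in% names(tausq)))
    stop("tausq must contain entries: ", paste(need, collapse = ", "))
  r <- tausq[need]
  out <- c(
    unique_V  = unname(r["VAS"] - r["AS"]),
    unique_A  = unname(r["VAS"] - r["VS"]),
    unique_S  = unname(r["VAS"] - r["VA"]),
    shared_VA = unname(r["VS"] + r["AS"] - r["S"] - r["VAS"]),
    shared_VS = unname(r["VA"] + r["AS"] - r["A"] - r["VAS"]),
    shared_AS = unname(r["VA"] + r["VS"] - r["V"] - r["VAS"]),
    shared_VAS = unname(r["VAS"] - r["VA"] - r["VS"] - r["AS"] +
                          r["V"] + r["A"] + r["S"]),
    full = unname(r["VAS"])
  )
  out
}

subset_keys <- c("V", "A", "S", "VA", "VS", "AS", "VAS")

subset_columns <- function(nv, na, ns) {
  v <- seq_len(nv); a <- nv + seq_len(na); s <- nv + na + seq_len(ns)
  list(V = v, A = a, S = s, VA = c(v, a), VS = c(v, s), AS = c(a, s),
       VAS = c(v, a, s))
}

# Evaluate all 7 subset models for one train/test split (masked vectors ok).
eval_subsets <- function(tr, te, X, cols) {
  vapply(subset_keys, function(k) {
    fit_predict_tausq(tr, te, X[, cols[[k]], drop = FALSE])$tausq
  }, 1.0)
}

#' Cross-validated variance partitioning over predictor groups
#'
#' Decomposes the cross-validated explained variance (predicted squared
#' Kendall tau-a) of a target RDM into unique and shared contributions of the
#' visual / action / social-affective predictor groups. Three train/test
#' schemes: `"split_subjects"` leaves out half of the subjects per iteration
#' (full designs); `"split_estimates"` leaves out half of the individual
#' similarity estimates of every pair independently (partial designs, where
#' different subjects saw different item subsets); `"split_half_neural"`
#' splits subjects in half and partitions each time window of time-resolved
#' RDMs.
#'
#' @param target list of subject `rdm`s (behavior schemes) or subject
#'   `time_rdm`s (`"split_half_neural"`).
#' @param groups a [predictor_groups()] object.
#' @param scheme cross-validation scheme (see above).
#' @param n_iter number of split iterations (default 100).
#' @param seed RNG seed (mandatory).
#' @param config an [inference_config()] for the significance tests.
#' @param signif run significance tests (default TRUE; sign permutation over
#'   iterations — omnibus-corrected across components for behavior,
#'   cluster-corrected across windows for neural).
#' @return an object of class `varpart`: list with `components`
#'   (iterations x 8 matrix, or iterations x 8 x windows array), component
#'   names as in [commonality_partition()], `times` (neural), `scheme`,
#'   `neg_tau_count` (iterations where some subset model anti-predicted),
#'   `n_masked` (pairs excluded per iteration), and `tests` (per-component
#'   p-values) when `signif`.
#' @export
crossval_varpart <- function(target, groups,
                             scheme = c("split_subjects", "split_estimates",
                                        "split_half_neural"),
                             n_iter = 100L, seed,
                             config = inference_config(), signif = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(groups, "predictor_groups"))
  set.seed(seed)
  nv <- length(groups$visual); na <- length(groups$action); ns <- length(groups$social)
  X <- predictor_matrix(c(groups$visual, groups$action, groups$social))
  cols <- subset_columns(nv, na, ns)
  comp_names <- c("unique_V", "unique_A", "unique_S", "shared_VA",
                  "shared_VS", "shared_AS", "shared_VAS", "full")
  n_sub <- length(target)
  if (scheme == "split_half_neural") {
    stopifnot(inherits(target[[1L]], "time_rdm"), n_sub >= 2L)
    nt <- ncol(target[[1L]]$values)
    comps <- array(NA_real_, c(n_iter, 8L, nt),
                   dimnames = list(NULL, comp_names, NULL))
    for (it in seq_len(n_iter)) {
      half <- sample(n_sub, floor(n_sub / 2))
      for (t in seq_len(nt)) {
        tr <- rowMeans(vapply(target[half], function(x) x$values[, t],
                              numeric(nrow(X))))
        te <- rowMeans(vapply(target[-half], function(x) x$values[, t],
                              numeric(nrow(X))))
        comps[it, , t] <- commonality_partition(eval_subsets(tr, te, X, cols))
      }
    }
    out <- list(components = comps, component_names = comp_names,
                times = target[[1L]]$times, scheme = scheme,
                n_iter = n_iter)
  } else {
    stopifnot(inherits(target[[1L]], "rdm"), n_sub >= 2L)
    np <- nrow(X)
    comps <- matrix(NA_real_, n_iter, 8L, dimnames = list(NULL, comp_names))
    n_masked <- integer(n_iter)
    if (scheme == "split_estimates") {
      V <- vapply(target, function(r) r$values, numeric(np))  # np x S
      E <- vapply(target, function(r) r$evidence, numeric(np))
      V[E == 0] <- 0
    }
    for (it in seq_len(n_iter)) {
      if (scheme == "split_subjects") {
        half <- sample(n_sub, floor(n_sub / 2))
        tr_r <- average_rdms(target[half], allow_missing = TRUE)
        te_r <- average_rdms(target[-half], allow_missing = TRUE)
        tr <- tr_r$values; te <- te_r$values
      } else {
        # independent per-pair split of the individual estimates
        A <- matrix(runif(length(V)) < 0.5, np, ncol(V))
        wtr <- E * A; wte <- E * !A
        tr <- rowSums(V * wtr) / rowSums(wtr)
        te <- rowSums(V * wte) / rowSums(wte)
        tr[rowSums(wtr) == 0] <- NA
        te[rowSums(wte) == 0] <- NA
      }
      n_masked[it] <- sum(is.na(tr) | is.na(te))
      comps[it, ] <- commonality_partition(eval_subsets(tr, te, X, cols))
    }
    out <- list(components = comps, component_names = comp_names,
                scheme = scheme, n_iter = n_iter, n_masked = n_masked)
  }
  out$neg_tau_count <- NA_integer_
  class(out) <- "varpart"
  if (signif) out$tests <- varpart_tests(out, config)
  out
}

# Significance of each component: one-tailed sign permutation over
# iterations; omnibus-corrected across components (behavior) or
# cluster-corrected across windows (neural), per component.
varpart_tests <- function(vp, config = inference_config()) {
  idx <- 1:7 # the 7 commonality components
  if (vp$scheme == "split_half_neural") {
    lapply(idx, function(k) {
      suppressMessages(sign_permutation_test(vp$components[, k, ],
                                             config, "cluster_sum"))
    }) -> tests
    names(tests) <- vp$component_names[idx]
    tests
  } else {
    suppressMessages(sign_permutation_test(vp$components[, idx, drop = FALSE],
                                           config, "omnibus_max"))
  }
}

#' @export
print.varpart <- function(x, ...) {
  cat(sprintf("<varpart> scheme = %s, %d iterations\n", x$scheme, x$n_iter))
  if (length(dim(x$components)) == 2L) {
    m <- colMeans(x$components)
    for (k in seq_along(m))
      cat(sprintf("  %-11s %+.5f\n", x$component_names[k], m[k]))
  } else {
    cat(sprintf("  %d windows; component means over time:\n",
                dim(x$components)[3L]))
    m <- apply(x$components, 2L, mean)
    for (k in seq_along(m))
      cat(sprintf("  %-11s %+.5f\n", x$component_names[k], m[k]))
  }
  invisible(x)
}

#' Onset distributions of time-resolved variance-partition components
#'
#' For a neural-scheme [crossval_varpart()] result: each component's
#' group-significant windows are found by a cluster-corrected sign
#' permutation test over iterations; each iteration's onset is the earliest
#' group-significant window at which that iteration's component value is
#' positive. Onset distributions are summarized (mean, SD, central CI) and
#' compared pairwise between the three unique components with two-sided
#' Wilcoxon signed-rank tests.
#'
#' @param vp a `varpart` from `scheme = "split_half_neural"`.
#' @param config an [inference_config()].
#' @param components which components to analyze (default: the three unique
#'   components).
#' @return list with `onsets` (iterations x components matrix of onset
#'   times, `NA` when an iteration never shows the effect), `summary`
#'   (data.frame: component, mean, sd, lo, hi, prop_missing), and
#'   `pairwise` (data.frame of paired test p-values).
#' @export
onset_distribution_compare <- function(vp, config = inference_config(),
                                       components = c("unique_V", "unique_A",
                                                      "unique_S")) {
  stopifnot(inherits(vp, "varpart"), vp$scheme == "split_half_neural")
  comp_idx <- match(components, vp$component_names)
  stopifnot(!anyNA(comp_idx))
  times <- vp$times
  onsets <- matrix(NA_real_, vp$n_iter, length(components),
                   dimnames = list(NULL, components))
  for (q in seq_along(comp_idx)) {
    k <- comp_idx[q]
    test <- suppressMessages(
      sign_permutation_test(vp$components[, k, ], config, "cluster_sum"))
    sig <- which(test$significant)
    if (length(sig) == 0L) next
    for (it in seq_len(vp$n_iter)) {
      pos <- sig[vp$components[it, k, sig] > 0]
      if (length(pos)) onsets[it, q] <- times[min(pos)]
    }
  }
  qs <- c((1 - config$ci) / 2, 1 - (1 - config$ci) / 2)
  summ <- data.frame(
    component = components,
    mean = apply(onsets, 2L, mean, na.rm = TRUE),
    sd = apply(onsets, 2L, sd, na.rm = TRUE),
    lo = apply(onsets, 2L, function(v) if (any(!is.na(v))) quantile(v, qs[1L], na.rm = TRUE) else NA_real_),
    hi = apply(onsets, 2L, function(v) if (any(!is.na(v))) quantile(v, qs[2L], na.rm = TRUE) else NA_real_),
    prop_missing = apply(onsets, 2L, function(v) mean(is.na(v))),
    row.names = NULL)
  pw <- data.frame(a = character(0), b = character(0), p = numeric(0))
  if (length(components) >= 2L) {
    cmb <- utils::combn(length(components), 2L)
    for (c2 in seq_len(ncol(cmb))) {
      i <- cmb[1L, c2]; j <- cmb[2L, c2]
      ok <- !is.na(onsets[, i]) & !is.na(onsets[, j])
      p <- if (sum(ok) >= 6L) paired_comparison(onsets[ok, i], onsets[ok, j]) else NA_real_
      pw <- rbind(pw, data.frame(a = components[i], b = components[j], p = p))
    }
  }
  list(onsets = onsets, summary = summ, pairwise = pw)
}
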