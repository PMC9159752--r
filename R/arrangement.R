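#' Create an empty multiple-arrangement session
#'
#' A session tracks the ordered arrangement trials of one subject together
#' with the per-pair evidence accumulated so far. Items are drawn inside the
#' unit disk; the session ends when every pair's evidence reaches the
#' evidence criterion (default 0.5) or the trial budget is exhausted.
#' Subjects may arrange only a subset of a larger item set (`item_ids` maps
#' local items to the full set).
#'
#' @param item_ids integer ids of the items this subject arranges (within a
#'   full set of `n_total` items).
#' @param n_total total number of items in the stimulus set.
#' @param criterion per-pair evidence criterion at which the session ends.
#' @param max_trial_size maximum items shown in any one trial (7 in the
#'   subset design, 8 in the full design).
#' @param trial_budget maximum number of trials (time-out).
#' @return an object of class `arrangement_session`.
#' @export
new_session <- function(item_ids, n_total = max(item_ids), criterion = 0.5,
                        max_trial_size = 8L, trial_budget = 1000L) {
  item_ids <- as.integer(item_ids)
  stopifnot(length(item_ids) >= 3L, !anyDuplicated(item_ids),
            all(item_ids >= 1L), all(item_ids <= n_total),
            criterion > 0, max_trial_size >= 3L)
  m <- length(item_ids)
  structure(list(item_ids = item_ids, n_total = as.integer(n_total),
                 trials = list(),
                 evidence = rep(0, n_pairs(m)),
                 appearances = rep(0L, m),
                 criterion = criterion,
                 max_trial_size = as.integer(max_trial_size),
                 trial_budget = as.integer(trial_budget)),
            class = "arrangement_session")
}

#' @export
print.arrangement_session <- function(x, ...) {
  cat(sprintf("<arrangement_session> %d items (of %d), %d trials, min evidence %.3f (criterion %.2f)\n",
              length(x$item_ids), x$n_total, length(x$trials),
              if (length(x$evidence)) min(x$evidence) else NA, x$criterion))
  invisible(x)
}

#' Has a session reached its evidence criterion?
#'
#' @param session an `arrangement_session`.
#' @return `TRUE` if every pair's evidence is at or above the criterion.
#' @export
session_complete <- function(session) {
  all(session$evidence >= session$criterion)
}

#' Simulate one arrangement trial by a synthetic participant
#'
#' The synthetic arranger embeds the subset's sub-RDM into the plane by
#' classical (metric) multidimensional scaling, rescales the configuration
#' isotropically to fit the unit disk, and jitters each coordinate with
#' Gaussian placement noise of standard deviation `placement_noise` (then
#' rescales again if the jitter pushed a point outside the disk).
#'
#' @param true_rdm the ground-truth `rdm` guiding the arranger (over the full
#'   item set).
#' @param subset integer ids (into `true_rdm`'s items) of the items shown.
#' @param placement_noise coordinate jitter SD (disk units).
#' @param seed optional RNG seed for reproducibility.
#' @return a list of class `arrangement_trial` with fields `subset` and
#'   `coords` (|subset| x 2, radius <= 1).
#' @export
simulate_arranger <- function(true_rdm, subset, placement_noise = 0, seed = NULL) {
  stopifnot(inherits(true_rdm, "rdm"), placement_noise >= 0)
  subset <- as.integer(subset)
  if (length(subset) < 2L) stop("subset must contain at least 2 items")
  if (any(subset < 1L) || any(subset > true_rdm$n_items)) stop("subset out of range")
  if (!is.null(seed)) set.seed(seed)
  m <- length(subset)
  d <- rdm_submatrix(true_rdm, subset)
  if (all(d == 0)) {
    warning("degenerate sub-RDM (all zeros): items placed at disk center")
    coords <- matrix(0, m, 2L)
    if (placement_noise > 0) {
      coords <- coords + matrix(rnorm(2L * m, sd = placement_noise), m, 2L)
      r <- max(sqrt(rowSums(coords^2)))
      if (r > 1) coords <- coords / r
    }
  } else {
    coords <- cpp_mds_disk(d, placement_noise)
  }
  structure(list(subset = subset, coords = coords), class = "arrangement_trial")
}

# Square dissimilarity submatrix of an rdm for the given items.
rdm_submatrix <- function(rdm, subset) {
  m <- length(subset)
  p <- all_pairs(m)
  v <- rdm$values[condensed_index(subset[p[, 1L]], subset[p[, 2L]], rdm$n_items)]
  d <- matrix(0, m, m)
  d[p] <- v
  d[p[, c(2L, 1L)]] <- v
  d
}

#' Select the next trial subset by lift-the-weakest sampling
#'
#' Adaptive sampling that re-presents the item pairs with the least
#' accumulated evidence: the minimum-evidence pair seeds the subset
#' (preferring rarely shown items, random tie-break). The subset then grows
#' by zooming in: unseen items join first (so fresh sessions cover all items
#' before any repeats), after which the items judged most similar to the
#' seed pair under the supplied dissimilarity estimate are added, up to the
#' trial-size cap. Re-arranging a subset of mutually similar items spreads
#' their on-screen distances over the whole disk, which is what lets
#' crowded pairs gain evidence quickly. Without an estimate, growth falls
#' back to the items with least evidence toward the seed (random among
#' ties).
#'
#' @param session an `arrangement_session`.
#' @param est optional dissimilarity estimate steering the zoom-in growth:
#'   an `rdm` over the session's full item set, or an `m x m` matrix over
#'   the session's local items.
#' @param size subset size (default: the session's trial-size cap, never more
#'   than the item count).
#' @return integer vector of *local* item indices (into `session$item_ids`),
#'   or `NULL` if the session has reached its criterion (completion signal).
#' @export
lift_the_weakest <- function(session, est = NULL, size = NULL) {
  stopifnot(inherits(session, "arrangement_session"))
  if (session_complete(session)) return(NULL)
  m <- length(session$item_ids)
  if (is.null(size)) size <- min(session$max_trial_size, m)
  size <- min(size, m)
  D <- if (is.null(est)) matrix(0, m, m)
       else if (inherits(est, "rdm")) rdm_submatrix(est, session$item_ids)
       else as.matrix(est)
  if (!all(dim(D) == m)) stop("est must cover the session's items")
  out <- cpp_next_subset(session$evidence, session$appearances, D,
                         size, session$criterion)
  if (length(out) == 0L) NULL else out
}

#' Accumulate pair evidence from an arrangement trial
#'
#' Each pair shown in the trial gains a per-trial evidence weight
#' `w = (on-screen distance / disk diameter)^2` (so far-apart placements are
#' more informative than crowded ones), and evidence accumulates across
#' trials as `1 - prod(1 - w_t)`. Evidence is monotonically nondecreasing and
#' bounded by 1.
#'
#' @param trial an `arrangement_trial` whose `subset` holds *local* item
#'   indices of the session.
#' @param session an `arrangement_session`.
#' @return the updated session (trial appended).
#' @export
update_evidence <- function(trial, session) {
  stopifnot(inherits(trial, "arrangement_trial"),
            inherits(session, "arrangement_session"))
  m <- length(session$item_ids)
  s <- trial$subset
  if (length(s) >= 2L) {
    d <- as.vector(dist(trial$coords))
    w <- pmin((d / 2)^2, 1)
    p <- all_pairs(length(s))
    k <- condensed_index(s[p[, 1L]], s[p[, 2L]], m)
    session$evidence[k] <- 1 - (1 - session$evidence[k]) * (1 - w)
  }
  session$appearances[s] <- session$appearances[s] + 1L
  session$trials[[length(session$trials) + 1L]] <- trial
  session
}

#' Simulate a complete adaptive arrangement session
#'
#' Runs lift-the-weakest subset selection, synthetic arrangement, and
#' evidence accumulation until the evidence criterion is met for every pair
#' or the trial budget runs out.
#'
#' @param true_rdm ground-truth `rdm` over the full item set.
#' @param item_ids items this subject arranges (default: all).
#' @param placement_noise coordinate jitter SD.
#' @param criterion,max_trial_size,trial_budget see [new_session()].
#' @param seed RNG seed (mandatory: sessions are stochastic).
#' @return a completed `arrangement_session`.
#' @export
simulate_session <- function(true_rdm, item_ids = seq_len(true_rdm$n_items),
                             placement_noise = 0.05, criterion = 0.5,
                             max_trial_size = 8L, trial_budget = 1000L,
                             seed) {
  stopifnot(inherits(true_rdm, "rdm"))
  set.seed(seed)
  s <- new_session(item_ids, n_total = true_rdm$n_items, criterion = criterion,
                   max_trial_size = max_trial_size, trial_budget = trial_budget)
  Dloc <- rdm_submatrix(true_rdm, s$item_ids) # the arranger's own estimate
  while (!session_complete(s) && length(s$trials) < s$trial_budget) {
    sub <- lift_the_weakest(s, est = Dloc)
    if (is.null(sub)) break
    d <- Dloc[sub, sub, drop = FALSE]
    coords <- if (all(d == 0)) matrix(0, length(sub), 2L)
              else cpp_mds_disk(d, placement_noise)
    tr <- structure(list(subset = sub, coords = coords),
                    class = "arrangement_trial")
    s <- update_evidence(tr, s)
  }
  s
}

#' Reconstruct a full RDM from an arrangement session by inverse MDS
#'
#' Iteratively estimates the underlying dissimilarities from partial 2D
#' arrangements: (1) each pair's dissimilarity is initialized as the
#' evidence-weighted mean of its on-screen distances; (2) each trial receives
#' a single positive least-squares scale aligning its on-screen distances to
#' the current global estimate; (3) scaled distances are re-averaged with
#' evidence weights; steps 2-3 repeat until the relative change drops below
#' `tol` (or `max_iter`). The final condensed vector is normalized to unit
#' root-mean-square, making estimates comparable across subjects.
#'
#' @param session an `arrangement_session` (real or simulated).
#' @param tol convergence tolerance on the relative change of the estimate.
#' @param max_iter iteration cap.
#' @param allow_missing if `TRUE`, pairs never co-presented are returned with
#'   `evidence = 0` (value 0) instead of raising an error.
#' @return an `rdm` over the session's *full* item set (`n_total`), with
#'   `metric_tag = "arrangement"`; pairs outside the subject's item subset
#'   carry zero evidence.
#' @export
inverse_mds_estimate <- function(session, tol = 1e-6, max_iter = 100L,
                                 allow_missing = FALSE) {
  stopifnot(inherits(session, "arrangement_session"))
  if (length(session$trials) == 0L) stop("session has no trials")
  m <- length(session$item_ids)
  # concatenate per-trial pair observations
  pk <- list(); dv <- list(); wv <- list(); tid <- list()
  for (t in seq_along(session$trials)) {
    tr <- session$trials[[t]]
    s <- tr$subset
    if (length(s) < 2L) next
    dmat <- as.matrix(dist(tr$coords))
    ii <- all_pairs(length(s))
    pk[[t]] <- condensed_index(s[ii[, 1L]], s[ii[, 2L]], m)
    dd <- dmat[ii]
    dv[[t]] <- dd
    wv[[t]] <- pmin((dd / 2)^2, 1)
    tid[[t]] <- rep(t, length(dd))
  }
  pk <- unlist(pk); dv <- unlist(dv); wv <- unlist(wv); tid <- unlist(tid)
  covered <- tabulate(pk, nbins = n_pairs(m)) > 0
  if (any(!covered)) {
    missing_pairs <- all_pairs(m)[!covered, , drop = FALSE]
    if (!allow_missing)
      stop(sprintf("%d pair(s) never co-presented, e.g. local items (%d, %d)",
                   sum(!covered), missing_pairs[1L, 1L], missing_pairs[1L, 2L]))
  }
  wsum <- rowsum(wv, pk)
  keys <- as.integer(rownames(wsum))
  ok <- wsum[, 1L] > 0
  dhat <- rep(0, n_pairs(m))
  dhat[keys] <- rowsum(wv * dv, pk)[, 1L] / pmax(wsum[, 1L], .Machine$double.eps)
  den_t <- rowsum(dv * dv, tid)[, 1L]
  tf <- factor(tid)
  for (it in seq_len(max_iter)) {
    num_t <- rowsum(dv * dhat[pk], tid)[, 1L]
    s_t <- ifelse(den_t > 0, num_t / den_t, 1)
    s_t[s_t <= 0] <- .Machine$double.eps
    newd <- dhat
    newd[keys] <- rowsum(wv * s_t[as.integer(tf)] * dv, pk)[, 1L] /
      pmax(wsum[, 1L], .Machine$double.eps)
    rel <- max(abs(newd - dhat)) / max(sqrt(mean(newd^2)), .Machine$double.eps)
    dhat <- newd
    if (rel < tol) break
  }
  rms <- sqrt(mean(dhat[covered]^2))
  if (rms > 0) dhat <- dhat / rms
  # lift local pairs into the full item set
  n <- session$n_total
  vals <- rep(0, n_pairs(n))
  evid <- rep(0, n_pairs(n))
  lp <- all_pairs(m)
  gk <- condensed_index(session$item_ids[lp[, 1L]], session$item_ids[lp[, 2L]], n)
  vals[gk] <- dhat
  evid[gk] <- session$evidence * covered
  make_rdm(vals, n, evidence = evid, metric_tag = "arrangement")
}

#' Leave-one-subject-out reliability of arrangement RDMs
#'
#' For each subject, the Kendall tau-a between their RDM and the
#' evidence-weighted average of all other subjects' RDMs, restricted to the
#' pairs the held-out subject covered (evidence > 0). Subjects with no
#' overlapping pairs are excluded with a warning.
#'
#' @param subject_rdms list of >= 3 `rdm` objects over the same item set.
#' @return named numeric vector of per-subject tau-a values (`NA` for
#'   excluded subjects).
#' @export
loo_reliability <- function(subject_rdms) {
  stopifnot(length(subject_rdms) >= 3L)
  n_sub <- length(subject_rdms)
  out <- rep(NA_real_, n_sub)
  for (s in seq_len(n_sub)) {
    others <- average_rdms(subject_rdms[-s], allow_missing = TRUE)
    mask <- subject_rdms[[s]]$evidence > 0 & others$evidence > 0 &
      !is.na(others$values)
    if (sum(mask) < 3L) {
      warning(sprintf("subject %d has too few overlapping pairs; excluded", s))
      next
    }
    out[s] <- tau_a(subject_rdms[[s]]$values[mask], others$values[mask])
  }
  names(out) <- names(subject_rdms) %||% paste0("subject", seq_len(n_sub))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag subjects whose training performance is an outlier
#'
#' Post-hoc subject exclusion rule: a subject is flagged when their score
#' (e.g., correlation of training-trial data with the group average) falls
#' more than 2 standard deviations below the group mean.
#'
#' @param scores numeric vector of per-subject scores.
#' @param n_sd exclusion threshold in SD units below the mean (default 2).
#' @return logical vector: `TRUE` for subjects to keep.
#' @export
training_inclusion <- function(scores, n_sd = 2) {
  scores >= mean(scores) - n_sd * sd(scores)
}
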