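#' @useDynLib actionrsa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cmdscale dist lm.fit quantile rnorm runif sd var wilcox.test
#' @importFrom stats cor aggregate ave complete.cases median
NULL

#' Construct a representational dissimilarity matrix (RDM)
#'
#' An RDM stores the lower/upper triangle of a symmetric dissimilarity matrix
#' as a condensed vector of length `n * (n - 1) / 2`, ordered row-major over
#' the upper triangle (the same ordering as [stats::dist()]). Each pair also
#' carries a nonnegative `evidence` weight: the number (or weight) of
#' independent estimates behind that pair's value. Full designs have evidence
#' one everywhere; partial designs (subjects who saw item subsets) have
#' heterogeneous evidence, and zero evidence marks a pair a source never saw.
#'
#' @param values numeric vector of pairwise dissimilarities, length
#'   `n_items * (n_items - 1) / 2`.
#' @param n_items number of items (conditions/stimuli).
#' @param evidence optional nonnegative per-pair weights; defaults to 1.
#' @param metric_tag one of `"euclidean"`, `"categorical"`, `"accuracy"`,
#'   `"arrangement"`, `"other"`.
#' @return an object of class `rdm`: a list with fields `n_items`, `values`,
#'   `evidence`, `metric_tag`.
#' @examples
#' make_rdm(c(3, 4, 1), n_items = 3)
#' @export
make_rdm <- function(values, n_items,
                     evidence = NULL,
                     metric_tag = c("other", "euclidean", "categorical",
                                    "accuracy", "arrangement")) {
  metric_tag <- match.arg(metric_tag)
  n_items <- as.integer(n_items)
  if (length(n_items) != 1L || is.na(n_items) || n_items < 2L)
    stop("n_items must be a single integer >= 2")
  np <- n_pairs(n_items)
  values <- as.numeric(values)
  if (length(values) != np)
    stop(sprintf("values has length %d but n_items = %d requires %d pairs",
                 length(values), n_items, np))
  if (!all(is.finite(values)))
    stop("values must be finite")
  if (is.null(evidence)) evidence <- rep(1, np)
  evidence <- as.numeric(evidence)
  if (length(evidence) != np)
    stop("evidence must have one entry per pair")
  if (any(!is.finite(evidence)) || any(evidence < 0))
    stop("evidence must be finite and nonnegative")
  if (metric_tag == "categorical" && !all(values %in% c(0, 1)))
    stop("categorical RDM values must be 0 or 1")
  structure(list(n_items = n_items, values = values,
                 evidence = evidence, metric_tag = metric_tag),
            class = "rdm")
}

#' Number of item pairs
#'
#' @param n_items number of items.
#' @return `n_items * (n_items - 1) / 2`.
#' @export
n_pairs <- function(n_items) as.integer(n_items * (n_items - 1L) / 2L)

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d items, %d pairs, metric = %s\n",
              x$n_items, length(x$values), x$metric_tag))
  cat(sprintf("  values: [%.4g, %.4g], mean evidence %.3g\n",
              min(x$values), max(x$values), mean(x$evidence)))
  invisible(x)
}

#' Condensed (pair) index of an item pair
#'
#' Maps an item pair `i < j` (1-based) to its position in the condensed
#' vector, row-major over the upper triangle — identical to the ordering of
#' [stats::dist()]. Vectorized over `i`, `j`.
#'
#' @param i,j item indices, `1 <= i < j <= n_items`.
#' @param n_items number of items.
#' @return 1-based pair index in `1 .. n_items*(n_items-1)/2`.
#' @seealso [condensed_pair()] for the inverse mapping.
#' @examples
#' condensed_index(1, 2, 4) # 1
#' condensed_index(3, 4, 4) # 6, the last pair of n = 4
#' @export
condensed_index <- function(i, j, n_items) {
  i <- as.integer(i); j <- as.integer(j)
  if (any(i == j)) stop("diagonal pairs (i == j) have no condensed index")
  if (any(i < 1L) || any(j < 1L) || any(i > n_items) || any(j > n_items))
    stop("item index out of range")
  lo <- pmin(i, j); hi <- pmax(i, j)
  as.integer((lo - 1L) * n_items - lo * (lo - 1L) / 2L + (hi - lo))
}

#' Item pair of a condensed index (inverse of `condensed_index`)
#'
#' @param k condensed pair index (1-based), vectorized.
#' @param n_items number of items.
#' @return a two-column integer matrix with columns `i`, `j` (`i < j`).
#' @export
condensed_pair <- function(k, n_items) {
  k <- as.integer(k)
  np <- n_pairs(n_items)
  if (any(k < 1L) || any(k > np)) stop("pair index out of range")
  # row i of the upper triangle holds pairs with first index i; find it by
  # inverting the cumulative pair count.
  i <- integer(length(k)); j <- integer(length(k))
  for (q in seq_along(k)) {
    kk <- k[q]; ii <- 1L
    while (kk > n_items - ii) {
      kk <- kk - (n_items - ii)
      ii <- ii + 1L
    }
    i[q] <- ii; j[q] <- ii + kk
  }
  cbind(i = i, j = j)
}

#' All item pairs of a condensed vector, in order
#'
#' @param n_items number of items.
#' @return a two-column integer matrix with one row per condensed entry.
#' @export
all_pairs <- function(n_items) {
  i <- rep(seq_len(n_items - 1L), times = (n_items - 1L):1L)
  j <- unlist(lapply(seq_len(n_items - 1L), function(a) (a + 1L):n_items),
              use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

#' Euclidean-distance RDM from an item-by-dimension feature matrix
#'
#' @param feature_matrix numeric matrix, one row per item, one column per
#'   feature dimension; no missing values.
#' @param standardize if `TRUE`, z-score each column before computing
#'   distances (off by default: multi-dimensional features are used raw).
#' @return an `rdm` with `metric_tag = "euclidean"`.
#' @export
euclidean_rdm <- function(feature_matrix, standardize = FALSE) {
  feature_matrix <- as.matrix(feature_matrix)
  storage.mode(feature_matrix) <- "double"
  if (anyNA(feature_matrix) || !all(is.finite(feature_matrix)))
    stop("feature matrix contains missing or non-finite values")
  if (ncol(feature_matrix) < 1L) stop("need at least one feature dimension")
  if (standardize) {
    s <- apply(feature_matrix, 2L, sd)
    s[s == 0] <- 1
    feature_matrix <- scale(feature_matrix, scale = s)
  }
  make_rdm(as.vector(dist(feature_matrix)), nrow(feature_matrix),
           metric_tag = "euclidean")
}

#' Binary categorical RDM from item labels
#'
#' Dissimilarity 0 for items sharing a label, 1 otherwise.
#'
#' @param labels vector of item labels (factor or character).
#' @return an `rdm` with `metric_tag = "categorical"`.
#' @export
categorical_rdm <- function(labels) {
  if (length(labels) < 2L) stop("need at least two items")
  labels <- as.character(labels)
  p <- all_pairs(length(labels))
  make_rdm(as.numeric(labels[p[, 1L]] != labels[p[, 2L]]), length(labels),
           metric_tag = "categorical")
}

#' Kendall's tau-a rank correlation
#'
#' Tau-a divides the concordant-minus-discordant count by the *full* pair
#' count `m (m - 1) / 2`; tied pairs count as neither concordant nor
#' discordant. This differs from tau-b (the [stats::cor()] variant), which
#' corrects the denominator for ties; under ties `|tau_a| <= |tau_b|`.
#'
#' @param x,y numeric vectors of equal length `m >= 2`.
#' @return a list of class `rank_correlation` with fields `tau_a` and
#'   `n_pairs_compared`.
#' @examples
#' kendall_tau_a(c(1, 2, 3, 4), c(1, 3, 2, 4))$tau_a # 4/6
#' @export
kendall_tau_a <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("inputs must not contain missing values")
  out <- cpp_kendall_tau_a(x, y)
  structure(out, class = "rank_correlation")
}

# Scalar tau-a, for internal hot paths.
tau_a <- function(x, y) cpp_kendall_tau_a(x, y)$tau_a

#' Evidence-weighted average of RDMs
#'
#' Per-pair weighted mean with weights given by each RDM's `evidence`; the
#' output evidence is the summed evidence. This supports partial-coverage
#' designs in which each source (e.g., subject) only saw a subset of items:
#' pairs a source never saw carry zero evidence and do not contribute. For
#' full designs with unit evidence this reduces to the plain mean.
#'
#' @param rdms a list of `rdm` objects sharing `n_items`.
#' @param allow_missing if `TRUE`, pairs with zero total evidence are returned
#'   as `NA` (a masked RDM) instead of raising an error.
#' @return an `rdm`. With `allow_missing = TRUE` the values may contain `NA`
#'   at zero-evidence pairs.
#' @export
average_rdms <- function(rdms, allow_missing = FALSE) {
  stopifnot(is.list(rdms), length(rdms) >= 1L)
  n <- rdms[[1L]]$n_items
  if (!all(vapply(rdms, function(r) r$n_items, 1L) == n))
    stop("all RDMs must share n_items")
  wsum <- Reduce(`+`, lapply(rdms, function(r) r$evidence))
  vsum <- Reduce(`+`, lapply(rdms, function(r) {
    v <- r$values * r$evidence
    v[r$evidence == 0] <- 0
    v
  }))
  miss <- wsum == 0
  if (any(miss) && !allow_missing)
    stop(sprintf("%d pair(s) have zero total evidence (first: pair %d); %s",
                 sum(miss), which(miss)[1L],
                 "use allow_missing = TRUE for a masked average"))
  vals <- vsum / wsum
  vals[miss] <- NA_real_
  out <- make_rdm(ifelse(miss, 0, vals), n, evidence = wsum,
                  metric_tag = rdms[[1L]]$metric_tag)
  out$values[miss] <- NA_real_
  out
}

#' Variance inflation factors of a predictor matrix
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column `j` on
#' all other columns (with intercept). Values near 1 indicate no collinearity.
#'
#' @param predictors numeric matrix (observations x predictors), `p >= 2`,
#'   no constant columns.
#' @return numeric vector of VIFs (named if the matrix has column names);
#'   perfectly collinear columns yield `Inf` with a warning.
#' @export
variance_inflation_factors <- function(predictors) {
  predictors <- as.matrix(predictors)
  p <- ncol(predictors)
  if (p < 2L) stop("need at least two predictors")
  if (any(apply(predictors, 2L, sd) == 0))
    stop("constant predictor column")
  vifs <- vapply(seq_len(p), function(j) {
    yj <- predictors[, j]
    fit <- lm.fit(cbind(1, predictors[, -j, drop = FALSE]), yj)
    r2 <- 1 - sum(fit$residuals^2) / sum((yj - mean(yj))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 1.0)
  if (any(is.infinite(vifs)))
    warning("perfectly collinear predictor column(s): infinite VIF")
  names(vifs) <- colnames(predictors)
  vifs
}
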