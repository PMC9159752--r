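#' Create a feature set
#'
#' A `feature_set` groups item-level feature value matrices with the metadata
#' the downstream analyses need: each feature carries a group tag (`visual`,
#' `action`, `social-affective`) and a provenance (`rating`, `annotation`,
#' `embedding`, `image-statistic`). All features must cover the same items.
#'
#' @param items character or integer vector of item ids.
#' @param features named list; each element a list with fields `values`
#'   (numeric vector or items x dims matrix), `group`, `provenance`, and
#'   optionally `type` (`"numeric"` or `"categorical"`).
#' @return an object of class `feature_set`.
#' @export
feature_set <- function(items, features = list()) {
  items <- as.character(items)
  stopifnot(length(items) >= 2L, !anyDuplicated(items))
  for (nm in names(features)) features[[nm]] <- validate_feature(features[[nm]], nm, length(items))
  structure(list(items = items, features = features), class = "feature_set")
}

validate_feature <- function(f, nm, n_items) {
  if (is.null(f$group) || !f$group %in% c("visual", "action", "social-affective"))
    stop(sprintf("feature '%s' has no valid group tag", nm))
  if (is.null(f$provenance))
    f$provenance <- "annotation"
  if (is.null(f$type)) f$type <- "numeric"
  if (f$type == "categorical") {
    if (length(f$values) != n_items)
      stop(sprintf("feature '%s' does not cover the item set", nm))
  } else {
    f$values <- as.matrix(f$values)
    if (nrow(f$values) != n_items)
      stop(sprintf("feature '%s' does not cover the item set", nm))
  }
  f
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d items, %d features\n",
              length(x$items), length(x$features)))
  for (nm in names(x$features)) {
    f <- x$features[[nm]]
    cat(sprintf("  %-14s group=%-16s provenance=%s\n", nm, f$group, f$provenance))
  }
  invisible(x)
}

#' Add a feature to a feature set
#'
#' @param fs a `feature_set`.
#' @param name feature name.
#' @param values numeric vector/matrix over items, or labels for
#'   `type = "categorical"`.
#' @param group group tag.
#' @param provenance provenance tag.
#' @param type `"numeric"` or `"categorical"`.
#' @return the updated `feature_set`.
#' @export
add_feature <- function(fs, name, values, group,
                        provenance = "annotation", type = "numeric") {
  stopifnot(inherits(fs, "feature_set"))
  fs$features[[name]] <- validate_feature(
    list(values = values, group = group, provenance = provenance, type = type),
    name, length(fs$items))
  fs
}

# ---- rating tables ---------------------------------------------------------

#' Validate a long-format rating table
#'
#' Ratings are integers on a 1-5 scale; each (rater, item, feature) appears at
#' most once. `catch_pass` records whether the rater answered all catch trials
#' correctly (constant within rater).
#'
#' @param table data.frame with columns `rater`, `item`, `feature`, `rating`,
#'   `catch_pass`.
#' @return the validated data.frame (invisibly classed `rating_table`).
#' @export
rating_table <- function(table) {
  need <- c("rater", "item", "feature", "rating", "catch_pass")
  if (!all(need %in% names(table)))
    stop("rating table needs columns: ", paste(need, collapse = ", "))
  if (nrow(table) == 0L) stop("rating table is empty")
  if (!all(table$rating %in% 1:5))
    stop("ratings must be integers in 1..5")
  key <- paste(table$rater, table$item, table$feature)
  if (anyDuplicated(key))
    stop("duplicate (rater, item, feature) entries")
  class(table) <- c("rating_table", "data.frame")
  table
}

#' Exclude unreliable raters
#'
#' Removes raters who failed any catch trial, or whose ratings are overly
#' repetitive: fewer than `min_unique` unique rating values across their whole
#' session (a rater using only two unique values or fewer out of five is
#' dropped under the default `min_unique = 3`).
#'
#' @param table a `rating_table`.
#' @param min_unique minimum number of distinct rating values a retained
#'   rater must have used.
#' @return the filtered table with attribute `"exclusions"`: a data.frame of
#'   excluded raters and reasons.
#' @export
exclude_raters <- function(table, min_unique = 3L) {
  table <- rating_table(table)
  by_rater <- split(table, table$rater)
  reasons <- lapply(names(by_rater), function(r) {
    tr <- by_rater[[r]]
    why <- character(0)
    if (!all(tr$catch_pass)) why <- c(why, "catch_fail")
    if (length(unique(tr$rating)) <= min_unique - 1L)
      why <- c(why, "repetitive_ratings")
    if (length(why)) data.frame(rater = r, reason = paste(why, collapse = "+")) else NULL
  })
  log <- do.call(rbind, reasons)
  keep_raters <- setdiff(names(by_rater), if (is.null(log)) character(0) else log$rater)
  if (length(keep_raters) == 0L)
    stop("all raters excluded")
  out <- table[table$rater %in% keep_raters, , drop = FALSE]
  class(out) <- c("rating_table", "data.frame")
  attr(out, "exclusions") <-
    if (is.null(log)) data.frame(rater = character(0), reason = character(0)) else log
  out
}

#' Aggregate ratings to per-item feature means
#'
#' Optionally z-scores each rater's ratings (within rater and feature, across
#' the items they rated) to remove rater-specific scale use, then averages
#' across raters per item and feature.
#'
#' @param table a `rating_table` (exclusions already applied).
#' @param zscore z-score per rater before averaging?
#' @return a list with `means` (items x features matrix) and `n_raters`
#'   (same shape, rater counts per cell). Errors if any item has zero ratings
#'   for some feature.
#' @export
aggregate_ratings <- function(table, zscore = FALSE) {
  table <- rating_table(table)
  x <- as.numeric(table$rating)
  if (zscore) {
    g <- interaction(table$rater, table$feature, drop = TRUE)
    mu <- ave(x, g, FUN = mean)
    sdev <- ave(x, g, FUN = sd)
    sdev[is.na(sdev) | sdev == 0] <- 1
    x <- (x - mu) / sdev
  }
  items <- sort(unique(as.character(table$item)))
  feats <- sort(unique(as.character(table$feature)))
  fi <- factor(as.character(table$item), levels = items)
  ff <- factor(as.character(table$feature), levels = feats)
  means <- tapply(x, list(fi, ff), mean)
  counts <- tapply(x, list(fi, ff), length)
  counts[is.na(counts)] <- 0
  if (anyNA(means))
    stop("item(s) with zero ratings for some feature")
  list(means = means, n_raters = counts)
}

#' Split-half reliability of rated features
#'
#' For each feature, raters are randomly split into two halves `n_splits`
#' times; the Spearman correlation between the two halves' item-mean vectors
#' estimates that feature's reliability. Features with any item rated by a
#' single rater only are excluded with a warning.
#'
#' @param table a `rating_table`.
#' @param n_splits number of random splits.
#' @param seed RNG seed.
#' @return a list per feature of split correlations, plus a `summary`
#'   data.frame (feature, mean, sd).
#' @export
rating_reliability <- function(table, n_splits = 100L, seed = 1L) {
  table <- rating_table(table)
  set.seed(seed)
  feats <- sort(unique(as.character(table$feature)))
  out <- list()
  for (f in feats) {
    tf <- table[table$feature == f, , drop = FALSE]
    raters <- unique(as.character(tf$rater))
    per_item <- table(as.character(tf$item))
    if (length(raters) < 2L || any(per_item < 2L)) {
      warning(sprintf("feature '%s' has items with < 2 raters; excluded", f))
      next
    }
    items <- sort(unique(as.character(tf$item)))
    rs <- vapply(seq_len(n_splits), function(s) {
      half <- sample(raters, floor(length(raters) / 2))
      a <- tf[tf$rater %in% half, ]
      b <- tf[!tf$rater %in% half, ]
      ma <- tapply(a$rating, factor(as.character(a$item), levels = items), mean)
      mb <- tapply(b$rating, factor(as.character(b$item), levels = items), mean)
      ok <- complete.cases(ma, mb)
      if (sum(ok) < 3L) return(NA_real_)
      cor(ma[ok], mb[ok], method = "spearman")
    }, 1.0)
    out[[f]] <- rs
  }
  if (length(out) == 0L) stop("no feature with enough raters")
  summ <- data.frame(feature = names(out),
                     mean = vapply(out, mean, 1.0, na.rm = TRUE),
                     sd = vapply(out, sd, 1.0, na.rm = TRUE),
                     row.names = NULL)
  list(splits = out, summary = summ)
}

# ---- image statistics ------------------------------------------------------

#' Mean luminance, hue, and saturation of a frame stack
#'
#' Image statistics are computed per frame and averaged across frames.
#' Luminance is the mean pixel value (mean over RGB channels for color
#' frames). Hue and saturation come from the HSV decomposition; hue is
#' averaged circularly (in degrees) over pixels with nonzero saturation, since
#' hue is undefined for achromatic pixels.
#'
#' @param frames a list of arrays, each `H x W` (grayscale) or `H x W x 3`
#'   (RGB), values in `[0, 1]`.
#' @return named numeric vector `c(luminance, hue, saturation)`; hue is `NA`
#'   for fully achromatic stacks.
#' @export
mean_frame_stats <- function(frames) {
  if (!is.list(frames) || length(frames) < 1L) stop("need at least one frame")
  per <- vapply(frames, function(fr) {
    fr <- as.array(fr)
    if (any(fr < 0) || any(fr > 1)) stop("pixel values must lie in [0, 1]")
    if (length(dim(fr)) == 2L) {
      c(lum = mean(fr), hx = NA_real_, hy = NA_real_, sat = 0)
    } else if (length(dim(fr)) == 3L && dim(fr)[3L] == 3L) {
      rgb <- matrix(fr, ncol = 3L)
      hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 1)
      h <- hsv[1L, ] * 360; s <- hsv[2L, ]
      chrom <- s > 0
      if (any(chrom)) {
        hx <- mean(cos(h[chrom] * pi / 180))
        hy <- mean(sin(h[chrom] * pi / 180))
      } else {
        hx <- NA_real_; hy <- NA_real_
      }
      c(lum = mean(rgb), hx = hx, hy = hy, sat = mean(s))
    } else stop("frames must be HxW or HxWx3 arrays")
  }, c(lum = 1.0, hx = 1.0, hy = 1.0, sat = 1.0))
  hx <- mean(per["hx", ], na.rm = TRUE)
  hy <- mean(per["hy", ], na.rm = TRUE)
  hue <- if (is.nan(hx) || is.nan(hy)) NA_real_ else (atan2(hy, hx) * 180 / pi) %% 360
  c(luminance = mean(per["lum", ]), hue = hue, saturation = mean(per["sat", ]))
}

#' Horn-Schunck optic flow between two frames
#'
#' The classic global variational estimator: brightness constancy plus an
#' `alpha^2`-weighted smoothness penalty, solved by Jacobi-style iterations in
#' which the flow at each pixel is pulled toward the local average and
#' corrected along the image gradient. Returns the dense flow field and its
#' mean magnitude in pixels/frame.
#'
#' @param frame_a,frame_b grayscale matrices of equal size, values in `[0, 1]`.
#' @param alpha smoothness weight (default 1).
#' @param n_iter number of iterations (default 100).
#' @return list with `u`, `v` (flow components) and `mean_magnitude`.
#' @export
horn_schunck_flow <- function(frame_a, frame_b, alpha = 1.0, n_iter = 100L) {
  a <- as.matrix(frame_a); b <- as.matrix(frame_b)
  if (!all(dim(a) == dim(b))) stop("frame shapes differ")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  sh <- function(m, dr, dc) { # shift with replicated borders
    nr <- nrow(m); nc <- ncol(m)
    r <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    c <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[r, c, drop = FALSE]
  }
  # Horn & Schunck forward-difference derivative estimates over the 2x2x2 cube
  ex <- (sh(a, 0, 1) - a + sh(b, 0, 1) - b +
           sh(a, 1, 1) - sh(a, 1, 0) + sh(b, 1, 1) - sh(b, 1, 0)) / 4
  ey <- (sh(a, 1, 0) - a + sh(b, 1, 0) - b +
           sh(a, 1, 1) - sh(a, 0, 1) + sh(b, 1, 1) - sh(b, 0, 1)) / 4
  et <- (b - a + sh(b, 0, 1) - sh(a, 0, 1) +
           sh(b, 1, 0) - sh(a, 1, 0) + sh(b, 1, 1) - sh(a, 1, 1)) / 4
  u <- matrix(0, nrow(a), ncol(a)); v <- u
  lap <- function(m) { # HS weighted neighborhood average
    (sh(m, -1, 0) + sh(m, 1, 0) + sh(m, 0, -1) + sh(m, 0, 1)) / 6 +
      (sh(m, -1, -1) + sh(m, -1, 1) + sh(m, 1, -1) + sh(m, 1, 1)) / 12
  }
  denom <- alpha^2 + ex^2 + ey^2
  for (k in seq_len(n_iter)) {
    ub <- lap(u); vb <- lap(v)
    t1 <- (ex * ub + ey * vb + et) / denom
    u <- ub - ex * t1
    v <- vb - ey * t1
  }
  list(u = u, v = v, mean_magnitude = mean(sqrt(u^2 + v^2)))
}

# ---- feature RDM battery ---------------------------------------------------

#' Attach precomputed embedding matrices as visual features
#'
#' Registers externally computed item embeddings (e.g., network-layer
#' activations, scene descriptors, motion-energy features) as visual-group
#' features with provenance `"embedding"`; they enter the battery through
#' Euclidean distances like any other vectorized feature.
#'
#' @param fs a `feature_set`.
#' @param embeddings named list of numeric item x dim matrices (rows must
#'   match the item set size and order).
#' @param group group tag for the embeddings (default `"visual"`).
#' @return the updated `feature_set`.
#' @export
attach_embeddings <- function(fs, embeddings, group = "visual") {
  stopifnot(inherits(fs, "feature_set"))
  for (nm in names(embeddings)) {
    m <- as.matrix(embeddings[[nm]])
    if (nrow(m) != length(fs$items))
      stop(sprintf("embedding '%s' has %d rows; item set has %d",
                   nm, nrow(m), length(fs$items)))
    fs <- add_feature(fs, nm, m, group = group, provenance = "embedding")
  }
  fs
}

#' Build the battery of feature RDMs
#'
#' Numeric features (ratings, annotations, embeddings, image statistics) yield
#' Euclidean-distance RDMs; categorical features (e.g., activity category)
#' yield binary same/different RDMs. Every RDM inherits its feature's group
#' tag.
#'
#' @param fs a `feature_set`.
#' @return named list of `rdm` objects, each with attributes `group` and
#'   `provenance`.
#' @export
build_feature_rdms <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  if (length(fs$features) == 0L) stop("feature set is empty")
  out <- lapply(names(fs$features), function(nm) {
    f <- fs$features[[nm]]
    r <- if (f$type == "categorical") categorical_rdm(f$values)
         else euclidean_rdm(f$values)
    attr(r, "group") <- f$group
    attr(r, "provenance") <- f$provenance
    r
  })
  names(out) <- names(fs$features)
  out
}

#' Pairwise tau-a intercorrelations between feature RDMs
#'
#' @param rdms named list of `rdm` objects over the same items.
#' @return symmetric matrix of Kendall tau-a values with unit diagonal.
#' @export
feature_intercorrelations <- function(rdms) {
  stopifnot(length(rdms) >= 2L)
  n <- rdms[[1L]]$n_items
  if (!all(vapply(rdms, function(r) r$n_items, 1L) == n))
    stop("RDMs differ in n_items")
  k <- length(rdms)
  m <- diag(1, k)
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    t <- tau_a(rdms[[a]]$values, rdms[[b]]$values)
    m[a, b] <- t; m[b, a] <- t
  }
  dimnames(m) <- list(names(rdms), names(rdms))
  m
}
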