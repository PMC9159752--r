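#' Write an RDM to its pair-list CSV format
#'
#' Format: a two-line metadata header (`n_items,metric_tag` and its values),
#' then one row per pair: `i,j,value,evidence` with 1-based `i < j` in
#' condensed order.
#'
#' @param rdm an `rdm`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rdm_csv <- function(rdm, path) {
  stopifnot(inherits(rdm, "rdm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("n_items,metric_tag",
               sprintf("%d,%s", rdm$n_items, rdm$metric_tag),
               "i,j,value,evidence"), con)
  p <- all_pairs(rdm$n_items)
  utils::write.table(
    data.frame(i = p[, 1L], j = p[, 2L],
               value = sprintf("%.17g", rdm$values),
               evidence = sprintf("%.17g", rdm$evidence)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an RDM from the pair-list CSV format
#'
#' @param path file written by [write_rdm_csv()].
#' @return an `rdm`.
#' @export
read_rdm_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L || lines[1L] != "n_items,metric_tag")
    stop(sprintf("malformed RDM file '%s': expected 'n_items,metric_tag' on line 1", path))
  meta <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  if (length(meta) != 2L)
    stop(sprintf("malformed RDM file '%s': line 2 must hold n_items and metric_tag", path))
  n <- as.integer(meta[1L])
  if (lines[3L] != "i,j,value,evidence")
    stop(sprintf("malformed RDM file '%s': expected pair header on line 3", path))
  df <- utils::read.csv(text = lines[-(1:3)], header = FALSE,
                        col.names = c("i", "j", "value", "evidence"))
  if (nrow(df) != n_pairs(n))
    stop(sprintf("malformed RDM file '%s': %d pair rows, expected %d",
                 path, nrow(df), n_pairs(n)))
  if (any(df$i >= df$j)) stop(sprintf("malformed RDM file '%s': need i < j", path))
  k <- condensed_index(df$i, df$j, n)
  vals <- numeric(n_pairs(n)); ev <- numeric(n_pairs(n))
  vals[k] <- df$value; ev[k] <- df$evidence
  make_rdm(vals, n, evidence = ev, metric_tag = meta[2L])
}

#' Export an RDM as a square dissimilarity matrix CSV
#'
#' @param rdm an `rdm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rdm_square <- function(rdm, path) {
  stopifnot(inherits(rdm, "rdm"))
  n <- rdm$n_items
  m <- matrix(0, n, n)
  p <- all_pairs(n)
  m[p] <- rdm$values
  m[p[, c(2L, 1L)]] <- rdm$values
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Import an RDM from a square dissimilarity matrix CSV
#'
#' @param path CSV holding an `n x n` numeric matrix.
#' @param tol symmetry tolerance (default 1e-9).
#' @param metric_tag tag for the resulting `rdm`.
#' @return an `rdm`.
#' @export
read_rdm_square <- function(path, tol = 1e-9, metric_tag = "other") {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  if (nrow(m) != ncol(m)) stop("matrix is not square")
  if (max(abs(m - t(m))) > tol) stop("matrix is not symmetric within tolerance")
  m <- (m + t(m)) / 2
  make_rdm(m[lower.tri(m)], nrow(m), metric_tag = metric_tag)
}

#' Write an arrangement session file
#'
#' One record per trial: trial index, global item id, and disk coordinates
#' in `[-1, 1]`; a metadata block (lines starting `#`) records the item set,
#' criterion, trial cap, and budget.
#'
#' @param session an `arrangement_session`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "arrangement_session"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_total=%d", session$n_total),
               sprintf("# item_ids=%s", paste(session$item_ids, collapse = " ")),
               sprintf("# criterion=%.17g", session$criterion),
               sprintf("# max_trial_size=%d", session$max_trial_size),
               sprintf("# trial_budget=%d", session$trial_budget),
               "trial,item,x,y"), con)
  for (t in seq_along(session$trials)) {
    tr <- session$trials[[t]]
    utils::write.table(
      data.frame(trial = t, item = session$item_ids[tr$subset],
                 x = sprintf("%.17g", tr$coords[, 1L]),
                 y = sprintf("%.17g", tr$coords[, 2L])),
      con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an arrangement session file
#'
#' Rebuilds the session (including accumulated evidence, by replaying the
#' trials) from the format of [write_session()]. Degenerate 2-item trials
#' are preserved with a warning.
#'
#' @param path session file path.
#' @return an `arrangement_session`.
#' @export
read_session <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, "="), meta_lines, value = TRUE)
    if (length(hit) != 1L) stop(sprintf("malformed session file '%s': missing %s", path, key))
    sub(paste0("^# ", key, "="), "", hit)
  }
  n_total <- as.integer(get_meta("n_total"))
  item_ids <- as.integer(strsplit(get_meta("item_ids"), " ")[[1L]])
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 1L || body[1L] != "trial,item,x,y")
    stop(sprintf("malformed session file '%s': missing trial header", path))
  df <- utils::read.csv(text = body[-1L], header = FALSE,
                        col.names = c("trial", "item", "x", "y"))
  s <- new_session(item_ids, n_total = n_total,
                   criterion = as.numeric(get_meta("criterion")),
                   max_trial_size = as.integer(get_meta("max_trial_size")),
                   trial_budget = as.integer(get_meta("trial_budget")))
  for (t in sort(unique(df$trial))) {
    rows <- df[df$trial == t, , drop = FALSE]
    if (nrow(rows) == 2L)
      warning(sprintf("trial %d has only 2 items; preserved", t))
    tr <- structure(list(subset = match(rows$item, item_ids),
                         coords = cbind(rows$x, rows$y)),
                    class = "arrangement_trial")
    s <- update_evidence(tr, s)
  }
  s
}

#' Write an epoch set to a delimited text file
#'
#' A metadata block (lines starting `#`: fs, window, dimensions, labels)
#' followed by one row per (trial, channel): `trial,channel,<t1>,...,<tT>`.
#'
#' @param epochs an `epoch_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.17g", epochs$fs),
               sprintf("# window=%.17g %.17g", epochs$window[1L], epochs$window[2L]),
               sprintf("# dims=%d %d %d", d[1L], d[2L], d[3L]),
               sprintf("# labels=%s", paste(epochs$labels, collapse = " "))), con)
  for (tr in seq_len(d[1L])) {
    m <- matrix(epochs$data[tr, , ], d[2L], d[3L])
    utils::write.table(
      cbind(tr, seq_len(d[2L]), format(m, digits = 17, trim = TRUE)),
      con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param path file path.
#' @return an `epoch_set` (label order preserved).
#' @export
read_epochs <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(hit) != 1L) stop(sprintf("malformed epochs file '%s': missing %s", path, key))
    sub(paste0("^# ", key, "="), "", hit)
  }
  fs <- as.numeric(get_meta("fs"))
  window <- as.numeric(strsplit(get_meta("window"), " ")[[1L]])
  d <- as.integer(strsplit(get_meta("dims"), " ")[[1L]])
  labels <- strsplit(get_meta("labels"), " ")[[1L]]
  suppressWarnings({
    num <- as.numeric(labels)
    if (!anyNA(num)) labels <- num
  })
  df <- utils::read.csv(text = lines[!grepl("^#", lines)], header = FALSE)
  data <- array(0, d)
  for (r in seq_len(nrow(df)))
    data[df[r, 1L], df[r, 2L], ] <- as.numeric(df[r, -(1:2)])
  epoch_set(data, labels, fs, window)
}
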