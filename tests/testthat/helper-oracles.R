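# Independent oracles and fixture builders shared across tests.

# Brute-force Kendall tau-a: explicit double loop over all entry pairs,
# counting concordant/discordant sign products (ties neither).
tau_a_bruteforce <- function(x, y) {
  m <- length(x)
  cd <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      cd <- cd + s
    }
  }
  cd / (m * (m - 1) / 2)
}

# tau-a via the tau-b identity: tau_b * sqrt((n0-n1)(n0-n2)) / n0, a second
# independent route through stats::cor.
tau_a_from_taub <- function(x, y) {
  m <- length(x)
  n0 <- m * (m - 1) / 2
  tie_term <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_term(x); n2 <- tie_term(y)
  if (n0 - n1 == 0 || n0 - n2 == 0) return(0)
  tb <- cor(x, y, method = "kendall")
  tb * sqrt((n0 - n1) * (n0 - n2)) / n0
}

random_rdm <- function(n_items, evidence = NULL) {
  make_rdm(runif(n_pairs(n_items)), n_items, evidence = evidence)
}

# Minimal rating table builder.
ratings_of <- function(raters, items, feature = "f", fun, catch_pass = TRUE) {
  rows <- list()
  for (r in seq_along(raters)) {
    rows[[r]] <- data.frame(rater = raters[r], item = items, feature = feature,
                            rating = fun(r), catch_pass = catch_pass[[min(r, length(catch_pass))]])
  }
  do.call(rbind, rows)
}
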