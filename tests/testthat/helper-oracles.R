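# Independent brute-force / closed-form oracles used to check the package's
# statistical primitives. These deliberately re-derive each quantity from
# first principles rather than calling the implementation under test.

# step-up BH by direct application of the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, clipped at 1, mapped back to input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# hypergeometric upper tail by combinatorial counting:
# P(overlap >= k) when |B| items are drawn without replacement from a universe
# of size n containing |A| marked items
oracle_hyper_upper <- function(k, n_a, n_b, n) {
  js <- max(k, 0):min(n_a, n_b)
  sum(choose(n_a, js) * choose(n - n_a, n_b - js)) / choose(n, n_b)
}

# same tail by exhaustive enumeration of every draw (tiny universes only)
oracle_hyper_enum <- function(set_a, set_b, universe) {
  draws <- utils::combn(length(universe), length(set_b))
  k_obs <- length(intersect(set_a, set_b))
  a_idx <- which(universe %in% set_a)
  mean(apply(draws, 2, function(d) sum(d %in% a_idx) >= k_obs))
}

# two-sided exact rank-sum p by enumeration of all rank assignments,
# doubling the smaller tail (capped at 1), matching the exact-test convention
oracle_ranksum_exact <- function(a, b) {
  n <- length(a) + length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  assign_a <- utils::combn(n, length(a))
  ws <- apply(assign_a, 2, function(idx) {
    sum(seq_len(n)[idx]) - length(a) * (length(a) + 1) / 2
  })
  lower <- mean(ws <= w_obs)
  upper <- mean(ws >= w_obs)
  min(1, 2 * min(lower, upper))
}

# pooled-variance two-sample t-test from the textbook formulas
oracle_t_pooled <- function(x, y, alternative = "two.sided") {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  switch(alternative,
    two.sided = 2 * stats::pt(-abs(tstat), df),
    less = stats::pt(tstat, df),
    greater = stats::pt(tstat, df, lower.tail = FALSE)
  )
}

# exact binomial upper tail by summing the pmf
oracle_binom_upper <- function(k, n, p) {
  ks <- k:n
  sum(choose(n, ks) * p^ks * (1 - p)^(n - ks))
}

# fine-grid trapezoid AUC of a logistic curve (refinement oracle)
oracle_logistic_auc <- function(k, od0, r, lag, duration, dt = 0.001) {
  t <- seq(0, duration, by = dt)
  y <- k / (1 + ((k - od0) / od0) * exp(-r * (t - lag)))
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

# small toy plate pair in long format: `sizes` is a named list
# strain -> c(no_drug, drug); each strain gets a 2x2 block
toy_plate_pair <- function(sizes, replicate = 1L) {
  strains <- names(sizes)
  n <- length(strains)
  ncols <- ceiling(sqrt(n))
  rows <- list()
  for (i in seq_len(n)) {
    br <- (i - 1) %/% ncols
    bc <- (i - 1) %% ncols
    for (cond_i in 1:2) {
      cond <- c("no_drug", "drug")[cond_i]
      rows[[length(rows) + 1]] <- tibble::tibble(
        plate_id = paste0("p1_", cond, "_r", replicate),
        condition = cond,
        replicate = replicate,
        row = br * 2 + rep(1:2, each = 2),
        col = bc * 2 + rep(1:2, times = 2),
        strain_id = strains[i],
        size = sizes[[i]][cond_i]
      )
    }
  }
  dplyr::bind_rows(rows)
}
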