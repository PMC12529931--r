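## Independent brute-force oracles. These deliberately re-derive each
## quantity from its definition with naive code, so they share no logic
## with the production path they check.

## mixture log-likelihood, one read at a time, no vectorization
oracle_grid_loglik <- function(hist, p_err, p_new, grid) {
  ll <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    p <- grid[gi]
    acc <- 0
    for (r in seq_len(nrow(hist))) {
      dens <- (1 - p) * dbinom(hist$k[r], hist$n[r], p_err) +
        p * dbinom(hist$k[r], hist$n[r], p_new)
      acc <- acc + hist$count[r] * log(dens)
    }
    ll[gi] <- acc
  }
  ll
}

## literal median-of-ratios definition
oracle_size_factors <- function(counts) {
  keep <- apply(counts > 0, 1, all)
  sub <- counts[keep, , drop = FALSE]
  geo <- apply(sub, 1, function(r) prod(r)^(1 / length(r)))
  sf <- apply(sub, 2, function(col) median(col / geo))
  sf / prod(sf)^(1 / length(sf))
}

## literal BH step-up: q_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

## one-sided hypergeometric upper tail for the 2x2 table
## [x11, x12 ; x21, x22], P(X >= x11) with margins fixed
oracle_fisher_greater <- function(x11, x12, x21, x22) {
  K <- x11 + x21        # total non-converted
  n <- x11 + x12        # site reads
  N <- x11 + x12 + x21 + x22
  xs <- x11:min(K, n)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

## rank-then-Pearson Spearman
oracle_spearman <- function(x, y) cor(rank(x), rank(y))
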