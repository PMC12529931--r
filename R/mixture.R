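#' Estimate the background T-to-C conversion rate from unlabeled controls
#'
#' Pools all reads of one or more unlabeled control samples and returns the
#' overall conversion frequency, total conversions over total uridine
#' positions. Unlabeled cells carry no 4sU, so this frequency measures the
#' combined sequencing-error and chemistry background `p_err`.
#'
#' @param control a `conversion_sample`, a histogram data.frame
#'   (gene, n, k, count), or a list of either.
#' @param floor value returned (with a warning) when no conversion is
#'   observed at all; the mixture likelihood needs `p_err > 0`.
#' @return background conversion probability.
#' @export
estimate_error_rate <- function(control, floor = 1e-6) {
  h <- pool_histograms(control)
  total_u <- sum(as.numeric(h$n) * h$count)
  if (total_u == 0) stop("no informative uridine positions in control data",
                         call. = FALSE)
  total_k <- sum(as.numeric(h$k) * h$count)
  if (total_k == 0) {
    warning("no conversions observed in control; returning floor ", floor)
    return(floor)
  }
  total_k / total_u
}

## accept a conversion_sample, a raw histogram data.frame, or a list of them
pool_histograms <- function(x) {
  if (inherits(x, "conversion_sample")) return(x$histogram)
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, pool_histograms))
}

#' Estimate the labeled-read conversion rate by EM
#'
#' Fits the two-component binomial mixture
#' `w * Binom(k; n, p_new) + (1 - w) * Binom(k; n, p_err)` to all pooled
#' reads of labeled samples, with the background rate `p_err` held fixed and
#' the new-read conversion rate `p_new` and global mixing weight `w` free.
#' Standard EM: responsibilities in the E-step, weighted conversion
#' frequency of the "new" component in the M-step; the observed-data
#' log-likelihood is non-decreasing across iterations.
#'
#' @param labeled labeled conversion data (same forms as
#'   [estimate_error_rate()]).
#' @param p_err fixed background conversion rate.
#' @param init_p_new,init_weight starting values.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap.
#' @return estimated `p_new`, with attributes `weight` (mixing proportion),
#'   `loglik` (per-iteration trace) and `iterations`.
#' @export
estimate_conversion_rate <- function(labeled, p_err,
                                     init_p_new = 10 * p_err,
                                     init_weight = 0.5,
                                     tol = 1e-8, max_iter = 500) {
  h <- pool_histograms(labeled)
  ## collapse to unique (n, k) cells; counts are the sufficient statistic
  key <- paste(h$n, h$k)
  agg <- rowsum(h$count, key)
  nk <- do.call(rbind, strsplit(rownames(agg), " "))
  n <- as.numeric(nk[, 1]); k <- as.numeric(nk[, 2]); cnt <- as.numeric(agg)
  if (all(k == 0))
    stop("no converted reads; p_new is unidentifiable", call. = FALSE)
  p_new <- init_p_new; w <- init_weight
  ll <- numeric(0)
  f0 <- dbinom(k, n, p_err)
  for (it in seq_len(max_iter)) {
    f1 <- dbinom(k, n, p_new)
    mix <- w * f1 + (1 - w) * f0
    ll[it] <- sum(cnt * log(mix))
    r <- w * f1 / mix
    w <- sum(cnt * r) / sum(cnt)
    p_new <- sum(cnt * r * k) / sum(cnt * r * n)
    p_new <- min(max(p_new, p_err * (1 + 1e-9)), 1 - 1e-12)
    if (it > 1 && abs(ll[it] - ll[it - 1]) < tol) break
  }
  structure(p_new, weight = w, loglik = ll, iterations = length(ll))
}

#' Global conversion rates for the mixture likelihood
#'
#' @param p_err background T-to-C rate.
#' @param p_new new-RNA T-to-C rate; must exceed `p_err`.
#' @return object of class `global_rates`.
#' @export
global_rates <- function(p_err, p_new) {
  stopifnot_prob(p_err, "p_err")
  stopifnot_prob(p_new, "p_new")
  if (p_new <= p_err) stop("'p_new' must exceed 'p_err'", call. = FALSE)
  structure(list(p_err = p_err, p_new = as.numeric(p_new)),
            class = "global_rates")
}

#' Per-gene new-to-total ratio posterior from a conversion histogram
#'
#' Evaluates the mixture likelihood
#' `L(pi) = prod_reads [ (1 - pi) Binom(k; n, p_err) + pi Binom(k; n, p_new) ]`
#' in log space on a uniform grid over [0, 1] under a flat prior, and
#' returns the MAP (ties resolved to the smallest grid value), the
#' normalized grid posterior, and a moment-matched Beta(alpha, beta)
#' summary used downstream for Monte Carlo propagation.
#'
#' @param hist histogram data.frame (n, k, count; a `gene` column is carried
#'   through if present) for a single gene.
#' @param rates a [global_rates()] object.
#' @param grid_size number of grid points (default 1000).
#' @param min_reads genes with fewer informative reads are flagged
#'   `insufficient` and return an all-NA estimate.
#' @return object of class `ntr_estimate`: list with `gene`, `pi_map`,
#'   `grid`, `posterior` (densities integrating to 1 over [0, 1]),
#'   `log_lik` (grid log-likelihood), `alpha`, `beta`, `mean`, `n_reads`,
#'   `insufficient`.
#' @export
estimate_ntr <- function(hist, rates, grid_size = 1000, min_reads = 10) {
  stopifnot(inherits(rates, "global_rates"))
  gene <- if (!is.null(hist$gene)) hist$gene[1] else NA_character_
  n_reads <- sum(hist$count)
  if (n_reads < min_reads) {
    return(structure(list(gene = gene, pi_map = NA_real_, grid = NULL,
                          posterior = NULL, log_lik = NULL,
                          alpha = NA_real_, beta = NA_real_, mean = NA_real_,
                          n_reads = n_reads, insufficient = TRUE),
                     class = "ntr_estimate"))
  }
  grid <- seq(0, 1, length.out = grid_size)
  ll <- ntr_grid_loglik(hist, rates, grid)
  w <- exp(ll - max(ll))
  dx <- grid[2] - grid[1]
  dens <- w / (sum(w) * dx)
  prob <- w / sum(w)
  m <- sum(grid * prob)
  v <- sum((grid - m)^2 * prob)
  ab <- beta_moments(m, v)
  structure(list(gene = gene, pi_map = grid[which.max(ll)], grid = grid,
                 posterior = dens, log_lik = ll,
                 alpha = ab[1], beta = ab[2], mean = m,
                 n_reads = n_reads, insufficient = FALSE),
            class = "ntr_estimate")
}

## grid log-likelihood of the two-component mixture for one gene
ntr_grid_loglik <- function(hist, rates, grid) {
  f0 <- dbinom(hist$k, hist$n, rates$p_err)
  f1 <- dbinom(hist$k, hist$n, rates$p_new)
  ## grid x entries matrix of per-read log densities, weighted by counts
  m <- log(outer(1 - grid, f0) + outer(grid, f1))
  as.vector(m %*% hist$count)
}

beta_moments <- function(m, v) {
  ## moment match on (0,1); guard the degenerate corners
  m <- min(max(m, 1e-12), 1 - 1e-12)
  v <- min(max(v, 1e-12), m * (1 - m) * (1 - 1e-9))
  s <- m * (1 - m) / v - 1
  c(alpha = m * s, beta = (1 - m) * s)
}

#' @export
print.ntr_estimate <- function(x, ...) {
  if (x$insufficient) {
    cat("ntr_estimate", x$gene, ": insufficient reads (", x$n_reads, ")\n")
  } else {
    ci <- c(ntr_posterior_quantile(x, 0.05), ntr_posterior_quantile(x, 0.95))
    cat(sprintf("ntr_estimate %s: MAP %.4f (90%% CI %.4f-%.4f), %d reads\n",
                x$gene, x$pi_map, ci[1], ci[2], x$n_reads))
  }
  invisible(x)
}

#' Quantile of a stored NTR posterior
#'
#' Linear interpolation of the grid posterior's cumulative distribution;
#' monotone in `q`.
#'
#' @param est an [estimate_ntr()] result.
#' @param q quantile level(s) in (0, 1).
#' @return value(s) in [0, 1].
#' @export
ntr_posterior_quantile <- function(est, q) {
  stopifnot(inherits(est, "ntr_estimate"))
  if (any(q <= 0 | q >= 1)) stop("'q' must lie in (0, 1)", call. = FALSE)
  if (est$insufficient) return(rep(NA_real_, length(q)))
  prob <- est$posterior / sum(est$posterior)
  cdf <- cumsum(prob)
  ## step-free inverse CDF: interpolate between grid midpoints
  stats::approx(x = c(0, cdf), y = c(est$grid[1], est$grid), xout = q,
                ties = "ordered", rule = 2)$y
}

#' Estimate NTR posteriors for every gene of one or more samples
#'
#' @param sample a `conversion_sample` or histogram data.frame with a
#'   `gene` column; a list pools histograms across samples (e.g. replicates
#'   of one condition).
#' @param rates a [global_rates()] object.
#' @param grid_size,min_reads passed to [estimate_ntr()].
#' @return data.frame: gene, n_reads, pi_map, mean, alpha, beta, ci_low,
#'   ci_high (90% equal-tailed), insufficient. The per-gene `ntr_estimate`
#'   objects are attached as attribute `estimates`.
#' @export
estimate_ntr_table <- function(sample, rates, grid_size = 1000, min_reads = 10) {
  h <- pool_histograms(sample)
  split_h <- split(h, h$gene)
  ests <- lapply(split_h, estimate_ntr, rates = rates,
                 grid_size = grid_size, min_reads = min_reads)
  tab <- data.frame(
    gene = names(ests),
    n_reads = vapply(ests, `[[`, 0, "n_reads"),
    pi_map = vapply(ests, `[[`, 0, "pi_map"),
    mean = vapply(ests, `[[`, 0, "mean"),
    alpha = vapply(ests, `[[`, 0, "alpha"),
    beta = vapply(ests, `[[`, 0, "beta"),
    ci_low = vapply(ests, function(e)
      if (e$insufficient) NA_real_ else ntr_posterior_quantile(e, 0.05), 0),
    ci_high = vapply(ests, function(e)
      if (e$insufficient) NA_real_ else ntr_posterior_quantile(e, 0.95), 0),
    insufficient = vapply(ests, `[[`, TRUE, "insufficient"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "estimates") <- ests
  tab
}
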