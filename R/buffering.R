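#' Spearman correlation between half-life and synthesis changes
#'
#' Transcript buffering leaves steady-state abundance constant while
#' half-life and synthesis move in opposite directions; among
#' steady-state-stable genes this shows up as a negative rank correlation
#' between the two log2 fold changes. Rank correlation uses average ranks
#' for ties; the two-sided p-value comes from the t-approximation
#' `t = R sqrt((n - 2) / (1 - R^2))` with `n - 2` degrees of freedom, or
#' from exact enumeration over all rank permutations for `n <= 9`.
#'
#' @param lfc_HL,lfc_S paired per-gene log2 fold changes, or a
#'   [turnover_changes()] table in `lfc_HL` (then restricted to its stable
#'   genes and `lfc_S` is ignored).
#' @param min_n minimum number of complete pairs (default 10; fewer returns
#'   NA with a warning).
#' @return list: `R` (Spearman), `p` (two-sided), `n`, `method`.
#' @export
buffering_correlation <- function(lfc_HL, lfc_S = NULL, min_n = 10) {
  if (inherits(lfc_HL, "turnover_changes")) {
    ch <- lfc_HL[lfc_HL$stable, ]
    lfc_S <- ch$lfc_S
    lfc_HL <- ch$lfc_HL
  }
  ok <- stats::complete.cases(lfc_HL, lfc_S)
  x <- lfc_HL[ok]; y <- lfc_S[ok]
  n <- length(x)
  if (n < min_n) {
    warning("fewer than ", min_n, " complete gene pairs; returning NA")
    return(list(R = NA_real_, p = NA_real_, n = n, method = "none"))
  }
  rx <- rank(x); ry <- rank(y)
  R <- stats::cor(rx, ry)
  if (n <= 9) {
    p <- spearman_exact_p(rx, ry)
    method <- "exact permutation"
  } else {
    tt <- R * sqrt((n - 2) / max(1 - R^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(R = R, p = min(p, 1), n = n, method = method)
}

## exact two-sided permutation p for |rho| on ranks, n <= 9
spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  perms <- e1071::permutations(n)
  obs <- abs(stats::cor(rx, ry))
  rperm <- matrix(ry[perms], nrow = nrow(perms))
  cx <- rx - mean(rx)
  denom <- sqrt(sum(cx^2)) * sqrt(sum((ry - mean(ry))^2))
  rho <- abs((rperm %*% cx) / denom)
  mean(rho >= obs - 1e-12)
}

#' Bootstrap test for a difference of medians
#'
#' Resamples `x` and `y` independently with replacement (their own sizes)
#' `iterations` times, recording `median(y*) - median(x*)`; percentile
#' confidence intervals at 95/99/99.9% and the star label of the smallest
#' level whose interval excludes zero. Genes (the vector elements) are the
#' resampling unit. A `paired` variant resamples index-matched pairs.
#'
#' @param x,y numeric vectors (e.g. per-gene half-lives in two genotypes).
#' @param iterations bootstrap iterations (>= 1000).
#' @param seed RNG seed; results are deterministic given it.
#' @param paired resample matched pairs instead of independent samples
#'   (requires equal lengths).
#' @return object of class `bootstrap_result`: observed difference,
#'   `iterations`, `ci95`, `ci99`, `ci999`, `label`, `seed`.
#' @export
bootstrap_median_difference <- function(x, y, iterations = 20000, seed = 1L,
                                        paired = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("'x' and 'y' must be nonempty", call. = FALSE)
  if (iterations < 1000) stop("need >= 1000 iterations", call. = FALSE)
  if (paired && length(x) != length(y))
    stop("paired resampling needs equal lengths", call. = FALSE)
  nx <- length(x); ny <- length(y)
  diffs <- numeric(iterations)
  with_seed(seed, {
    chunk <- max(1L, min(iterations, floor(2e6 / max(nx, ny))))
    done <- 0L
    while (done < iterations) {
      m <- min(chunk, iterations - done)
      if (paired) {
        idx <- matrix(sample.int(nx, nx * m, replace = TRUE), nrow = nx)
        mx <- apply(matrix(x[idx], nrow = nx), 2, stats::median)
        my <- apply(matrix(y[idx], nrow = nx), 2, stats::median)
      } else {
        mx <- apply(matrix(x[sample.int(nx, nx * m, replace = TRUE)],
                           nrow = nx), 2, stats::median)
        my <- apply(matrix(y[sample.int(ny, ny * m, replace = TRUE)],
                           nrow = ny), 2, stats::median)
      }
      diffs[done + seq_len(m)] <- my - mx
      done <- done + m
    }
  })
  ci <- function(lv) unname(stats::quantile(diffs, c((1 - lv) / 2, 1 - (1 - lv) / 2)))
  res <- structure(list(observed = stats::median(y) - stats::median(x),
                        iterations = iterations,
                        ci95 = ci(0.95), ci99 = ci(0.99), ci999 = ci(0.999),
                        label = NA_character_, seed = seed, paired = paired),
                   class = "bootstrap_result")
  res$label <- significance_stars(res)
  res
}

#' Star label from bootstrap confidence intervals
#'
#' `***` when the 99.9% interval excludes zero, `**` for 99%, `*` for 95%,
#' `ns` otherwise.
#'
#' @param result a [bootstrap_median_difference()] result (or any list with
#'   `ci95`, `ci99`, `ci999`).
#' @return one of `"***"`, `"**"`, `"*"`, `"ns"`.
#' @export
significance_stars <- function(result) {
  excl <- function(ci) ci[1] > 0 || ci[2] < 0
  if (excl(result$ci999)) "***"
  else if (excl(result$ci99)) "**"
  else if (excl(result$ci95)) "*"
  else "ns"
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap median difference: %.4g [%s] (95%% CI %.4g..%.4g, %d iterations%s)\n",
    x$observed, x$label, x$ci95[1], x$ci95[2], x$iterations,
    if (x$paired) ", paired" else ""))
  invisible(x)
}
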