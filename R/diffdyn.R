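#' Log2 fold change with pseudocount
#'
#' @param a,b non-negative baseline and comparison values.
#' @param pseudocount stabilizer added to both; use ~1e-8 for already
#'   positive quantities (half-life, synthesis), 0.5 for counts.
#' @return `log2((b + pseudocount) / (a + pseudocount))`.
#' @export
log2fc <- function(a, b, pseudocount = 1e-8) {
  if (any(a < 0 | b < 0, na.rm = TRUE))
    stop("'a' and 'b' must be non-negative", call. = FALSE)
  log2(b + pseudocount) - log2(a + pseudocount)
}

#' Signed ROPE statistic for a posterior log2 change
#'
#' Propagates two Beta NTR posteriors through the half-life transform by
#' seeded Monte Carlo and returns `P(Delta > w) - P(Delta < -w)` for the
#' posterior of `Delta = log2(HL_B / HL_A)` (metric `"HL"`) or of the
#' synthesis-rate ratio `log2(S_B / S_A) = -Delta + log2(E_B / E_A)`
#' (metric `"S"`, with the abundance ratio supplied as `lfc_E`). Values
#' near +1/-1 mean the change is confidently directional and outside the
#' region of practical equivalence; swapping A and B flips the sign.
#'
#' @param postA,postB Beta posterior summaries: `ntr_estimate` objects or
#'   lists with `alpha` and `beta`.
#' @param params a [labeling_params()] (pulse length and half-life caps).
#' @param w half-width of the region of practical equivalence in log2
#'   units.
#' @param metric `"HL"` or `"S"`.
#' @param lfc_E log2 abundance ratio B/A (used for metric `"S"`).
#' @param n_draws Monte Carlo draws.
#' @param seed optional seed for reproducibility.
#' @return signed statistic in [-1, 1].
#' @export
rope_statistic <- function(postA, postB, params, w = 0.25,
                           metric = c("HL", "S"), lfc_E = 0,
                           n_draws = 1e5, seed = NULL) {
  metric <- match.arg(metric)
  a <- beta_pars(postA); b <- beta_pars(postB)
  if (anyNA(c(a, b))) return(NA_real_)
  with_seed(seed, {
    piA <- stats::rbeta(n_draws, a[1], a[2])
    piB <- stats::rbeta(n_draws, b[1], b[2])
    dhl <- log2(as.numeric(ntr_to_halflife(piB, params))) -
      log2(as.numeric(ntr_to_halflife(piA, params)))
    delta <- if (metric == "HL") dhl else lfc_E - dhl
    mean(delta > w) - mean(delta < -w)
  })
}

beta_pars <- function(p) {
  if (inherits(p, "ntr_estimate")) c(p$alpha, p$beta)
  else c(p$alpha, p$beta)
}

#' Classify per-gene turnover changes
#'
#' A parameter counts as changed when the magnitude of its log2 fold change
#' exceeds `lfc_threshold` AND the magnitude of its ROPE statistic exceeds
#' `rope_threshold` (both gates required); the fold-change sign gives the
#' direction. Genes passing for both half-life and synthesis are
#' `HL_and_S`; genes passing for neither are `none`.
#'
#' @param lfc_HL,rope_HL,lfc_S,rope_S per-gene statistics (vectors).
#' @param lfc_threshold log2 fold-change gate (default 1).
#' @param rope_threshold ROPE gate (default 0.45).
#' @return character vector in
#'   `{HL_up, HL_down, S_up, S_down, HL_and_S, none}`; NA statistics fail
#'   their gate.
#' @export
classify_turnover_change <- function(lfc_HL, rope_HL, lfc_S, rope_S,
                                     lfc_threshold = 1,
                                     rope_threshold = 0.45) {
  gate <- function(lfc, rope)
    !is.na(lfc) & !is.na(rope) &
      abs(lfc) > lfc_threshold & abs(rope) > rope_threshold
  hl <- gate(lfc_HL, rope_HL)
  s <- gate(lfc_S, rope_S)
  out <- rep("none", length(hl))
  out[hl & !s] <- ifelse(lfc_HL[hl & !s] > 0, "HL_up", "HL_down")
  out[s & !hl] <- ifelse(lfc_S[s & !hl] > 0, "S_up", "S_down")
  out[hl & s] <- "HL_and_S"
  out
}

#' Steady-state differential expression (simplified Wald test)
#'
#' Size-factor-normalized log2 counts per gene; Wald-type statistic =
#' difference of condition means over the pooled standard error (variance
#' floored), referred to a Student-t distribution with `nA + nB - 2`
#' degrees of freedom; BH-adjusted q-values. This is a deliberately simple,
#' self-contained test: it does not shrink dispersions or fold changes the
#' way dedicated count-model packages do.
#'
#' @param counts matrix genes x samples (raw counts).
#' @param design data.frame with columns sample, condition.
#' @param condition_a,condition_b the contrast (B vs A).
#' @param factors optional named size factors; computed by [size_factors()]
#'   when NULL.
#' @param var_floor lower bound on the per-gene pooled variance.
#' @return data.frame: gene, lfc_E, stat, de_p, de_q, mean_a, mean_b.
#'   With a single replicate in either condition the p and q are NA.
#' @export
steady_state_de <- function(counts, design, condition_a, condition_b,
                            factors = NULL, var_floor = 1e-8) {
  counts <- as.matrix(counts)
  sa <- design$sample[design$condition == condition_a]
  sb <- design$sample[design$condition == condition_b]
  if (!length(sa) || !length(sb))
    stop("contrast references an undefined condition", call. = FALSE)
  if (is.null(factors)) factors <- size_factors(counts[, c(sa, sb), drop = FALSE])
  y <- log2(sweep(counts[, c(sa, sb), drop = FALSE], 2,
                  factors[c(sa, sb)], "/") + 0.5)
  ya <- y[, sa, drop = FALSE]; yb <- y[, sb, drop = FALSE]
  na <- ncol(ya); nb <- ncol(yb)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  lfc <- mb - ma
  if (na < 2 || nb < 2) {
    p <- rep(NA_real_, nrow(y)); stat <- rep(NA_real_, nrow(y))
  } else {
    va <- apply(ya, 1, stats::var); vb <- apply(yb, 1, stats::var)
    pooled <- pmax(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2), var_floor)
    se <- sqrt(pooled * (1 / na + 1 / nb))
    stat <- lfc / se
    p <- 2 * stats::pt(-abs(stat), df = na + nb - 2)
  }
  data.frame(gene = rownames(y), lfc_E = lfc, stat = stat, de_p = p,
             de_q = if (all(is.na(p))) p else bh_adjust(p),
             mean_a = ma, mean_b = mb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble the per-gene turnover-change table for one contrast
#'
#' Combines condition-level half-life/synthesis estimates, pooled NTR
#' posteriors, and steady-state differential expression into one record per
#' gene: log2 fold changes of HL, S and abundance, signed ROPE statistics,
#' the change class, and a steady-state-stable flag
#' (`|lfc_E| < 1` and `de_q > 0.05`).
#'
#' @param turnover a [quantify()] result covering both conditions.
#' @param posteriors named list (by condition) of [estimate_ntr_table()]
#'   results with Beta summaries (typically from replicate-pooled
#'   histograms).
#' @param de a [steady_state_de()] result for the same contrast.
#' @param condition_a,condition_b the contrast (B vs A).
#' @param params a [labeling_params()].
#' @param lfc_threshold,rope_threshold,rope_width classification gates and
#'   ROPE half-width.
#' @param n_draws,seed Monte Carlo settings for the ROPE propagation.
#' @return data.frame of class `turnover_changes`: gene, contrast, lfc_HL,
#'   rope_HL, lfc_S, rope_S, lfc_E, de_p, de_q, class, stable.
#' @export
turnover_changes <- function(turnover, posteriors, de,
                             condition_a, condition_b, params,
                             lfc_threshold = 1, rope_threshold = 0.45,
                             rope_width = 0.25, n_draws = 1e5, seed = 1L) {
  ta <- turnover[turnover$condition == condition_a, ]
  tb <- turnover[turnover$condition == condition_b, ]
  genes <- intersect(ta$gene, tb$gene)
  ta <- ta[match(genes, ta$gene), ]; tb <- tb[match(genes, tb$gene), ]
  pa <- posteriors[[condition_a]]; pb <- posteriors[[condition_b]]
  ia <- match(genes, pa$gene); ib <- match(genes, pb$gene)
  ide <- match(genes, de$gene)
  lfc_hl <- log2fc(ta$HL_hours, tb$HL_hours)
  lfc_s <- log2fc(ta$S_per_h, tb$S_per_h)
  lfc_e <- de$lfc_E[ide]
  rope_hl <- rope_s <- rep(NA_real_, length(genes))
  with_seed(seed, {
    for (i in seq_along(genes)) {
      if (is.na(ia[i]) || is.na(ib[i])) next
      if (isTRUE(pa$insufficient[ia[i]]) || isTRUE(pb$insufficient[ib[i]]))
        next
      A <- list(alpha = pa$alpha[ia[i]], beta = pa$beta[ia[i]])
      B <- list(alpha = pb$alpha[ib[i]], beta = pb$beta[ib[i]])
      piA <- stats::rbeta(n_draws, A$alpha, A$beta)
      piB <- stats::rbeta(n_draws, B$alpha, B$beta)
      dhl <- log2(as.numeric(ntr_to_halflife(piB, params))) -
        log2(as.numeric(ntr_to_halflife(piA, params)))
      rope_hl[i] <- mean(dhl > rope_width) - mean(dhl < -rope_width)
      ## S = delta * E with E treated as fixed: the synthesis log-ratio
      ## posterior is the abundance ratio minus the HL log-ratio posterior
      ds <- (lfc_s[i] + lfc_hl[i]) - dhl
      rope_s[i] <- mean(ds > rope_width) - mean(ds < -rope_width)
    }
  })
  cls <- classify_turnover_change(lfc_hl, rope_hl, lfc_s, rope_s,
                                  lfc_threshold, rope_threshold)
  q <- de$de_q[ide]
  stable <- !is.na(lfc_e) & abs(lfc_e) < 1 & (!is.na(q) & q > 0.05)
  out <- data.frame(
    gene = genes, contrast = paste(condition_b, "vs", condition_a),
    lfc_HL = lfc_hl, rope_HL = rope_hl, lfc_S = lfc_s, rope_S = rope_s,
    lfc_E = lfc_e, de_p = de$de_p[ide], de_q = q, class = cls,
    stable = stable, stringsAsFactors = FALSE)
  structure(out, class = c("turnover_changes", "data.frame"),
            thresholds = c(lfc = lfc_threshold, rope = rope_threshold,
                           rope_width = rope_width))
}

#' Decompose differentially expressed genes by turnover driver
#'
#' Among genes with a steady-state expression change (`|lfc_E| > 1` and
#' `de_q < 0.05`), the fractions whose turnover change is synthesis-only,
#' half-life-only, both, or neither.
#'
#' @param changes a [turnover_changes()] table.
#' @param lfc_threshold,q_threshold DEG definition.
#' @return named numeric vector (S_only, HL_only, both, neither) summing to
#'   1 over DEGs, with attribute `n_deg`; all zero (with a warning) when no
#'   gene qualifies.
#' @export
deg_decomposition <- function(changes, lfc_threshold = 1, q_threshold = 0.05) {
  deg <- !is.na(changes$lfc_E) & abs(changes$lfc_E) > lfc_threshold &
    !is.na(changes$de_q) & changes$de_q < q_threshold
  n <- sum(deg)
  if (n == 0) {
    warning("no differentially expressed genes; returning zeros")
    return(structure(c(S_only = 0, HL_only = 0, both = 0, neither = 0),
                     n_deg = 0L))
  }
  cls <- changes$class[deg]
  s_only <- cls %in% c("S_up", "S_down")
  hl_only <- cls %in% c("HL_up", "HL_down")
  both <- cls == "HL_and_S"
  structure(c(S_only = mean(s_only), HL_only = mean(hl_only),
              both = mean(both), neither = mean(cls == "none")),
            n_deg = n)
}
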