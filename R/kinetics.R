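#' Labeling parameters
#'
#' @param t 4sU pulse duration in hours.
#' @param hl_min,hl_max half-life caps in hours applied when the NTR pins
#'   to 1 or 0 (or implies a value beyond the caps); capped entries are
#'   flagged so downstream medians stay finite without silently trusting
#'   extrapolated values.
#' @return object of class `labeling_params`.
#' @export
labeling_params <- function(t = 1, hl_min = 0.05, hl_max = 48) {
  if (t <= 0) stop("pulse duration 't' must be positive", call. = FALSE)
  if (hl_min <= 0 || hl_max <= hl_min)
    stop("need 0 < hl_min < hl_max", call. = FALSE)
  structure(list(t = t, hl_min = hl_min, hl_max = hl_max),
            class = "labeling_params")
}

#' Median-of-ratios size factors
#'
#' Per-sample median of the ratios of counts to the per-gene geometric mean,
#' over genes with nonzero counts in every sample; factors are rescaled to
#' geometric mean 1, so they are comparable across runs and a doubled
#' library gets exactly twice the factor of its peers.
#'
#' @param counts numeric matrix, genes x samples (>= 2 samples).
#' @return named vector of positive size factors with geometric mean 1.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) stop("no gene has nonzero counts in all samples", call. = FALSE)
  lg <- log(counts[ok, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Degradation rate from the new-to-total ratio
#'
#' Under steady-state one-compartment turnover a pulse of `t` hours labels
#' the fraction `pi = 1 - exp(-delta * t)` of a transcript pool, so
#' `delta = -ln(1 - pi) / t`.
#'
#' @param pi NTR in [0, 1].
#' @param params a [labeling_params()].
#' @return degradation rate per hour (Inf at `pi = 1`).
#' @export
degradation_rate <- function(pi, params) {
  stopifnot(inherits(params, "labeling_params"))
  if (any(pi < 0 | pi > 1, na.rm = TRUE))
    stop("'pi' must lie in [0, 1]", call. = FALSE)
  d <- -log(1 - pi) / params$t
  d[!is.na(d) & d == 0] <- 0   # normalize IEEE negative zero at pi = 0
  d
}

#' Half-life from the new-to-total ratio
#'
#' `HL = ln 2 / delta = -t ln 2 / ln(1 - pi)`. Values implied beyond the
#' configured caps (including the `pi = 0` and `pi = 1` endpoints) are
#' clamped to `hl_max` / `hl_min` and flagged via the `capped` attribute.
#'
#' @inheritParams degradation_rate
#' @return half-life in hours, with logical attribute `capped`.
#' @export
ntr_to_halflife <- function(pi, params) {
  delta <- degradation_rate(pi, params)
  hl <- log(2) / delta
  capped <- is.na(hl) | hl > params$hl_max | hl < params$hl_min
  hl[is.na(hl) | hl > params$hl_max] <- params$hl_max
  hl[hl < params$hl_min] <- params$hl_min
  hl[is.na(pi)] <- NA_real_
  capped[is.na(pi)] <- NA
  structure(hl, capped = capped)
}

#' Inverse of [ntr_to_halflife()]
#'
#' @param hl half-life in hours.
#' @param params a [labeling_params()].
#' @return the NTR a transcript of that half-life reaches after the pulse.
#' @export
halflife_to_ntr <- function(hl, params) {
  stopifnot(inherits(params, "labeling_params"))
  1 - exp(-log(2) * params$t / hl)
}

#' Synthesis rate from NTR and normalized expression
#'
#' At steady state `S = delta * E`: abundance times turnover. Capping flags
#' from the half-life transform propagate.
#'
#' @param pi NTR in [0, 1].
#' @param E_norm size-factor-normalized expression (>= 0).
#' @param params a [labeling_params()].
#' @return synthesis rate in normalized units per hour, attribute `capped`.
#' @export
synthesis_rate <- function(pi, E_norm, params) {
  if (any(E_norm < 0, na.rm = TRUE))
    stop("'E_norm' must be non-negative", call. = FALSE)
  hl <- ntr_to_halflife(pi, params)
  delta <- log(2) / as.numeric(hl)
  structure(delta * E_norm, capped = attr(hl, "capped"))
}

#' Correct 4sU dropout against an unlabeled companion sample
#'
#' Short-lived (high-NTR) transcripts can be underrepresented in labeled
#' libraries because labeled (new) molecules are preferentially lost. Under
#' that mechanism a gene retains the fraction `1 - d * pi_true` of its
#' reads and its observed NTR shrinks to
#' `pi_obs = pi (1 - d) / (1 - d pi)`. The correction fits the single
#' retention parameter `d` by least squares to the trend of the normalized
#' labeled/unlabeled log2 count ratio against the estimated NTR (the
#' trend's shape identifies `d`; the global normalization offset is
#' profiled out, so no extrapolation to NTR = 0 is needed), then inverts
#' the thinning exactly: `pi' = pi / (1 - d + d pi)` and
#' `c' = c / (1 - d pi')`. Equivalently, `pi' = 1 - (1 - pi) c / c'` — the
#' gene's surviving pre-existing (old-RNA) read quantity is preserved,
#' since uniform-per-old-read observation is unaffected by dropout.
#' On dropout-free data the fitted `d` is ~0 and the correction is a
#' near-identity.
#'
#' @param labeled_counts,unlabeled_counts named per-gene raw counts of the
#'   labeled sample and its unlabeled partner.
#' @param ntr named per-gene NTR estimates of the labeled sample.
#' @param sf_labeled,sf_unlabeled size factors of the two samples.
#' @param d optional known dropout strength; estimated when NULL.
#' @return list with `counts` (corrected labeled counts), `ntr` (corrected
#'   NTR, clipped to [0, 1]), `d` (fitted retention parameter), and
#'   `trend` (data.frame pi, f: the fitted log2 retention curve, for
#'   diagnostics).
#' @export
dropout_correction <- function(labeled_counts, unlabeled_counts, ntr,
                               sf_labeled = 1, sf_unlabeled = 1, d = NULL) {
  genes <- intersect(names(labeled_counts), names(unlabeled_counts))
  genes <- intersect(genes, names(ntr)[!is.na(ntr)])
  lab <- labeled_counts[genes] / sf_labeled
  unl <- unlabeled_counts[genes] / sf_unlabeled
  use <- lab > 0 & unl > 0
  if (sum(use) < 50)
    stop("too few genes with coverage in both samples for trend fitting",
         call. = FALSE)
  lf <- log2(lab[use] + 0.5) - log2(unl[use] + 0.5)
  p <- ntr[genes][use]
  if (is.null(d)) {
    sse <- function(dd) {
      pt <- p / (1 - dd + dd * p)
      r <- lf - log2(1 - dd * pt)
      sum((r - mean(r))^2)
    }
    opt <- stats::optimize(sse, c(0, 0.95))
    d <- if (opt$objective > sse(0) - 1e-12) 0 else opt$minimum
  }
  pa <- ntr[genes]
  pi_corr <- pa / (1 - d + d * pa)
  corrected <- labeled_counts
  corrected[genes] <- ifelse(is.na(pi_corr), labeled_counts[genes],
                             labeled_counts[genes] / (1 - d * pi_corr))
  ntr_corr <- ntr
  ntr_corr[genes] <- pmin(pmax(pi_corr, 0), 1)
  ps <- sort(unique(p))
  list(counts = corrected, ntr = ntr_corr, d = d,
       trend = data.frame(pi = ps,
                          f = log2(1 - d * ps / (1 - d + d * ps))))
}

#' Quantify turnover for a full experimental design
#'
#' Normalizes labeled-sample counts by median-of-ratios size factors,
#' optionally corrects 4sU dropout per labeled sample against its
#' condition's unlabeled control, converts NTRs to degradation rate,
#' half-life and synthesis rate per replicate, and summarizes conditions by
#' the median across replicates.
#'
#' @param ntr_tables named list (by sample) of [estimate_ntr_table()]
#'   results for the labeled samples.
#' @param counts matrix genes x samples of raw counts (labeled and
#'   unlabeled).
#' @param design data.frame with columns sample, condition, replicate,
#'   labeled.
#' @param params a [labeling_params()].
#' @param dropout_correct apply [dropout_correction()] where an unlabeled
#'   partner exists (skipped with a warning otherwise).
#' @return object of class `turnover_table`: condition-level data.frame
#'   (gene, condition, n_replicates, E_norm, delta, HL_hours, S_per_h,
#'   capped, insufficient) with the per-replicate table as attribute
#'   `replicates`.
#' @export
quantify <- function(ntr_tables, counts, design, params,
                     dropout_correct = FALSE) {
  stopifnot(inherits(params, "labeling_params"))
  lab_design <- design[design$labeled, , drop = FALSE]
  if (!all(lab_design$sample %in% names(ntr_tables)))
    stop("missing NTR tables for labeled samples", call. = FALSE)
  if (!nrow(lab_design) || !nrow(counts) ||
      !any(vapply(ntr_tables[lab_design$sample], nrow, 0L) > 0))
    return(empty_turnover_table())
  sf <- size_factors(counts[, design$sample, drop = FALSE])
  rep_rows <- vector("list", nrow(lab_design))
  for (i in seq_len(nrow(lab_design))) {
    smp <- lab_design$sample[i]
    cond <- lab_design$condition[i]
    tab <- ntr_tables[[smp]]
    ntr <- stats::setNames(tab$pi_map, tab$gene)
    cnt <- counts[, smp]
    if (dropout_correct) {
      partner <- design$sample[!design$labeled & design$condition == cond]
      if (!length(partner)) {
        warning("no unlabeled partner for condition ", cond,
                "; dropout correction skipped")
      } else {
        corr <- dropout_correction(cnt, counts[, partner[1]], ntr,
                                   sf[smp], sf[partner[1]])
        cnt <- corr$counts
        ntr <- corr$ntr
      }
    }
    genes <- tab$gene
    e_norm <- cnt[genes] / sf[smp]
    pi_hat <- ntr[genes]
    hl <- ntr_to_halflife(pi_hat, params)
    s <- synthesis_rate(pi_hat, e_norm, params)
    rep_rows[[i]] <- data.frame(
      gene = genes, condition = cond, sample = smp,
      replicate = lab_design$replicate[i],
      E_norm = as.numeric(e_norm), pi = pi_hat,
      delta = log(2) / as.numeric(hl),
      HL_hours = as.numeric(hl), S_per_h = as.numeric(s),
      capped = as.logical(attr(hl, "capped")),
      insufficient = tab$insufficient,
      stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, rep_rows)
  rownames(reps) <- NULL
  med_or_na <- function(x) if (all(is.na(x))) NA_real_ else
    stats::median(x, na.rm = TRUE)
  agg <- function(col, fun) {
    a <- stats::aggregate(reps[[col]],
                          by = list(gene = reps$gene, condition = reps$condition),
                          FUN = fun)
    a$x
  }
  base <- stats::aggregate(reps$HL_hours,
                           by = list(gene = reps$gene, condition = reps$condition),
                           FUN = length)
  out <- data.frame(
    gene = base$gene, condition = base$condition, n_replicates = base$x,
    E_norm = agg("E_norm", med_or_na), pi = agg("pi", med_or_na),
    HL_hours = agg("HL_hours", med_or_na),
    S_per_h = agg("S_per_h", med_or_na),
    capped = agg("capped", function(x) any(x, na.rm = TRUE)),
    insufficient = agg("insufficient", function(x) all(x)),
    stringsAsFactors = FALSE)
  out$delta <- log(2) / out$HL_hours
  out <- out[order(out$condition, out$gene),
             c("gene", "condition", "n_replicates", "E_norm", "pi", "delta",
               "HL_hours", "S_per_h", "capped", "insufficient")]
  rownames(out) <- NULL
  structure(out, class = c("turnover_table", "data.frame"),
            replicates = reps, size_factors = sf, params = params)
}

empty_turnover_table <- function() {
  structure(data.frame(gene = character(), condition = character(),
                       n_replicates = integer(), E_norm = numeric(),
                       pi = numeric(), delta = numeric(),
                       HL_hours = numeric(), S_per_h = numeric(),
                       capped = logical(), insufficient = logical(),
                       stringsAsFactors = FALSE),
            class = c("turnover_table", "data.frame"))
}
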