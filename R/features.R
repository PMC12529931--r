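#' Z-score rows and k-means cluster temporal profiles
#'
#' Each gene's profile across timepoints (replicates already summarized) is
#' standardized to mean 0, sd 1; constant profiles carry no shape and are
#' dropped with a warning. Lloyd's k-means with `n_init` random restarts is
#' run on the z-scored matrix and the restart with the smallest total
#' within-cluster sum of squares kept; deterministic given `seed`.
#'
#' @param profiles numeric matrix genes x timepoints (rownames = genes).
#' @param k number of centers.
#' @param seed RNG seed.
#' @param n_init random restarts (default 25).
#' @param iter_max Lloyd iteration cap per restart.
#' @return object of class `cluster_result`: list with `cluster` (named
#'   gene -> id in 1..k), `centers` (k x timepoints, z-score space), `k`,
#'   `wss` (total within-cluster sum of squares), `seed`, `dropped`
#'   (constant genes).
#' @export
zscore_cluster <- function(profiles, k = 8, seed = 1L, n_init = 25,
                           iter_max = 100) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- sprintf("row%d", seq_len(nrow(profiles)))
  if (anyNA(profiles)) stop("profiles contain missing values", call. = FALSE)
  sds <- apply(profiles, 1, stats::sd)
  dropped <- rownames(profiles)[sds == 0]
  if (length(dropped))
    warning(length(dropped), " constant profile(s) dropped from clustering")
  z <- profiles[sds > 0, , drop = FALSE]
  if (k > nrow(z)) stop("'k' exceeds the number of usable genes", call. = FALSE)
  z <- t(scale(t(z)))
  km <- with_seed(seed,
                  stats::kmeans(z, centers = k, nstart = n_init,
                                iter.max = iter_max))
  structure(list(cluster = km$cluster, centers = km$centers, k = k,
                 wss = km$tot.withinss, seed = seed, dropped = dropped),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: k =", x$k, ",", length(x$cluster),
      "genes, total WSS =", signif(x$wss, 5), "\n")
  invisible(x)
}

#' Wilcoxon rank-sum association of a transcript feature with a gene group
#'
#' Tests whether a structural feature (GC fraction, 3'UTR length, ...)
#' differs between two gene groups, e.g. transcripts with increased
#' half-life versus unchanged transcripts. Average ranks for ties; exact
#' p-value when both groups have at most `exact_max` members and no ties,
#' otherwise the normal approximation with continuity correction. Group
#' medians are reported so the direction of the shift is explicit.
#'
#' @param values_a,values_b feature values of the two groups, or
#'   (`values_a` = group labels of length n with exactly two levels,
#'   `values_b` = feature values of length n).
#' @param exact_max exact-enumeration size cutoff per group (default 12).
#' @return list: `statistic` (rank-sum W of group A), `p` (two-sided),
#'   `median_a`, `median_b`, `n_a`, `n_b`, `exact`.
#' @export
feature_association <- function(values_a, values_b, exact_max = 12) {
  if (length(values_a) == length(values_b) &&
      (is.character(values_a) || is.factor(values_a)) &&
      length(unique(values_a)) == 2) {
    lv <- sort(unique(as.character(values_a)))
    grp <- as.character(values_a)
    x <- values_b[grp == lv[1]]
    y <- values_b[grp == lv[2]]
  } else {
    x <- values_a; y <- values_b
  }
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_a = stats::median(x), median_b = stats::median(y),
       n_a = length(x), n_b = length(y), exact = exact)
}

#' Half-life profile matrix for clustering
#'
#' Builds the gene x timepoint matrix of condition-summarized half-lives
#' for one genotype from a [quantify()] result, averaging replicate
#' summaries per timepoint (mean of the condition medians when several
#' conditions map to a timepoint).
#'
#' @param turnover a [quantify()] result.
#' @param design data.frame mapping condition to timepoint (columns
#'   condition, timepoint), deduplicated internally.
#' @param value column to pivot (default `"HL_hours"`).
#' @param complete_only keep only genes quantified at every timepoint.
#' @return numeric matrix genes x timepoints.
#' @export
profile_matrix <- function(turnover, design, value = "HL_hours",
                           complete_only = TRUE) {
  map <- unique(design[, c("condition", "timepoint")])
  tt <- turnover[turnover$condition %in% map$condition, ]
  tt$timepoint <- map$timepoint[match(tt$condition, map$condition)]
  agg <- stats::aggregate(tt[[value]],
                          by = list(gene = tt$gene, timepoint = tt$timepoint),
                          FUN = mean, na.rm = TRUE)
  tps <- unique(map$timepoint)
  genes <- unique(agg$gene)
  m <- matrix(NA_real_, length(genes), length(tps),
              dimnames = list(genes, tps))
  m[cbind(match(agg$gene, genes), match(agg$timepoint, tps))] <- agg$x
  if (complete_only) m <- m[stats::complete.cases(m), , drop = FALSE]
  m
}
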