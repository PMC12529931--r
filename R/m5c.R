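#' Per-gene bisulfite conversion context
#'
#' The null hypothesis for site calling is the gene's own background
#' conversion behavior: across all assayed cytosines of a gene, the totals
#' of converted and non-converted reads define its empirical conversion
#' rate. Intergenic sites fall back to a conservative fixed conversion
#' rate.
#'
#' @param sites site table (chrom, pos, strand, gene, coverage,
#'   non_converted); `gene` may be NA for intergenic sites.
#' @param fallback_rate conversion rate assumed outside genes (default
#'   0.9).
#' @param fallback_total pseudo read total used to build the background
#'   contingency column for intergenic sites.
#' @return object of class `conversion_context`: per-gene data.frame
#'   (gene, total, converted, rate) plus the fallback settings.
#' @export
conversion_context <- function(sites, fallback_rate = 0.9,
                               fallback_total = 1000) {
  if (fallback_rate <= 0 || fallback_rate > 1)
    stop("'fallback_rate' must lie in (0, 1]", call. = FALSE)
  g <- sites[!is.na(sites$gene), , drop = FALSE]
  tot <- rowsum(cbind(g$coverage, g$coverage - g$non_converted), g$gene)
  genes <- data.frame(gene = rownames(tot), total = tot[, 1],
                      converted = tot[, 2],
                      rate = ifelse(tot[, 1] > 0, tot[, 2] / tot[, 1], NA),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(genes = genes, fallback_rate = fallback_rate,
                 fallback_total = fallback_total),
            class = "conversion_context")
}

#' Call candidate m5C sites from a bisulfite site table
#'
#' Applies the coverage, count and rate filters, then tests each passing
#' site for enrichment of non-converted reads over the gene's background
#' with a one-sided Fisher's exact test on the 2x2 table
#' `[site non-converted, site converted | background non-converted,
#' background converted]`, where the background column is the gene's
#' assayed totals excluding the tested site. Intergenic sites use the
#' fallback conversion rate with a pseudo read total. Benjamini-Hochberg
#' q-values are computed over the tested sites.
#'
#' @param sites site table (chrom, pos, strand, gene, coverage,
#'   non_converted).
#' @param context a [conversion_context()]; computed from `sites` when
#'   NULL.
#' @param min_coverage sites need coverage strictly greater than this
#'   (default 20).
#' @param c_cutoff minimum non-converted reads (default 3).
#' @param min_rate minimum methylation rate, strict (default 0.1).
#' @return data.frame of class `called_sites`: input columns plus `rate`,
#'   `passes_filters`, `p`, `q` (NA for sites failing the filters).
#' @export
call_sites <- function(sites, context = NULL, min_coverage = 20,
                       c_cutoff = 3, min_rate = 0.1) {
  stopifnot(all(c("chrom", "pos", "strand", "coverage", "non_converted")
                %in% names(sites)))
  if (any(sites$non_converted > sites$coverage))
    stop("non_converted exceeds coverage", call. = FALSE)
  if (is.null(context)) context <- conversion_context(sites)
  out <- sites
  out$rate <- ifelse(out$coverage > 0, out$non_converted / out$coverage, 0)
  out$passes_filters <- out$coverage > min_coverage &
    out$non_converted >= c_cutoff & out$rate > min_rate
  out$p <- NA_real_
  gi <- match(out$gene, context$genes$gene)
  for (i in which(out$passes_filters)) {
    nc <- out$non_converted[i]
    conv <- out$coverage[i] - nc
    if (!is.na(out$gene[i]) && !is.na(gi[i])) {
      bg_total <- context$genes$total[gi[i]] - out$coverage[i]
      bg_conv <- context$genes$converted[gi[i]] - conv
      bg_nc <- bg_total - bg_conv
      if (bg_total <= 0) {         # gene has no other assayed cytosine
        bg_total <- context$fallback_total
        bg_nc <- round((1 - context$fallback_rate) * bg_total)
        bg_conv <- bg_total - bg_nc
      }
    } else {
      bg_total <- context$fallback_total
      bg_nc <- round((1 - context$fallback_rate) * bg_total)
      bg_conv <- bg_total - bg_nc
    }
    out$p[i] <- stats::fisher.test(
      matrix(c(nc, conv, bg_nc, bg_conv), nrow = 2),
      alternative = "greater")$p.value
  }
  out$q <- NA_real_
  tested <- !is.na(out$p)
  if (any(tested)) out$q[tested] <- bh_adjust(out$p[tested])
  structure(out, class = c("called_sites", "data.frame"))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_i = min over j >= rank(i) of p_(j) * m / j`, capped at 1;
#' order-preserving in p.
#'
#' @param p vector of p-values in [0, 1] (NA passed through).
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' All-replicate consensus m5C sites for a condition
#'
#' A site (chrom, pos, strand) is kept when it passes the filters and its
#' q-value is below `fdr` in EVERY replicate of the condition. With a
#' single replicate the consensus is that replicate's significant sites.
#'
#' @param called list of [call_sites()] results, one per replicate.
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame: chrom, pos, strand, gene, mean_rate (across
#'   replicates), n_replicates.
#' @export
consensus_sites <- function(called, fdr = 0.05) {
  if (!length(called))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), gene = character(),
                      mean_rate = numeric(), n_replicates = integer(),
                      stringsAsFactors = FALSE))
  keys <- lapply(called, function(d) {
    sig <- d$passes_filters & !is.na(d$q) & d$q < fdr
    d <- d[sig, , drop = FALSE]
    d$key <- paste(d$chrom, d$pos, d$strand)
    d
  })
  common <- Reduce(intersect, lapply(keys, `[[`, "key"))
  first <- keys[[1]][match(common, keys[[1]]$key), , drop = FALSE]
  rates <- sapply(keys, function(d) d$rate[match(common, d$key)])
  mean_rate <- if (length(common))
    rowMeans(matrix(rates, nrow = length(common))) else numeric()
  data.frame(chrom = first$chrom, pos = first$pos, strand = first$strand,
             gene = first$gene, mean_rate = mean_rate,
             n_replicates = rep(length(called), length(common)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Methyltransferase-dependent sites
#'
#' Set difference of consensus sites: present in the wild-type condition
#' but absent from the knockout at the matched timepoint.
#'
#' @param consensus_wt,consensus_ko [consensus_sites()] results.
#' @return the wild-type rows whose (chrom, pos, strand) is not in the
#'   knockout consensus.
#' @export
dependent_sites <- function(consensus_wt, consensus_ko) {
  kw <- paste(consensus_wt$chrom, consensus_wt$pos, consensus_wt$strand)
  kk <- paste(consensus_ko$chrom, consensus_ko$pos, consensus_ko$strand)
  out <- consensus_wt[!(kw %in% kk), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of methylated transcripts with turnover-change classes
#'
#' Gene-level three-way Venn between transcripts carrying m5C sites,
#' transcripts with altered half-life, and transcripts with altered
#' synthesis, plus the fraction of dynamics-altered transcripts carrying
#' sites.
#'
#' @param sites site table with a `gene` column (e.g.
#'   [dependent_sites()]).
#' @param changes a [turnover_changes()] table.
#' @return list: `regions` (named counts of the 7 Venn regions), `n_union`,
#'   `frac_altered_with_m5c`.
#' @export
overlap_with_dynamics <- function(sites, changes) {
  m5c <- unique(stats::na.omit(sites$gene))
  hl <- changes$gene[changes$class %in% c("HL_up", "HL_down", "HL_and_S")]
  s <- changes$gene[changes$class %in% c("S_up", "S_down", "HL_and_S")]
  u <- union(m5c, union(hl, s))
  inm <- u %in% m5c; inh <- u %in% hl; ins <- u %in% s
  regions <- c(
    m5c_only = sum(inm & !inh & !ins),
    HL_only = sum(!inm & inh & !ins),
    S_only = sum(!inm & !inh & ins),
    m5c_HL = sum(inm & inh & !ins),
    m5c_S = sum(inm & !inh & ins),
    HL_S = sum(!inm & inh & ins),
    m5c_HL_S = sum(inm & inh & ins))
  altered <- union(hl, s)
  list(regions = regions, n_union = length(u),
       frac_altered_with_m5c = if (length(altered))
         mean(altered %in% m5c) else NA_real_)
}

#' Export sites as BED
#'
#' Native site tables are 1-based; BED is 0-based half-open, so `start =
#' pos - 1`, `end = pos`.
#'
#' @param sites site table (chrom, pos, strand; optional gene).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
sites_to_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$chrom, start = sites$pos - 1L,
                    end = sites$pos,
                    name = if (!is.null(sites$gene))
                      ifelse(is.na(sites$gene), ".", sites$gene) else ".",
                    score = 0L, strand = sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
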