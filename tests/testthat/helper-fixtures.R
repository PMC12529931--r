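## shared fixture builders

hist_df <- function(n, k, count, gene = "g1") {
  data.frame(gene = rep(gene, length.out = length(n)), n = n, k = k,
             count = count, stringsAsFactors = FALSE)
}

## read-level simulator used to exercise the estimators under known truth,
## independent of the package's own generator
draw_gene_hist <- function(pi, n_reads, p_err, p_new, u_mean = 30,
                           gene = "g1") {
  n <- 1L + rpois(n_reads, u_mean - 1)
  new <- runif(n_reads) < pi
  k <- rbinom(n_reads, n, ifelse(new, p_new, p_err))
  agg <- aggregate(list(count = rep(1L, n_reads)),
                   by = list(n = n, k = k), FUN = sum)
  cbind(gene = gene, agg, stringsAsFactors = FALSE)
}

## small standard config for pipeline-ish tests
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 150, timepoints = c("d0", "d4"),
                   genotypes = c("WT", "KO"), n_replicates = 2,
                   library_size = 1.5e5, seed = 42L,
                   bs_n_sites = 150)
  do.call(sim_config, utils::modifyList(defaults, args))
}
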