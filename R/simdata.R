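#' Configuration for the synthetic TUC-seq / BS-seq generator
#'
#' Bundles every parameter of the ground-truthed simulator: the experimental
#' design (genotypes, timepoints, replicates), the labeling and sequencing
#' model (pulse length, conversion rates, uridines per read, library sizes),
#' the structure of true turnover changes between conditions (buffered and
#' differentially expressed gene fractions), 4sU dropout strength, and the
#' bisulfite site model.
#'
#' The defaults emulate a 1 h 4sU pulse read out on a 3'-end mRNA library:
#' a low background T-to-C rate (`p_err`), a moderately elevated rate in
#' labeled new transcripts (`p_new`), about 30 uridine positions per read,
#' and roughly 1000 reads per gene.
#'
#' @param n_genes number of genes.
#' @param timepoints character vector of timepoint labels; the first is the
#'   reference state.
#' @param genotypes character vector of genotype labels; the first is wild
#'   type (bisulfite sites flagged as methyltransferase-dependent are
#'   unmethylated in the others).
#' @param n_replicates labeled replicates per genotype x timepoint condition
#'   (each condition additionally gets one unlabeled control).
#' @param library_size,library_size_disp mean library size (reads) and
#'   log-normal sdlog of sample-to-sample library-size variation.
#' @param pulse_hours 4sU pulse duration t in hours.
#' @param p_err background T-to-C conversion probability per uridine
#'   (sequencing error plus chemistry background).
#' @param p_new T-to-C conversion probability per uridine in labeled new RNA.
#' @param u_per_read mean uridine positions per read; per-read counts are
#'   1 + Poisson(u_per_read - 1) so every read carries signal.
#' @param hl_range true half-life range in hours (log-uniform draw).
#' @param buffering_fraction fraction of genes whose half-life and synthesis
#'   change in opposite directions between conditions while steady-state
#'   abundance stays within |log2 fc| < 1 (transcript buffering).
#' @param buffering_target_corr target Spearman correlation (in [-1, 0])
#'   between the true log half-life and log synthesis changes of buffered
#'   genes.
#' @param deg_fraction fraction of genes with a genuine steady-state
#'   expression change (|log2 fc| > 1), driven by synthesis or by stability.
#' @param dropout_strength d in [0, 1]: probability that a labeled (new)
#'   read is lost to 4sU dropout; a gene's expected read retention is
#'   1 - d * NTR.
#' @param bs_n_sites,bs_methylated_fraction,bs_dependent_fraction,bs_rate_shape
#'   bisulfite site model: number of simulated cytosines, fraction truly
#'   methylated, fraction of methylated sites that are
#'   methyltransferase-dependent, and Beta shape parameters (length 2) for
#'   true methylation rates (defaults give mostly low-stoichiometry sites).
#' @param bs_conversion_rate bisulfite conversion efficiency in (0, 1].
#' @param bs_coverage_mean,bs_coverage_size negative-binomial per-site
#'   coverage model.
#' @param bs_intergenic_fraction fraction of simulated sites outside genes.
#' @param seed integer master seed; every generator call derives
#'   deterministic child seeds from it.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_genes = 1000,
                       timepoints = c("d0", "d1", "d4"),
                       genotypes = c("WT", "KO"),
                       n_replicates = 2,
                       library_size = 1e6,
                       library_size_disp = 0.15,
                       pulse_hours = 1,
                       p_err = 0.001,
                       p_new = 0.04,
                       u_per_read = 30,
                       hl_range = c(0.5, 16),
                       buffering_fraction = 0.25,
                       buffering_target_corr = -0.8,
                       deg_fraction = 0.15,
                       dropout_strength = 0,
                       bs_n_sites = 600,
                       bs_methylated_fraction = 0.25,
                       bs_dependent_fraction = 0.6,
                       bs_rate_shape = c(1.2, 4),
                       bs_conversion_rate = 0.99,
                       bs_coverage_mean = 50,
                       bs_coverage_size = 10,
                       bs_intergenic_fraction = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot_prob(p_err, "p_err")
  stopifnot_prob(p_new, "p_new")
  if (p_new <= p_err) stop("'p_new' must exceed 'p_err'", call. = FALSE)
  if (length(hl_range) != 2 || any(hl_range <= 0) || diff(hl_range) < 0)
    stop("'hl_range' must be a positive increasing interval", call. = FALSE)
  stopifnot_prob(buffering_fraction, "buffering_fraction", open = FALSE)
  stopifnot_prob(deg_fraction, "deg_fraction", open = FALSE)
  if (buffering_fraction + deg_fraction > 1)
    stop("'buffering_fraction' + 'deg_fraction' must not exceed 1",
         call. = FALSE)
  if (buffering_target_corr < -1 || buffering_target_corr > 0)
    stop("'buffering_target_corr' must lie in [-1, 0]", call. = FALSE)
  stopifnot_prob(dropout_strength, "dropout_strength", open = FALSE)
  if (bs_conversion_rate <= 0 || bs_conversion_rate > 1)
    stop("'bs_conversion_rate' must lie in (0, 1]", call. = FALSE)
  if (pulse_hours <= 0) stop("'pulse_hours' must be positive", call. = FALSE)
  if (n_replicates < 1) stop("'n_replicates' must be >= 1", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,",
      length(x$genotypes), "genotypes x", length(x$timepoints),
      "timepoints x", x$n_replicates, "replicates; pulse",
      x$pulse_hours, "h; seed", x$seed, "\n")
  invisible(x)
}

condition_label <- function(genotype, timepoint) paste(genotype, timepoint, sep = ".")

#' Simulate ground-truth turnover parameters, methylation and annotation
#'
#' Draws, for every gene and condition, a true half-life `HL_true` (hours),
#' synthesis rate `S_true` (units/h) and steady-state abundance
#' `E_true = S_true * HL_true / ln 2`. The reference condition (first
#' genotype, first timepoint) is drawn log-uniformly over `hl_range`; every
#' other condition perturbs it according to the gene's class:
#' \describe{
#'   \item{buffered}{(Delta log2 HL, Delta log2 S) drawn from a bivariate
#'     normal whose Gaussian correlation is calibrated so the empirical
#'     Spearman correlation matches `buffering_target_corr`; the synthesis
#'     change is then adjusted, if needed, to keep |log2 fc| of abundance
#'     below 1 (stable steady state, opposing turnover changes).}
#'   \item{deg}{a genuine expression change with |log2 fc| > 1, driven by
#'     synthesis (half of these genes) or by stability (other half).}
#'   \item{constant}{identical to the reference condition.}
#' }
#' Also generates the bisulfite methylation ground truth (site coordinates,
#' true rates, methyltransferase dependence) and a per-gene annotation
#' (GC fraction, 3'UTR length).
#'
#' @param config a [sim_config()].
#' @return object of class `sim_truth`: list with data.frames `turnover`
#'   (gene, condition, genotype, timepoint, class, HL_true, S_true, E_true),
#'   `methylation` (site_id, chrom, pos, strand, gene, rate_true,
#'   dependent), `annotation` (gene, gc_fraction, utr3_length), and the
#'   `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "truth"), {
    ng <- config$n_genes
    genes <- sprintf("G%05d", seq_len(ng))
    ## gene classes
    n_buf <- round(config$buffering_fraction * ng)
    n_deg <- round(config$deg_fraction * ng)
    class <- rep("constant", ng)
    idx <- sample.int(ng, n_buf + n_deg)
    class[idx[seq_len(n_buf)]] <- "buffered"
    if (n_deg > 0) class[idx[n_buf + seq_len(n_deg)]] <- "deg"
    deg_driver <- ifelse(class == "deg" & (runif(ng) < 0.5), "S", "HL")

    ## reference condition
    hl0 <- exp(runif(ng, log(config$hl_range[1]), log(config$hl_range[2])))
    e0 <- exp(rnorm(ng, 0, 1))            # relative abundance, arbitrary units
    s0 <- e0 * log(2) / hl0

    conds <- expand.grid(timepoint = config$timepoints,
                         genotype = config$genotypes,
                         stringsAsFactors = FALSE)[, c("genotype", "timepoint")]
    ref <- 1L
    ## Gaussian correlation giving the requested Spearman on the copula
    rho <- 2 * sin(pi * config$buffering_target_corr / 6)

    rows <- vector("list", nrow(conds))
    for (ci in seq_len(nrow(conds))) {
      gt <- conds$genotype[ci]; tp <- conds$timepoint[ci]
      hl <- hl0; s <- s0
      if (ci != ref) {
        buf <- which(class == "buffered")
        if (length(buf)) {
          z1 <- rnorm(length(buf)); z2 <- rnorm(length(buf))
          dh <- z1
          ds <- rho * z1 + sqrt(1 - rho^2) * z2
          de <- dh + ds                     # log2 abundance change
          over <- abs(de) >= 1
          ds[over] <- ds[over] - sign(de[over]) * (abs(de[over]) - 0.95)
          hl[buf] <- hl0[buf] * 2^dh
          s[buf] <- s0[buf] * 2^ds
        }
        dg <- which(class == "deg")
        if (length(dg)) {
          shift <- sample(c(-1, 1), length(dg), replace = TRUE) *
            runif(length(dg), 1.2, 2.5)
          sdrv <- deg_driver[dg] == "S"
          s[dg[sdrv]] <- s0[dg[sdrv]] * 2^shift[sdrv]
          hl[dg[!sdrv]] <- hl0[dg[!sdrv]] * 2^shift[!sdrv]
        }
      }
      rows[[ci]] <- data.frame(
        gene = genes, condition = condition_label(gt, tp),
        genotype = gt, timepoint = tp, class = class,
        HL_true = hl, S_true = s, E_true = s * hl / log(2),
        stringsAsFactors = FALSE)
    }
    turnover <- do.call(rbind, rows)
    rownames(turnover) <- NULL

    ## methylation ground truth
    ns <- config$bs_n_sites
    n_inter <- round(config$bs_intergenic_fraction * ns)
    site_gene <- c(rep(NA_character_, n_inter),
                   sample(genes, ns - n_inter, replace = TRUE))
    rate <- numeric(ns)
    meth <- runif(ns) < config$bs_methylated_fraction
    meth[is.na(site_gene)] <- FALSE       # intergenic sites kept unmethylated
    rate[meth] <- 0.05 + 0.9 * rbeta(sum(meth), config$bs_rate_shape[1],
                                     config$bs_rate_shape[2])
    dependent <- meth & (runif(ns) < config$bs_dependent_fraction)
    methylation <- data.frame(
      site_id = sprintf("S%05d", seq_len(ns)),
      chrom = paste0("chr", sample(1:19, ns, replace = TRUE)),
      pos = sample.int(1e8, ns),
      strand = sample(c("+", "-"), ns, replace = TRUE),
      gene = site_gene, rate_true = rate, dependent = dependent,
      stringsAsFactors = FALSE)
    methylation <- methylation[order(methylation$chrom, methylation$pos), ]
    rownames(methylation) <- NULL

    annotation <- data.frame(
      gene = genes,
      gc_fraction = rbeta(ng, 45, 55),
      utr3_length = round(exp(rnorm(ng, log(800), 0.6))),
      stringsAsFactors = FALSE)

    structure(list(turnover = turnover, methylation = methylation,
                   annotation = annotation, config = config),
              class = "sim_truth")
  })
}

## fraction of transcripts synthesized during a pulse of t hours for a
## transcript with half-life hl: 1 - 2^(-t/hl)
true_ntr <- function(hl, t) 1 - 2^(-t / hl)

#' Simulate read-level conversion data for one sample
#'
#' Generates a 3'-end library for one condition and replicate: per-gene read
#' counts proportional to true abundance scaled to a log-normally sampled
#' library size; each read is "new" with probability equal to the gene's
#' new-to-total ratio (0 in unlabeled controls), carries
#' `n ~ 1 + Poisson(u_per_read - 1)` uridine positions and
#' `k ~ Binomial(n, p_new)` (new) or `Binomial(n, p_err)` (pre-existing)
#' T-to-C conversions. Reads are aggregated to per-gene (n, k) histograms,
#' the sufficient statistic of the downstream mixture likelihood.
#'
#' @param truth a [simulate_truth()] result.
#' @param condition condition label, `"<genotype>.<timepoint>"`.
#' @param replicate replicate number (only used to derive the seed).
#' @param labeled logical: 4sU-labeled sample (`TRUE`) or unlabeled control.
#' @param seed optional seed; defaults to a child of the config seed.
#' @return object of class `conversion_sample`: list with `histogram`
#'   (data.frame gene, n, k, count), `counts` (named per-gene read totals,
#'   including zero-read genes), `sample`, `condition`, `labeled`.
#' @export
simulate_conversion_reads <- function(truth, condition, replicate = 1,
                                      labeled = TRUE, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  tr <- truth$turnover[truth$turnover$condition == condition, ]
  if (!nrow(tr)) stop("unknown condition: ", condition, call. = FALSE)
  if (is.null(seed))
    seed <- child_seed(cfg$seed, paste("reads", condition, replicate, labeled))
  sample_name <- paste0(condition, ".", if (labeled) "4sU" else "ctrl",
                        ".R", replicate)
  with_seed(seed, {
    lib <- rlnorm(1, log(cfg$library_size), cfg$library_size_disp)
    lambda <- lib * tr$E_true / sum(tr$E_true)
    n_reads <- rpois(nrow(tr), lambda)
    pi_g <- if (labeled) true_ntr(tr$HL_true, cfg$pulse_hours) else rep(0, nrow(tr))
    gene_idx <- rep.int(seq_len(nrow(tr)), n_reads)
    total <- length(gene_idx)
    is_new <- runif(total) < pi_g[gene_idx]
    n <- 1L + rpois(total, cfg$u_per_read - 1)
    k <- rbinom(total, n, ifelse(is_new, cfg$p_new, cfg$p_err))
    hist <- aggregate_reads(tr$gene, gene_idx, n, k)
    counts <- stats::setNames(n_reads, tr$gene)
    structure(list(histogram = hist, counts = counts, sample = sample_name,
                   condition = condition, labeled = labeled),
              class = "conversion_sample")
  })
}

## aggregate read-level (gene, n, k) triples into count histograms
aggregate_reads <- function(genes, gene_idx, n, k) {
  if (!length(gene_idx))
    return(data.frame(gene = character(), n = integer(), k = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  nmax <- max(n) + 1L
  key <- (as.numeric(gene_idx) - 1) * nmax * nmax + as.numeric(n) * nmax +
    as.numeric(k)
  o <- sort.int(key, method = "radix")
  r <- rle(o)
  v <- r$values
  gi <- floor(v / (nmax * nmax))
  rem <- v - gi * nmax * nmax
  nn <- floor(rem / nmax)
  kk <- rem - nn * nmax
  data.frame(gene = genes[gi + 1L], n = as.integer(nn), k = as.integer(kk),
             count = r$lengths, stringsAsFactors = FALSE)
}

#' Thin a labeled sample to emulate 4sU dropout
#'
#' 4sU labeling can leave short-lived (high-NTR) transcripts
#' underrepresented among mapped reads. The generator emulates this by
#' dropping labeled (new) reads with probability `d`, so a gene's expected
#' read retention is `1 - d * pi_true`. Because the histogram no longer
#' records which reads were new, each (n, k) cell is thinned binomially with
#' retention `1 - d * P(new | n, k)`, the posterior new-read probability
#' under the generator's own mixture at the gene's true NTR; this has the
#' same gene-level expectation and preferentially removes converted reads,
#' biasing both counts and the estimated NTR downward as real dropout does.
#'
#' @param sample a `conversion_sample` (labeled).
#' @param truth the [simulate_truth()] object the sample was generated from.
#' @param d dropout strength in [0, 1]; `d = 0` returns the input unchanged.
#' @param seed optional seed.
#' @return a `conversion_sample` with thinned histogram and counts.
#' @export
apply_dropout <- function(sample, truth, d, seed = NULL) {
  stopifnot(inherits(sample, "conversion_sample"), inherits(truth, "sim_truth"))
  if (d < 0 || d > 1) stop("'d' must lie in [0, 1]", call. = FALSE)
  if (d == 0 || !sample$labeled) return(sample)
  cfg <- truth$config
  tr <- truth$turnover[truth$turnover$condition == sample$condition, ]
  pi_g <- stats::setNames(true_ntr(tr$HL_true, cfg$pulse_hours), tr$gene)
  h <- sample$histogram
  if (is.null(seed)) seed <- child_seed(cfg$seed, paste("dropout", sample$sample))
  with_seed(seed, {
    f0 <- dbinom(h$k, h$n, cfg$p_err)
    f1 <- dbinom(h$k, h$n, cfg$p_new)
    p <- pi_g[h$gene]
    post_new <- p * f1 / (p * f1 + (1 - p) * f0)
    keep <- rbinom(nrow(h), h$count, 1 - d * post_new)
    h$count <- keep
    h <- h[h$count > 0, , drop = FALSE]
    rownames(h) <- NULL
    counts <- sample$counts
    kept <- tapply(h$count, h$gene, sum)
    counts[] <- 0L
    counts[names(kept)] <- as.integer(kept)
    out <- sample
    out$histogram <- h
    out$counts <- counts
    out
  })
}

#' Simulate a bisulfite-sequencing site table for one sample
#'
#' For every cytosine in the methylation ground truth, draws a
#' negative-binomial coverage and a binomial non-converted read count with
#' success probability `rate + (1 - rate) * (1 - conversion_rate)`:
#' methylated cytosines resist conversion, unmethylated ones appear
#' non-converted only through incomplete bisulfite conversion. Sites flagged
#' as methyltransferase-dependent have true rate 0 in non-reference
#' genotypes.
#'
#' @param truth a [simulate_truth()] result.
#' @param genotype genotype label (first configured genotype = wild type).
#' @param replicate replicate number (seed derivation only).
#' @param conversion_rate bisulfite conversion efficiency in (0, 1];
#'   defaults to the config value.
#' @param seed optional seed.
#' @return data.frame: chrom, pos (1-based), strand, gene, coverage,
#'   non_converted.
#' @export
simulate_bisulfite <- function(truth, genotype, replicate = 1,
                               conversion_rate = NULL, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  if (is.null(conversion_rate)) conversion_rate <- cfg$bs_conversion_rate
  if (conversion_rate <= 0 || conversion_rate > 1)
    stop("'conversion_rate' must lie in (0, 1]", call. = FALSE)
  m <- truth$methylation
  rate <- m$rate_true
  if (genotype != cfg$genotypes[1]) rate[m$dependent] <- 0
  if (is.null(seed))
    seed <- child_seed(cfg$seed, paste("bs", genotype, replicate))
  with_seed(seed, {
    cov <- rnbinom(nrow(m), mu = cfg$bs_coverage_mean, size = cfg$bs_coverage_size)
    p_nc <- rate + (1 - rate) * (1 - conversion_rate)
    nc <- rbinom(nrow(m), cov, p_nc)
    data.frame(chrom = m$chrom, pos = m$pos, strand = m$strand,
               gene = m$gene, coverage = cov, non_converted = nc,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete labeling experiment
#'
#' Convenience wrapper: generates the truth, then for every genotype x
#' timepoint condition `n_replicates` labeled samples plus one unlabeled
#' control, applying 4sU dropout at the configured strength.
#'
#' @param config a [sim_config()].
#' @return list with `truth`, `samples` (list of `conversion_sample`), and
#'   `design` (data.frame sample, condition, genotype, timepoint, replicate,
#'   labeled).
#' @export
simulate_experiment <- function(config) {
  truth <- simulate_truth(config)
  samples <- list()
  design <- list()
  for (gt in config$genotypes) for (tp in config$timepoints) {
    cond <- condition_label(gt, tp)
    for (r in seq_len(config$n_replicates)) {
      s <- simulate_conversion_reads(truth, cond, r, labeled = TRUE)
      if (config$dropout_strength > 0)
        s <- apply_dropout(s, truth, config$dropout_strength)
      samples[[s$sample]] <- s
      design[[length(design) + 1L]] <- data.frame(
        sample = s$sample, condition = cond, genotype = gt, timepoint = tp,
        replicate = r, labeled = TRUE, stringsAsFactors = FALSE)
    }
    s <- simulate_conversion_reads(truth, cond, 1, labeled = FALSE)
    samples[[s$sample]] <- s
    design[[length(design) + 1L]] <- data.frame(
      sample = s$sample, condition = cond, genotype = gt, timepoint = tp,
      replicate = 1, labeled = FALSE, stringsAsFactors = FALSE)
  }
  list(truth = truth, samples = samples,
       design = do.call(rbind, design))
}

#' Assemble the per-gene count matrix of an experiment
#'
#' @param experiment a [simulate_experiment()] result.
#' @param labeled_only keep only labeled samples (default all).
#' @return integer matrix genes x samples.
#' @export
count_matrix <- function(experiment, labeled_only = FALSE) {
  samples <- experiment$samples
  if (labeled_only)
    samples <- samples[vapply(samples, `[[`, TRUE, "labeled")]
  m <- vapply(samples, `[[`, numeric(length(samples[[1]]$counts)), "counts")
  rownames(m) <- names(samples[[1]]$counts)
  m
}

#' Write an experiment's tables to a directory
#'
#' Emits the truth table, per-sample conversion histograms, the count
#' matrix, the gene annotation and per-replicate BS-seq site tables as
#' tab-delimited files with metadata headers, in deterministic order.
#'
#' @param experiment a [simulate_experiment()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of written paths.
#' @export
write_sim_tables <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- experiment$truth$config
  meta <- list(seed = cfg$seed, pulse_hours = cfg$pulse_hours,
               p_err = cfg$p_err, p_new = cfg$p_new)
  paths <- character()
  p <- file.path(dir, "truth.tsv")
  write_tsv_table(experiment$truth$turnover, p, meta); paths <- c(paths, p)
  p <- file.path(dir, "annotation.tsv")
  write_tsv_table(experiment$truth$annotation, p, meta); paths <- c(paths, p)
  hist <- do.call(rbind, lapply(experiment$samples, function(s)
    cbind(sample = s$sample, s$histogram, stringsAsFactors = FALSE)))
  rownames(hist) <- NULL
  p <- file.path(dir, "conversion_histograms.tsv")
  write_tsv_table(hist, p, meta); paths <- c(paths, p)
  cm <- count_matrix(experiment)
  p <- file.path(dir, "counts.tsv")
  write_tsv_table(data.frame(gene = rownames(cm), cm, check.names = FALSE,
                             stringsAsFactors = FALSE), p, meta)
  paths <- c(paths, p)
  for (gt in cfg$genotypes) for (r in seq_len(cfg$n_replicates)) {
    bs <- simulate_bisulfite(experiment$truth, gt, r)
    p <- file.path(dir, sprintf("bs_sites_%s_R%d.tsv", gt, r))
    write_tsv_table(bs, p, meta); paths <- c(paths, p)
  }
  invisible(paths)
}
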