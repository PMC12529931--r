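test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(p_err = 0.05, p_new = 0.04), "p_new")
  expect_error(sim_config(buffering_fraction = 0.7, deg_fraction = 0.5),
               "exceed 1")
  expect_error(sim_config(dropout_strength = 1.5), "dropout_strength")
  expect_error(sim_config(hl_range = c(4, 2)), "hl_range")
  expect_error(sim_config(buffering_target_corr = 0.3), "buffering_target_corr")
  expect_error(sim_config(pulse_hours = 0), "pulse")
})

test_that("truth tables satisfy the steady-state identity and are deterministic", {
  cfg <- quick_config(n_genes = 300, seed = 5L)
  tr <- simulate_truth(cfg)
  tt <- tr$turnover
  expect_true(all(tt$HL_true > 0))
  expect_lt(max(abs(tt$E_true - tt$S_true * tt$HL_true / log(2)) /
                  tt$E_true), 1e-9)
  expect_true(all(tr$methylation$rate_true >= 0 &
                    tr$methylation$rate_true <= 1))
  tr2 <- simulate_truth(cfg)
  expect_identical(tr, tr2)
})

test_that("a degenerate config yields identical conditions", {
  cfg <- quick_config(n_genes = 80, buffering_fraction = 0,
                      deg_fraction = 0, seed = 7L)
  tt <- simulate_truth(cfg)$turnover
  ref <- tt[tt$condition == tt$condition[1], ]
  for (cond in unique(tt$condition)) {
    cur <- tt[tt$condition == cond, ]
    expect_equal(cur$HL_true, ref$HL_true)
    expect_equal(cur$S_true, ref$S_true)
  }
})

test_that("buffered genes hit the target HL/S anticorrelation with stable abundance", {
  cfg <- sim_config(n_genes = 2000, timepoints = c("d0", "d4"),
                    genotypes = "WT", buffering_target_corr = -0.8,
                    buffering_fraction = 0.5, deg_fraction = 0, seed = 11L)
  tt <- simulate_truth(cfg)$turnover
  ref <- tt[tt$timepoint == "d0", ]
  alt <- tt[tt$timepoint == "d4", ]
  buf <- ref$class == "buffered"
  dh <- log2(alt$HL_true[buf] / ref$HL_true[buf])
  ds <- log2(alt$S_true[buf] / ref$S_true[buf])
  expect_gt(sum(buf), 900)
  expect_lt(abs(oracle_spearman(dh, ds) - (-0.8)), 0.05)
  de <- log2(alt$E_true[buf] / ref$E_true[buf])
  expect_true(all(abs(de) < 1))
  ## deg genes really change abundance
  dg <- ref$class == "deg"
  dde <- abs(log2(alt$E_true[dg] / ref$E_true[dg]))
  expect_true(all(dde > 1))
})

test_that("unlabeled controls convert at the background rate, labeled above it", {
  cfg <- quick_config(n_genes = 100, timepoints = "d0", genotypes = "WT",
                      library_size = 5e4, seed = 13L)
  tr <- simulate_truth(cfg)
  ctrl <- simulate_conversion_reads(tr, "WT.d0", labeled = FALSE)
  lab <- simulate_conversion_reads(tr, "WT.d0", labeled = TRUE)
  freq <- function(s) with(s$histogram, sum(k * count) / sum(n * count))
  n_u <- sum(ctrl$histogram$n * ctrl$histogram$count)
  se <- sqrt(cfg$p_err * (1 - cfg$p_err) / n_u)
  expect_lt(abs(freq(ctrl) - cfg$p_err), 3 * se)
  expect_gt(freq(lab), freq(ctrl))
  expect_error(simulate_conversion_reads(tr, "WT.d9"), "unknown condition")
})

test_that("one elapsed half-life labels half the transcript pool", {
  ## a gene with HL = t has NTR 1/2; its pooled conversion frequency is
  ## the mixture average of the two component rates
  cfg <- quick_config(n_genes = 50, timepoints = "d0", genotypes = "WT",
                      hl_range = c(1, 1), library_size = 2e5, seed = 17L)
  tr <- simulate_truth(cfg)
  lab <- simulate_conversion_reads(tr, "WT.d0", labeled = TRUE)
  f <- with(lab$histogram, sum(k * count) / sum(n * count))
  expected <- 0.5 * cfg$p_new + 0.5 * cfg$p_err
  expect_lt(abs(f - expected) / expected, 0.05)
})

test_that("dropout thinning is the identity at d = 0 and biases high-NTR genes", {
  cfg <- quick_config(n_genes = 200, timepoints = "d0", genotypes = "WT",
                      library_size = 2e5, seed = 19L)
  tr <- simulate_truth(cfg)
  s <- simulate_conversion_reads(tr, "WT.d0", labeled = TRUE)
  expect_identical(apply_dropout(s, tr, 0), s)
  expect_error(apply_dropout(s, tr, 1.2), "0, 1")
  thinned <- apply_dropout(s, tr, 0.5, seed = 3L)
  expect_true(all(thinned$counts <= s$counts))
  tt <- tr$turnover
  pi_true <- 1 - 2^(-1 / tt$HL_true[match(names(s$counts), tt$gene)])
  keep <- s$counts > 50
  ret <- log((thinned$counts[keep] + 0.5) / (s$counts[keep] + 0.5))
  slope <- coef(lm(ret ~ pi_true[keep]))[2]
  expect_lt(slope, -0.3)
})

test_that("dropout retention approaches 1 - d at NTR ~ 1", {
  cfg <- quick_config(n_genes = 40, timepoints = "d0", genotypes = "WT",
                      hl_range = c(0.05, 0.0500001), library_size = 2e5,
                      seed = 23L)
  tr <- simulate_truth(cfg)   # HL = 0.05 h << t: essentially all reads new
  s <- simulate_conversion_reads(tr, "WT.d0", labeled = TRUE)
  thinned <- apply_dropout(s, tr, 0.5, seed = 5L)
  expect_lt(abs(sum(thinned$counts) / sum(s$counts) - 0.5), 0.05)
})

test_that("bisulfite tables follow the non-conversion model", {
  cfg <- quick_config(n_genes = 30, seed = 29L)
  tr <- simulate_truth(cfg)
  ## override the methylation truth with controlled rates
  n <- 3000
  tr$methylation <- data.frame(
    site_id = sprintf("S%d", 1:n), chrom = "chr1", pos = seq_len(n),
    strand = "+", gene = "G00001",
    rate_true = rep(c(0, 1, 0.15), each = n / 3),
    dependent = FALSE, stringsAsFactors = FALSE)
  bs <- simulate_bisulfite(tr, "WT", conversion_rate = 1, seed = 7L)
  expect_true(all(bs$non_converted[tr$methylation$rate_true == 0] == 0))
  expect_true(all(bs$non_converted[tr$methylation$rate_true == 1] ==
                    bs$coverage[tr$methylation$rate_true == 1]))
  bs99 <- simulate_bisulfite(tr, "WT", conversion_rate = 0.99, seed = 7L)
  part <- tr$methylation$rate_true == 0.15
  ## expected non-conversion fraction 0.15 + 0.85 * 0.01 = 0.1585
  obs <- sum(bs99$non_converted[part]) / sum(bs99$coverage[part])
  expect_lt(abs(obs - 0.1585), 0.01)
  ## knockout abolishes dependent sites only
  tr$methylation$dependent <- tr$methylation$rate_true == 0.15
  ko <- simulate_bisulfite(tr, "KO", conversion_rate = 1, seed = 8L)
  expect_true(all(ko$non_converted[part] == 0))
  expect_error(simulate_bisulfite(tr, "WT", conversion_rate = 0), "conversion_rate")
})

test_that("experiment assembly is deterministic and writes valid tables", {
  cfg <- quick_config(n_genes = 60, library_size = 3e4, seed = 31L)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$samples, e2$samples)
  expect_equal(nrow(e1$design),
               length(cfg$genotypes) * length(cfg$timepoints) *
                 (cfg$n_replicates + 1))
  dir <- withr::local_tempdir()
  paths <- write_sim_tables(e1, dir)
  rep <- validate_tables(paths)
  expect_true(all(rep$pass))
})
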