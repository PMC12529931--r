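test_that("log2 fold change handles pseudocounts and rejects negatives", {
  expect_equal(log2fc(5, 5), 0)
  expect_equal(log2fc(1, 2), 1, tolerance = 1e-7)
  expect_equal(log2fc(3, 12), 2, tolerance = 1e-7)
  expect_equal(log2fc(0, 0, pseudocount = 0.5), 0)
  expect_error(log2fc(-1, 2), "non-negative")
})

test_that("ROPE statistic is symmetric, saturating, and antisymmetric", {
  params <- labeling_params(1)
  ## identical tight posteriors: no credible change
  A <- list(alpha = 200, beta = 200)
  expect_lt(abs(rope_statistic(A, A, params, seed = 1L)), 0.02)
  ## ~point masses four-fold apart in half-life: Delta ~ +2
  B <- list(alpha = 0.159 * 5000, beta = (1 - 0.159) * 5000)
  up <- rope_statistic(A, B, params, seed = 2L)
  expect_gt(up, 0.99)
  down <- rope_statistic(B, A, params, seed = 2L)
  expect_lt(abs(up + down), 0.02)
  ## missing posterior propagates NA
  expect_true(is.na(rope_statistic(list(alpha = NA, beta = NA), A, params)))
})

test_that("Monte Carlo ROPE agrees with a high-resolution oracle", {
  params <- labeling_params(1)
  A <- list(alpha = 30, beta = 70)
  B <- list(alpha = 45, beta = 55)
  fast <- rope_statistic(A, B, params, n_draws = 1e5, seed = 7L)
  oracle <- rope_statistic(A, B, params, n_draws = 2e6, seed = 8L)
  expect_lt(abs(fast - oracle), 0.01)
})

test_that("classification applies both gates exactly", {
  ## single-parameter changes with passing and failing ROPE gates
  expect_equal(classify_turnover_change(1.5, 0.6, 0.2, 0.1), "HL_up")
  expect_equal(classify_turnover_change(1.5, 0.2, 0.2, 0.1), "none")
  expect_equal(classify_turnover_change(-1.2, -0.5, 1.1, 0.5), "HL_and_S")
  expect_equal(classify_turnover_change(0.2, 0.9, -1.4, -0.8), "S_down")
  expect_equal(classify_turnover_change(-1.2, -0.5, 0.3, 0.2), "HL_down")
  ## boundaries are strict
  expect_equal(classify_turnover_change(1, 0.9, 0, 0), "none")
  expect_equal(classify_turnover_change(1.4, 0.45, 0, 0), "none")
  expect_equal(classify_turnover_change(NA, NA, 2, 0.9), "S_up")
  ## vectorized and order-invariant
  lfc <- c(1.5, -1.5, 0.2); rope <- c(0.6, -0.6, 0.1)
  cls <- classify_turnover_change(lfc, rope, rep(0, 3), rep(0, 3))
  perm <- c(3, 1, 2)
  expect_equal(classify_turnover_change(lfc[perm], rope[perm],
                                        rep(0, 3), rep(0, 3)), cls[perm])
})

test_that("the Wald-type DE test is calibrated under the null and finds real changes", {
  set.seed(301)
  ng <- 2000
  mu <- exp(rnorm(ng, 5, 1))
  counts <- matrix(rpois(ng * 6, rep(mu, 6)), ncol = 6,
                   dimnames = list(sprintf("g%04d", 1:ng), paste0("s", 1:6)))
  design <- data.frame(sample = paste0("s", 1:6),
                       condition = rep(c("A", "B"), each = 3),
                       stringsAsFactors = FALSE)
  de <- steady_state_de(counts, design, "A", "B")
  frac <- mean(de$de_p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  ## identical replicate sets across conditions
  c2 <- cbind(counts[, 1:3], counts[, 1:3])
  colnames(c2) <- paste0("s", 1:6)
  de0 <- steady_state_de(c2, design, "A", "B")
  expect_equal(de0$lfc_E, rep(0, ng))
  expect_true(all(de0$de_p > 0.99))
  ## genuine four-fold change at low dispersion
  set.seed(302)
  mu2 <- rep(400, 300)
  ca <- matrix(rpois(300 * 3, mu2), ncol = 3)
  cb <- matrix(rpois(300 * 3, mu2 * 4), ncol = 3)
  cnt <- cbind(ca, cb)
  dimnames(cnt) <- list(sprintf("g%03d", 1:300), paste0("s", 1:6))
  ## equal-size libraries: supply unit factors so the global shift is kept
  de4 <- steady_state_de(cnt, design, "A", "B",
                         factors = setNames(rep(1, 6), paste0("s", 1:6)))
  expect_lt(abs(median(de4$lfc_E) - 2), 0.1)
  expect_gt(mean(de4$de_q < 0.05), 0.95)
  ## single replicate: no inference
  d1 <- design[c(1, 4), ]
  de1 <- steady_state_de(counts[, c(1, 4)], d1, "A", "B")
  expect_true(all(is.na(de1$de_p)))
  expect_error(steady_state_de(counts, design, "A", "Z"), "undefined")
})

test_that("DEG decomposition partitions the DEG set", {
  ch <- data.frame(gene = sprintf("g%d", 1:8),
                   lfc_E = c(2, -2, 1.5, 2, 0.2, 2, -1.8, 2),
                   de_q = c(0.001, 0.001, 0.01, 0.01, 0.001, 0.2, 0.01, 0.01),
                   class = c("S_up", "S_down", "HL_up", "HL_and_S", "S_up",
                             "S_up", "none", "S_down"),
                   stringsAsFactors = FALSE)
  out <- deg_decomposition(ch)
  expect_equal(attr(out, "n_deg"), 6L)
  expect_equal(sum(out), 1)
  expect_equal(unname(out["S_only"]), 3 / 6)
  expect_equal(unname(out["HL_only"]), 1 / 6)
  expect_equal(unname(out["both"]), 1 / 6)
  ## all-S fixture
  ch2 <- ch[ch$class %in% c("S_up", "S_down") & ch$de_q < 0.05 &
              abs(ch$lfc_E) > 1, ]
  expect_equal(as.vector(deg_decomposition(ch2)), c(1, 0, 0, 0))
  expect_warning(out0 <- deg_decomposition(ch[0, ]), "no differentially")
  expect_equal(sum(out0), 0)
})

test_that("turnover change assembly flags stable genes and respects gates", {
  cfg <- quick_config(n_genes = 120, library_size = 1.2e5, seed = 303L)
  exp <- simulate_experiment(cfg)
  rates <- global_rates(cfg$p_err, cfg$p_new)
  params <- labeling_params(1)
  labs <- exp$design$sample[exp$design$labeled]
  nt <- lapply(setNames(nm = labs), function(s)
    estimate_ntr_table(exp$samples[[s]], rates))
  counts <- count_matrix(exp)
  tt <- quantify(nt, counts, exp$design, params)
  conds <- unique(exp$design$condition[exp$design$labeled])
  po <- lapply(setNames(nm = conds), function(cn) {
    smp <- exp$design$sample[exp$design$labeled & exp$design$condition == cn]
    estimate_ntr_table(exp$samples[smp], rates)
  })
  de <- steady_state_de(counts, exp$design, "WT.d0", "WT.d4")
  ch <- turnover_changes(tt, po, de, "WT.d0", "WT.d4", params,
                         n_draws = 3000, seed = 5L)
  expect_true(all(ch$class %in% c("HL_up", "HL_down", "S_up", "S_down",
                                  "HL_and_S", "none")))
  expect_true(all(abs(ch$rope_HL) <= 1, na.rm = TRUE))
  gate <- !is.na(ch$lfc_HL) & abs(ch$lfc_HL) > 1 &
    !is.na(ch$rope_HL) & abs(ch$rope_HL) > 0.45
  expect_true(all(ch$class[gate] %in% c("HL_up", "HL_down", "HL_and_S")))
  expect_equal(ch$stable,
               !is.na(ch$lfc_E) & abs(ch$lfc_E) < 1 &
                 !is.na(ch$de_q) & ch$de_q > 0.05)
  ## same seed reproduces the ROPE statistics exactly
  ch2 <- turnover_changes(tt, po, de, "WT.d0", "WT.d4", params,
                          n_draws = 3000, seed = 5L)
  expect_identical(ch$rope_HL, ch2$rope_HL)
})

test_that("BH adjustment matches the literal step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(305)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
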