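## small site-table builder: one gene with `n_bg` unmethylated background
## cytosines plus explicit test sites
site_fixture <- function(test_sites, n_bg = 20, bg_cov = 50, bg_nc = 0,
                         gene = "G1") {
  bg <- data.frame(chrom = "chr1", pos = 1000 + seq_len(n_bg), strand = "+",
                   gene = gene, coverage = bg_cov, non_converted = bg_nc,
                   stringsAsFactors = FALSE)
  rbind(test_sites, bg)
}

test_that("site filters follow the coverage, count and rate rules", {
  ts <- data.frame(chrom = "chr1", pos = c(1, 2, 3, 4, 5), strand = "+",
                   gene = "G1",
                   coverage = c(20, 21, 100, 100, 50),
                   non_converted = c(15, 15, 0, 2, 25),
                   stringsAsFactors = FALSE)
  called <- call_sites(site_fixture(ts))
  got <- called[match(1:5, called$pos), ]
  expect_equal(got$passes_filters,
               c(FALSE,  # coverage not strictly > 20
                 TRUE,
                 FALSE,  # no non-converted reads
                 FALSE,  # below the C-cutoff of 3
                 TRUE))
  expect_true(all(is.na(got$p[!got$passes_filters])))
  ## rate gate is strict at 0.1
  ts2 <- data.frame(chrom = "chr1", pos = 1:2, strand = "+", gene = "G1",
                    coverage = c(100, 100), non_converted = c(10, 11),
                    stringsAsFactors = FALSE)
  c2 <- call_sites(site_fixture(ts2))
  expect_equal(c2$passes_filters[match(1:2, c2$pos)], c(FALSE, TRUE))
  expect_error(call_sites(data.frame(chrom = "c", pos = 1, strand = "+",
                                     gene = "g", coverage = 5,
                                     non_converted = 9)), "exceeds")
})

test_that("Fisher p-values match the brute-force hypergeometric tail", {
  ## worked case: 25/50 non-converted at a 990/10 gene background
  ts <- data.frame(chrom = "chr1", pos = 1, strand = "+", gene = "G1",
                   coverage = 50, non_converted = 25,
                   stringsAsFactors = FALSE)
  sites <- site_fixture(ts, n_bg = 20, bg_cov = 50, bg_nc = 0)
  sites$non_converted[sites$pos > 1000] <-
    c(rep(1, 10), rep(0, 10))       # 10 non-converted in 1000 bg reads
  called <- call_sites(sites)
  p <- called$p[called$pos == 1]
  expect_lt(p, 1e-6)
  expect_equal(p, oracle_fisher_greater(25, 25, 10, 990), tolerance = 1e-9)
  ## randomized small tables, margins <= 200
  set.seed(501)
  for (i in 1:15) {
    cov <- sample(25:60, 1); nc <- sample(3:15, 1)
    bgt <- sample(80:140, 1); bgn <- sample(0:5, 1)
    ts <- data.frame(chrom = "chr1", pos = 1, strand = "+", gene = "G1",
                     coverage = cov, non_converted = min(nc, cov),
                     stringsAsFactors = FALSE)
    sites <- site_fixture(ts, n_bg = 1, bg_cov = bgt, bg_nc = bgn)
    called <- call_sites(sites, min_coverage = 20, c_cutoff = 1,
                         min_rate = 0)
    p <- called$p[called$pos == 1]
    nc_ <- min(nc, cov)
    oracle <- oracle_fisher_greater(nc_, cov - nc_, bgn, bgt - bgn)
    expect_equal(p, oracle, tolerance = 1e-9)
  }
})

test_that("intergenic sites fall back to the conservative conversion rate", {
  ts <- data.frame(chrom = "chr2", pos = 7, strand = "-", gene = NA,
                   coverage = 60, non_converted = 30,
                   stringsAsFactors = FALSE)
  called <- call_sites(site_fixture(ts))
  p <- called$p[called$chrom == "chr2"]
  expect_false(is.na(p))
  ## background: fallback_total = 1000 at rate 0.9 -> 100 non-converted
  expect_equal(p, oracle_fisher_greater(30, 30, 100, 900), tolerance = 1e-9)
})

test_that("consensus requires significance in every replicate", {
  mk <- function(pos_sig) {
    ts <- data.frame(chrom = "chr1", pos = c(1, 2), strand = "+", gene = "G1",
                     coverage = 100,
                     non_converted = ifelse(c(1, 2) %in% pos_sig, 50, 1),
                     stringsAsFactors = FALSE)
    call_sites(site_fixture(ts))
  }
  both <- consensus_sites(list(mk(c(1, 2)), mk(c(1, 2))))
  expect_setequal(both$pos, c(1, 2))
  one <- consensus_sites(list(mk(c(1, 2)), mk(1)))
  expect_equal(one$pos, 1)
  single <- consensus_sites(list(mk(2)))
  expect_equal(single$pos, 2)
  expect_equal(nrow(consensus_sites(list())), 0)
})

test_that("dependent sites are the wild-type-only consensus", {
  wt <- data.frame(chrom = "chr1", pos = c(1, 2, 3), strand = "+",
                   gene = c("a", "b", "c"), mean_rate = 0.5,
                   n_replicates = 2, stringsAsFactors = FALSE)
  ko <- wt[2, ]
  dep <- dependent_sites(wt, ko)
  expect_equal(dep$pos, c(1, 3))
  expect_equal(nrow(dependent_sites(wt, wt)), 0)
  expect_equal(nrow(dependent_sites(wt, wt[0, ])), 3)
})

test_that("a simulated knockout recovers exactly the abolished sites", {
  cfg <- quick_config(n_genes = 50, bs_n_sites = 300,
                      bs_coverage_mean = 80, seed = 503L)
  tr <- simulate_truth(cfg)
  ## make truth clean: strong sites, decent coverage
  m <- tr$methylation
  strong <- m$rate_true > 0
  called_wt <- lapply(1:2, function(r)
    call_sites(simulate_bisulfite(tr, "WT", r)))
  called_ko <- lapply(1:2, function(r)
    call_sites(simulate_bisulfite(tr, "KO", r)))
  dep <- dependent_sites(consensus_sites(called_wt),
                         consensus_sites(called_ko))
  key <- function(d) paste(d$chrom, d$pos, d$strand)
  truth_dep <- key(m[m$dependent & m$rate_true >= 0.3, ])
  ## every confidently detectable truly dependent site is recovered
  cov_ok <- sapply(called_wt, function(d)
    d$coverage[match(truth_dep, key(d))] >= 50)
  detectable <- truth_dep[rowSums(cov_ok) == 2]
  expect_gt(length(detectable), 5)
  expect_true(all(detectable %in% key(dep)))
  ## and nothing truly independent shows up as dependent
  indep <- key(m[!m$dependent, ])
  expect_lt(mean(key(dep) %in% indep), 0.1)
})

test_that("gene-level overlap partitions the union", {
  sites <- data.frame(gene = c("a", "b", "b", NA), stringsAsFactors = FALSE)
  ch <- data.frame(gene = c("b", "c", "d", "e"),
                   class = c("HL_up", "S_down", "HL_and_S", "none"),
                   stringsAsFactors = FALSE)
  ov <- overlap_with_dynamics(sites, ch)
  expect_equal(sum(ov$regions), ov$n_union)
  expect_equal(unname(ov$regions["m5c_only"]), 1)   # a
  expect_equal(unname(ov$regions["m5c_HL"]), 1)     # b
  expect_equal(unname(ov$regions["S_only"]), 1)     # c
  expect_equal(unname(ov$regions["HL_S"]), 1)       # d
  expect_equal(ov$frac_altered_with_m5c, 1 / 3)
  ## disjoint sets
  ov2 <- overlap_with_dynamics(data.frame(gene = "z"), ch)
  expect_equal(unname(ov2$regions["m5c_HL_S"]), 0)
  expect_equal(unname(ov2$regions["m5c_only"]), 1)
})

test_that("BED export shifts to 0-based half-open coordinates", {
  sites <- data.frame(chrom = "chr1", pos = c(5, 10), strand = c("+", "-"),
                      gene = c("g", NA), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  sites_to_bed(sites, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, c(4, 9))
  expect_equal(bed$V3, c(5, 10))
})
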