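#' Run the full turnover-dynamics pipeline on synthetic data
#'
#' End-to-end orchestration: simulate an experiment from a [sim_config()],
#' estimate the global conversion rates (background from the unlabeled
#' controls, labeled rate by EM), estimate per-sample and per-condition
#' NTR posteriors, quantify half-lives and synthesis rates (with 4sU
#' dropout correction when the generator applied dropout), classify
#' turnover changes for every contrast, quantify buffering and bootstrap
#' median differences, call bisulfite m5C consensus and
#' methyltransferase-dependent sites, cluster half-life time courses, and
#' write all result tables plus a run manifest to `out_dir`. Fully
#' deterministic given the config seed: a rerun produces byte-identical
#' files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param contrasts optional data.frame (condition_a, condition_b);
#'   defaults to each later timepoint versus the first within the first
#'   genotype, plus second-vs-first genotype at every timepoint. Validated
#'   against the design before any computation.
#' @param lfc_threshold,rope_threshold,rope_width classification gates.
#' @param rope_draws Monte Carlo draws per gene for the ROPE statistics.
#' @param bootstrap_iterations bootstrap iterations per contrast.
#' @param fdr consensus-site FDR threshold.
#' @param k_clusters k for the half-life profile clustering.
#' @return invisibly, a list with the main in-memory results (`turnover`,
#'   `changes`, `buffering`, `bootstrap`, `consensus`, `dependent`,
#'   `clusters`, `rates`, `paths`).
#' @export
run_pipeline <- function(config, out_dir, contrasts = NULL,
                         lfc_threshold = 1, rope_threshold = 0.45,
                         rope_width = 0.25, rope_draws = 2e4,
                         bootstrap_iterations = 20000, fdr = 0.05,
                         k_clusters = 8) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))

  conds <- as.vector(outer(config$genotypes, config$timepoints,
                           condition_label))
  if (is.null(contrasts)) {
    g1 <- config$genotypes[1]
    contrasts <- data.frame(
      condition_a = condition_label(g1, config$timepoints[1]),
      condition_b = condition_label(g1, config$timepoints[-1]),
      stringsAsFactors = FALSE)
    if (length(config$genotypes) > 1) {
      g2 <- config$genotypes[2]
      contrasts <- rbind(contrasts, data.frame(
        condition_a = condition_label(g1, config$timepoints),
        condition_b = condition_label(g2, config$timepoints),
        stringsAsFactors = FALSE))
    }
  }
  bad <- setdiff(unlist(contrasts[, c("condition_a", "condition_b")]), conds)
  if (length(bad))
    stop("contrast references undefined condition(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  meta <- list(seed = config$seed, lfc_threshold = lfc_threshold,
               rope_threshold = rope_threshold, rope_width = rope_width,
               rope_draws = rope_draws, fdr = fdr,
               bootstrap_iterations = bootstrap_iterations)
  paths <- character()
  emit <- function(x, name, extra = NULL) {
    p <- file.path(out_dir, name)
    write_tsv_table(x, p, c(meta, extra))
    paths <<- c(paths, p)
    p
  }

  message("simulating experiment (", config$n_genes, " genes)")
  exp <- stage("simulate", simulate_experiment(config))
  stage("simulate", {
    emit(exp$truth$turnover, "truth.tsv")
    emit(exp$truth$annotation, "annotation.tsv")
    emit(exp$design, "design.tsv")
  })
  counts <- count_matrix(exp)
  stage("simulate", emit(data.frame(gene = rownames(counts), counts,
                                    check.names = FALSE), "counts.tsv"))

  message("estimating global conversion rates")
  rates <- stage("estimate-rates", {
    ctrl <- exp$samples[!vapply(exp$samples, `[[`, TRUE, "labeled")]
    lab <- exp$samples[vapply(exp$samples, `[[`, TRUE, "labeled")]
    p_err <- estimate_error_rate(ctrl)
    p_new <- estimate_conversion_rate(lab, p_err)
    global_rates(p_err, as.numeric(p_new))
  })
  stage("estimate-rates",
        emit(data.frame(p_err = rates$p_err, p_new = rates$p_new),
             "global_rates.tsv"))

  message("estimating NTR posteriors")
  params <- labeling_params(t = config$pulse_hours)
  lab_design <- exp$design[exp$design$labeled, ]
  ntr_tables <- stage("ntr", {
    tabs <- lapply(lab_design$sample, function(s)
      estimate_ntr_table(exp$samples[[s]], rates))
    names(tabs) <- lab_design$sample
    tabs
  })
  cond_posteriors <- stage("ntr", {
    po <- lapply(unique(lab_design$condition), function(cn) {
      smp <- lab_design$sample[lab_design$condition == cn]
      estimate_ntr_table(exp$samples[smp], rates)
    })
    names(po) <- unique(lab_design$condition)
    po
  })
  stage("ntr", {
    flat <- do.call(rbind, lapply(names(ntr_tables), function(s) {
      d <- ntr_tables[[s]]
      attr(d, "estimates") <- NULL
      cbind(sample = s, d, stringsAsFactors = FALSE)
    }))
    emit(flat, "ntr.tsv")
  })

  message("quantifying turnover")
  turnover <- stage("quantify",
                    quantify(ntr_tables, counts, exp$design, params,
                             dropout_correct = config$dropout_strength > 0))
  stage("quantify", emit(as.data.frame(turnover), "turnover.tsv"))

  message("classifying turnover changes (", nrow(contrasts), " contrasts)")
  changes <- list(); buffering <- list(); boots <- list()
  for (i in seq_len(nrow(contrasts))) {
    ca <- contrasts$condition_a[i]; cb <- contrasts$condition_b[i]
    lbl <- paste(cb, "vs", ca)
    ch <- stage("classify", {
      de <- steady_state_de(counts, exp$design, ca, cb)
      turnover_changes(turnover, cond_posteriors, de, ca, cb, params,
                       lfc_threshold, rope_threshold, rope_width,
                       n_draws = rope_draws,
                       seed = child_seed(config$seed, paste("rope", lbl)))
    })
    changes[[lbl]] <- ch
    buffering[[lbl]] <- stage("buffering", {
      bc <- buffering_correlation(ch)
      data.frame(contrast = lbl, R = bc$R, p = bc$p, n = bc$n,
                 stringsAsFactors = FALSE)
    })
    boots[[lbl]] <- stage("bootstrap", {
      do.call(rbind, lapply(c(HL = "HL_hours", S = "S_per_h"), function(col) {
        xa <- turnover[turnover$condition == ca, col]
        xb <- turnover[turnover$condition == cb, col]
        b <- bootstrap_median_difference(
          xa, xb, iterations = bootstrap_iterations,
          seed = child_seed(config$seed, paste("boot", lbl, col)))
        data.frame(contrast = lbl, metric = col, observed = b$observed,
                   ci95_lo = b$ci95[1], ci95_hi = b$ci95[2],
                   ci99_lo = b$ci99[1], ci99_hi = b$ci99[2],
                   ci999_lo = b$ci999[1], ci999_hi = b$ci999[2],
                   label = b$label, stringsAsFactors = FALSE)
      }))
    })
  }
  all_changes <- do.call(rbind, lapply(changes, as.data.frame))
  rownames(all_changes) <- NULL
  emit(all_changes, "turnover_changes.tsv")
  emit(do.call(rbind, buffering), "buffering.tsv")
  bt <- do.call(rbind, boots); rownames(bt) <- NULL
  emit(bt, "bootstrap.tsv")

  message("calling m5C sites")
  m5c <- stage("m5c", {
    consensus <- list()
    for (gt in config$genotypes) {
      called <- lapply(seq_len(config$n_replicates), function(r) {
        tab <- simulate_bisulfite(exp$truth, gt, r)
        call_sites(tab)
      })
      consensus[[gt]] <- consensus_sites(called, fdr = fdr)
    }
    dep <- if (length(config$genotypes) > 1)
      dependent_sites(consensus[[1]], consensus[[2]]) else consensus[[1]][0, ]
    list(consensus = consensus, dependent = dep)
  })
  for (gt in names(m5c$consensus))
    emit(m5c$consensus[[gt]], sprintf("m5c_consensus_%s.tsv", gt))
  emit(m5c$dependent, "m5c_dependent.tsv")

  message("clustering half-life profiles")
  clusters <- stage("cluster", {
    g1_design <- exp$design[exp$design$genotype == config$genotypes[1] &
                              exp$design$labeled, ]
    pm <- profile_matrix(turnover, g1_design)
    pm <- pm[is.finite(rowSums(pm)), , drop = FALSE]
    k <- min(k_clusters, max(1, nrow(pm) - 1))
    suppressWarnings(zscore_cluster(pm, k = k,
                                    seed = child_seed(config$seed, "cluster")))
  })
  emit(data.frame(gene = names(clusters$cluster),
                  cluster = as.integer(clusters$cluster)),
       "clusters.tsv")

  manifest <- data.frame(
    key = c("package", "version", "seed", "n_genes", "conditions",
            "contrasts", "lfc_threshold", "rope_threshold", "rope_width",
            "rope_draws", "bootstrap_iterations", "fdr", "k_clusters"),
    value = c("tucdyn", as.character(utils::packageVersion("tucdyn")),
              config$seed, config$n_genes, paste(conds, collapse = ","),
              paste(paste(contrasts$condition_b, contrasts$condition_a,
                          sep = "|"), collapse = ","),
              lfc_threshold, rope_threshold, rope_width, rope_draws,
              bootstrap_iterations, fdr, k_clusters),
    stringsAsFactors = FALSE)
  emit(manifest, "manifest.tsv")

  invisible(list(truth = exp$truth, turnover = turnover, changes = changes,
                 buffering = do.call(rbind, buffering), bootstrap = bt,
                 consensus = m5c$consensus, dependent = m5c$dependent,
                 clusters = clusters, rates = rates, paths = paths))
}

#' Validate pipeline table files
#'
#' Schema and invariant checks for the tab-delimited formats the pipeline
#' reads and writes. The table type is recognized from the header columns;
#' per-type invariants (k <= n, non_converted <= coverage, positive
#' half-lives, the steady-state identity of truth tables, ...) are checked
#' row-wise and the first violating row reported.
#'
#' @param paths character vector of file paths.
#' @return data.frame: file, type, rows, pass, message.
#' @export
validate_tables <- function(paths) {
  check_one <- function(path) {
    if (!file.exists(path))
      return(list(type = "missing", rows = 0L, pass = FALSE,
                  message = "file not found"))
    tab <- tryCatch(read_tsv_table(path), error = function(e)
      conditionMessage(e))
    if (is.character(tab))
      return(list(type = "unreadable", rows = 0L, pass = FALSE,
                  message = paste("parse error:", tab)))
    cols <- names(tab)
    fail_row <- function(type, bad, what) {
      if (any(bad, na.rm = TRUE))
        list(type = type, rows = nrow(tab), pass = FALSE,
             message = sprintf("%s violated at row %d", what,
                               which(bad)[1]))
      else list(type = type, rows = nrow(tab), pass = TRUE, message = "ok")
    }
    if (all(c("gene", "n", "k", "count") %in% cols))
      return(fail_row("conversion_histogram",
                      tab$k > tab$n | tab$k < 0 | tab$count < 0,
                      "0 <= k <= n and count >= 0"))
    if (all(c("coverage", "non_converted") %in% cols))
      return(fail_row("bs_sites",
                      tab$non_converted > tab$coverage |
                        tab$non_converted < 0,
                      "0 <= non_converted <= coverage"))
    if (all(c("HL_true", "S_true", "E_true") %in% cols))
      return(fail_row("truth",
                      tab$HL_true <= 0 |
                        abs(tab$E_true - tab$S_true * tab$HL_true / log(2)) >
                        1e-6 * pmax(tab$E_true, 1e-12),
                      "HL_true > 0 and E = S*HL/ln2"))
    if (all(c("gene", "gc_fraction", "utr3_length") %in% cols))
      return(fail_row("annotation",
                      tab$gc_fraction < 0 | tab$gc_fraction > 1 |
                        tab$utr3_length < 0,
                      "gc in [0,1], utr3_length >= 0"))
    if ("gene" %in% cols && ncol(tab) > 1 &&
        all(vapply(tab[-1], is.numeric, TRUE)))
      return(fail_row("counts", Reduce(`|`, lapply(tab[-1], function(x)
        x < 0)), "counts >= 0"))
    list(type = "unknown", rows = nrow(tab), pass = FALSE,
         message = paste("unrecognized schema; columns:",
                         paste(cols, collapse = ",")))
  }
  res <- lapply(paths, check_one)
  data.frame(file = paths,
             type = vapply(res, `[[`, "", "type"),
             rows = vapply(res, function(r) as.integer(r$rows), 0L),
             pass = vapply(res, `[[`, TRUE, "pass"),
             message = vapply(res, `[[`, "", "message"),
             stringsAsFactors = FALSE)
}
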