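#' @keywords internal
#' @import stats
"_PACKAGE"

## numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## run expr with a local RNG state seeded by `seed`; the caller's RNG
## stream is untouched, so pipeline stages can be reordered freely
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

## derive a reproducible child seed from a base seed and a label,
## kept within 32-bit integer range
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

stopifnot_prob <- function(x, name, open = TRUE) {
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (any(!is.finite(x)) || bad)
    stop(sprintf("'%s' must be a probability in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  invisible(x)
}

#' Write a TSV table with a metadata comment header
#'
#' All pipeline outputs are tab-delimited with a leading block of
#' `# key=value` comment lines recording the package version, seed and
#' thresholds, so that a rerun with identical seeds is byte-identical.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @param meta named list or character vector of metadata to record.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path, meta = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  header <- c(paste0("# tucdyn=", as.character(utils::packageVersion("tucdyn"))))
  if (length(meta))
    header <- c(header, paste0("# ", names(meta), "=",
                               vapply(meta, function(v) paste(v, collapse = ","), "")))
  writeLines(header, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv_table()]
#'
#' @param path file path; `#`-prefixed comment lines are skipped.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
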