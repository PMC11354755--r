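#' @importFrom stats median p.adjust rpois rbinom runif rlnorm sd t.test setNames
#' @importFrom utils read.table write.table
#' @importFrom rlang .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-sided Welch t-test with explicit handling of degenerate inputs
#'
#' Tests whether `mut` exceeds `wt` (alternative: greater) using an
#' unequal-variance t-test. When both groups have zero variance the Welch
#' statistic is undefined; the limiting p-value is reported instead (0 when
#' the mutant mean is larger, 1 when smaller, 0.5 when the means tie) and
#' the result is flagged degenerate.
#'
#' @param mut,wt numeric vectors of replicate values.
#' @param alternative one of "greater", "less", "two.sided".
#' @return list with `p_value`, `statistic` (NA when degenerate) and
#'   `degenerate` flag.
#' @keywords internal
welch_test <- function(mut, wt, alternative = "greater") {
  mut <- mut[is.finite(mut)]
  wt <- wt[is.finite(wt)]
  if (length(mut) < 2L || length(wt) < 2L) {
    stop("welch_test requires at least two finite values per group")
  }
  v_m <- stats::var(mut)
  v_w <- stats::var(wt)
  if (v_m == 0 && v_w == 0) {
    d <- mean(mut) - mean(wt)
    p <- switch(alternative,
      greater   = if (d > 0) 0 else if (d < 0) 1 else 0.5,
      less      = if (d < 0) 0 else if (d > 0) 1 else 0.5,
      two.sided = if (d != 0) 0 else 1
    )
    return(list(p_value = p, statistic = NA_real_, degenerate = TRUE))
  }
  res <- tryCatch(
    stats::t.test(mut, wt, alternative = alternative, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res)) {
    d <- mean(mut) - mean(wt)
    p <- switch(alternative,
      greater   = if (d > 0) 0 else if (d < 0) 1 else 0.5,
      less      = if (d < 0) 0 else if (d > 0) 1 else 0.5,
      two.sided = if (d != 0) 0 else 1
    )
    return(list(p_value = p, statistic = NA_real_, degenerate = TRUE))
  }
  list(p_value = unname(res$p.value), statistic = unname(res$statistic),
       degenerate = FALSE)
}

#' Write a data frame as TSV with a commented parameter header
#'
#' Every pipeline output table carries the exact parameter values used, as
#' `# key=value` comment lines, so printed numbers remain auditable.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param params named list of parameters recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_header <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(params)) {
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, function(x) paste(format(x), collapse = ","),
                              character(1))), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_header()], ignoring header comments
#' @param path file path.
#' @return data frame.
#' @export
read_tsv_header <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

## Deterministic sub-seed derivation; keeps results < 2^31 for any small
## base seed and independent across (genotype, replicate) streams.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 13L + 7919L * as.integer(stream)
}

## Run code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
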