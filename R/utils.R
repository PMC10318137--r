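#' @import data.table
#' @importFrom stats rnorm runif rpois rexp rbinom median sd var cor glm
#'   binomial plogis qnorm pchisq pt qt dbinom predict coef lm as.formula
#'   complete.cases quantile setNames
#' @importFrom utils head
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".BY", "song_id", "participant_id", "t_sec", "immersion",
  "familiar", "label", "avg", "minlen", "len", "n_p", "med", "sample_sd",
  "total_immersion", "avg_immersion", "peak_immersion", "n_participants",
  ".row", "d_mean", "d_sd", "d_r", "col_a", "col_b", "ok", "gap_at",
  "..cols", "..keep", "..shared", "t_len"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a top-level seed
#'
#' Stage seeds are a deterministic function of the top-level seed and the
#' stage name, so adding or reordering pipeline stages never perturbs the
#' random stream of earlier stages.
#'
#' @param seed integer top-level seed.
#' @param stage character stage name.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; all arithmetic stays < 2^53
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer((abs(seed) %% m * 1000003 + h) %% (m - 1) + 1)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

# md5 digest of a data.frame's CSV serialization (provenance tracking)
table_digest <- function(df) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  data.table::fwrite(as.data.table(df), tmp)
  unname(tools::md5sum(tmp))
}

normalize_label <- function(x) {
  out <- tolower(trimws(as.character(x)))
  bad <- !out %in% c("hit", "flop")
  if (any(bad)) {
    stop("song labels must be 'hit' or 'flop'; offending values: ",
         paste(unique(out[bad]), collapse = ", "), call. = FALSE)
  }
  out
}
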