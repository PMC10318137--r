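#' Configuration for sequential conditional synthesis
#'
#' @param n_rows number of synthetic rows to draw (default 10,000).
#' @param visit_order column visit order; the first column is drawn from
#'   its source marginal by bootstrap, each later column from a
#'   recursive-partitioning tree of that column on the previously
#'   synthesized columns. The class label goes first so both classes are
#'   represented proportionally.
#' @param method_per_column optional named character vector overriding the
#'   per-column method: `"bootstrap"`, `"tree_donor"`, or `"normal"` (a
#'   linear-Gaussian conditional draw for continuous columns, available
#'   when a source is too small to grow trees).
#' @param min_leaf minimum donor rows per tree leaf (default 2).
#' @param seed integer seed.
#' @return a validated `synthesis_config` list.
#' @export
synthesis_config <- function(n_rows = 10000L,
                             visit_order = c("label", "avg_immersion",
                                             "retreat", "peak_immersion"),
                             method_per_column = NULL,
                             min_leaf = 2L,
                             seed = 1L) {
  assert_scalar_number(n_rows, "n_rows", lo = 1)
  assert_scalar_number(min_leaf, "min_leaf", lo = 1)
  if (anyDuplicated(visit_order)) {
    stop("visit_order must list each column exactly once", call. = FALSE)
  }
  if (!is.null(method_per_column)) {
    bad <- setdiff(method_per_column, c("bootstrap", "tree_donor", "normal"))
    if (length(bad)) stop("unknown synthesis method: ", bad[1], call. = FALSE)
  }
  structure(list(n_rows = as.integer(n_rows), visit_order = visit_order,
                 method_per_column = method_per_column,
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "synthesis_config")
}

# Route rows of `newdata` down a fitted rpart tree to leaf node numbers.
# Only primary continuous splits are used (the synthesis trees are fitted
# with maxsurrogate = maxcompete = 0 on numeric predictors). Verified at
# fit time against rpart's own training-row assignment (`fit$where`).
rpart_leaf_of <- function(fit, newdata) {
  frame <- fit$frame
  nodes <- as.integer(row.names(frame))
  is_leaf <- frame$var == "<leaf>"
  if (all(is_leaf)) return(rep.int(nodes[1L], nrow(newdata)))
  splits <- fit$splits
  split_row <- integer(nrow(frame))
  split_row[!is_leaf] <- seq_len(sum(!is_leaf))
  out <- integer(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    node <- 1L
    repeat {
      fr <- match(node, nodes)
      if (is_leaf[fr]) break
      sp <- splits[split_row[fr], , drop = TRUE]
      x <- newdata[[as.character(frame$var[fr])]][i]
      goes_left <- if (sp[["ncat"]] < 0) x < sp[["index"]] else x >= sp[["index"]]
      node <- 2L * node + !goes_left
    }
    out[i] <- node
  }
  out
}

synth_one_column <- function(col, done_cols, source, synth, method, min_leaf) {
  n_rows <- nrow(synth)
  src_vals <- source[[col]]
  if (method == "bootstrap" || length(done_cols) == 0L) {
    return(src_vals[sample.int(length(src_vals), n_rows, replace = TRUE)])
  }
  if (method == "normal") {
    fml <- as.formula(paste(col, "~", paste(done_cols, collapse = "+")))
    fit <- lm(fml, data = source)
    mu <- predict(fit, newdata = synth)
    sig <- sqrt(sum(fit$residuals^2) / max(1L, fit$df.residual))
    return(rnorm(n_rows, mu, sig))
  }
  # tree_donor: fit column ~ previous columns on the source, route each
  # synthetic row to a leaf, sample a donor value uniformly from that leaf
  fml <- as.formula(paste(col, "~", paste(done_cols, collapse = "+")))
  ctrl <- rpart::rpart.control(cp = 0, minsplit = 2L * min_leaf,
                               minbucket = min_leaf, xval = 0,
                               maxcompete = 0, maxsurrogate = 0)
  fit <- rpart::rpart(fml, data = source, method = "anova", control = ctrl)
  train_nodes <- as.integer(row.names(fit$frame))[fit$where]
  routed <- rpart_leaf_of(fit, source)
  if (!identical(routed, train_nodes)) {
    stop("internal error: leaf routing disagrees with rpart on source rows",
         call. = FALSE)
  }
  leaves <- rpart_leaf_of(fit, synth)
  out <- numeric(n_rows)
  for (leaf in unique(leaves)) {
    donors <- src_vals[train_nodes == leaf]
    sel <- leaves == leaf
    out[sel] <- donors[sample.int(length(donors), sum(sel), replace = TRUE)]
  }
  out
}

#' Inflate a feature table by sequential conditional synthesis
#'
#' Synthesizes `config$n_rows` rows column by column in `visit_order`: the
#' first column is a bootstrap draw from its source marginal; each later
#' column is drawn by fitting a regression tree of that column on the
#' previously synthesized columns over the source and sampling a donor
#' value uniformly from the leaf each synthetic row falls into. Because all
#' draws are donor-based, every synthetic value occurs somewhere in the
#' source column, so synthetic ranges never exceed source ranges.
#'
#' @param source feature table (>= 2 rows, no missing values) containing
#'   all `visit_order` columns.
#' @param config a [synthesis_config()].
#' @return a `data.table` of `n_rows` synthetic rows with attributes
#'   `provenance` (source digest, config, seed).
#' @export
synthesize_table <- function(source, config = synthesis_config()) {
  stopifnot(inherits(config, "synthesis_config"))
  source <- as.data.table(source)
  cols <- config$visit_order
  missing_cols <- setdiff(cols, names(source))
  if (length(missing_cols)) {
    stop("source lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(source) < 2L) stop("source must have at least 2 rows", call. = FALSE)
  src <- source[, ..cols]
  if (anyNA(src)) stop("source contains missing values", call. = FALSE)

  # character/factor columns are synthesized on a numeric coding and
  # decoded afterwards (donor draws make the coding lossless)
  codecs <- list()
  for (col in cols) {
    if (!is.numeric(src[[col]])) {
      lev <- sort(unique(as.character(src[[col]])))
      codecs[[col]] <- lev
      src[[col]] <- match(as.character(src[[col]]), lev)
    }
  }

  set.seed(config$seed)
  synth <- data.table(.row = seq_len(config$n_rows))
  done <- character(0)
  for (col in cols) {
    method <- config$method_per_column[[col]] %||%
      (if (length(done) == 0L) "bootstrap" else "tree_donor")
    synth[[col]] <- synth_one_column(col, done, src, synth, method,
                                     config$min_leaf)
    done <- c(done, col)
  }
  synth[, .row := NULL]
  for (col in names(codecs)) synth[[col]] <- codecs[[col]][synth[[col]]]

  setattr(synth, "provenance",
          list(source_digest = table_digest(source), config = config,
               seed = config$seed, n_source_rows = nrow(source)))
  synth[]
}

#' Check distributional fidelity of a synthetic table
#'
#' Compares per-column means and SDs (in source-SD units) and all pairwise
#' correlations between a source table and its synthetic counterpart.
#' "Statistically identical" is operationalized as effect-size tolerances
#' rather than hypothesis tests, since at 10,000 rows any test rejects
#' trivially small differences.
#'
#' @param source,synthetic tables with identical columns.
#' @param tolerance_sd max |mean difference| and |SD difference| in units
#'   of the source SD (default 0.25).
#' @param tolerance_r max absolute pairwise-correlation difference
#'   (default 0.15).
#' @return list with `pass`, per-column `moments` table, `correlations`
#'   table, and `failures` (character description of each violation).
#' @export
validate_synthesis <- function(source, synthetic, tolerance_sd = 0.25,
                               tolerance_r = 0.15) {
  source <- as.data.table(source)
  synthetic <- as.data.table(synthetic)
  if (!setequal(names(source), names(synthetic))) {
    stop("column mismatch between source and synthetic tables", call. = FALSE)
  }
  shared <- names(source)
  num <- function(df) {
    out <- as.data.table(df)[, ..shared]
    for (cl in shared) {
      if (!is.numeric(out[[cl]])) {
        lev <- sort(unique(as.character(as.data.table(source)[[cl]])))
        out[[cl]] <- match(as.character(out[[cl]]), lev)
      }
    }
    out
  }
  so <- num(source); sy <- num(synthetic)
  sds <- vapply(so, sd, numeric(1))
  sds[sds == 0] <- 1  # constant columns: differences measured absolutely
  moments <- data.table(
    column = shared,
    d_mean = (vapply(sy, mean, numeric(1)) - vapply(so, mean, numeric(1))) / sds,
    d_sd = (vapply(sy, sd, numeric(1)) - vapply(so, sd, numeric(1))) / sds)
  failures <- character(0)
  bad <- moments[abs(d_mean) > tolerance_sd | abs(d_sd) > tolerance_sd]
  if (nrow(bad)) {
    failures <- c(failures, sprintf("moments off for column %s", bad$column))
  }
  corrs <- data.table(col_a = character(0), col_b = character(0),
                      d_r = numeric(0))
  if (length(shared) >= 2L) {
    keep <- shared[vapply(so, function(x) sd(x) > 0, logical(1))]
    if (length(keep) >= 2L) {
      r_so <- cor(so[, ..keep]); r_sy <- cor(sy[, ..keep])
      r_sy[is.na(r_sy)] <- 0  # synthetic column collapsed to a constant
      idx <- which(upper.tri(r_so), arr.ind = TRUE)
      corrs <- data.table(col_a = keep[idx[, 1]], col_b = keep[idx[, 2]],
                          d_r = r_sy[idx] - r_so[idx])
      badr <- corrs[abs(d_r) > tolerance_r]
      if (nrow(badr)) {
        failures <- c(failures, sprintf("correlation off for %s~%s",
                                        badr$col_a, badr$col_b))
      }
    }
  }
  list(pass = length(failures) == 0L, moments = moments,
       correlations = corrs, failures = failures)
}

#' Split a synthetic table into random halves
#'
#' @param synthetic table with an even row count.
#' @param seed integer seed.
#' @return list with disjoint `train` and `test` halves whose union is the
#'   input.
#' @export
split_half <- function(synthetic, seed = 1L) {
  synthetic <- as.data.table(synthetic)
  n <- nrow(synthetic)
  if (n %% 2L != 0L) stop("row count must be even to split in half",
                          call. = FALSE)
  set.seed(as.integer(seed))
  idx <- sample.int(n, n %/% 2L)
  list(train = synthetic[idx], test = synthetic[-idx])
}
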