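## Reference tables ------------------------------------------------------

PARAM_COLS <- c("theta", "T1", "T2", "Tgf", "Tdur", "Nm4", "F")

canonical_params <- function(df) {
  out <- as.data.frame(setNames(rep(list(rep(NA_real_, nrow(df))), length(PARAM_COLS)),
                                PARAM_COLS))
  for (p in intersect(names(df), PARAM_COLS)) out[[p]] <- as.numeric(df[[p]])
  out
}

#' Construct a reference table from components
#'
#' Low-level constructor used by [build_reference_table()] and available
#' for assembling tables from externally computed rows (e.g. imported
#' simulations).
#'
#' @param model character/factor of model labels, one per row.
#' @param params data.frame of parameter draws (missing parameters may be
#'   `NA`).
#' @param stats numeric matrix of statistic vectors (rows aligned with
#'   `model`); column names must match `stat_names(stat_config)`.
#' @param stat_config a [stat_config()].
#' @param priors,config,seed optional provenance (a `prior_spec`, a
#'   [sample_config()], the master seed).
#' @return an object of class `reference_table`.
#' @export
reference_table <- function(model, params, stats, stat_config,
                            priors = NULL, config = NULL, seed = NULL) {
  stats <- as.matrix(stats)
  if (is.null(colnames(stats))) colnames(stats) <- stat_names(stat_config)
  stopifnot(length(model) == nrow(stats), nrow(params) == nrow(stats),
            identical(colnames(stats), stat_names(stat_config)))
  structure(list(model = factor(model, levels = intersect(MODEL_IDS, unique(model))),
                 params = canonical_params(params),
                 stats = stats,
                 stat_config = stat_config,
                 priors = priors, config = config, seed = seed),
            class = "reference_table")
}

#' Simulate a reference table over prior draws
#'
#' For each model, draws `n_per_model` parameter vectors from the priors,
#' simulates a multi-locus dataset under the implied demography and
#' stores its compressed statistic vector. Row-level seeds are derived
#' from `(seed, model index, row index)` with [derive_seed()], so the
#' table is identical however rows are scheduled.
#'
#' @param models character vector of model ids, or list of
#'   [model_spec()]s.
#' @param priors a `prior_spec` ([prior_preset()]); its admixture mode
#'   determines the continuous/pulse variant of models A-F.
#' @param config a [sample_config()].
#' @param n_per_model rows simulated per model (may be 0 for an empty
#'   table with a valid header).
#' @param stat_config a [stat_config()].
#' @param seed master integer seed.
#' @return an object of class `reference_table` with fields `model`
#'   (factor), `params` (data.frame of canonical parameter columns),
#'   `stats` (matrix) and provenance.
#' @export
#' @examples
#' tab <- build_reference_table("ISO", prior_preset("simulation"),
#'                              sample_config(n_loci = 20), n_per_model = 5,
#'                              stat_config("means_only"), seed = 1)
#' tab
build_reference_table <- function(models, priors, config, n_per_model,
                                  stat_config = admixabc::stat_config("full_3pop"),
                                  seed = 1L) {
  if (!is.list(models)) models <- as.list(models)
  models <- lapply(models, as_model_spec, admixture_mode = priors$admixture_mode)
  stopifnot(inherits(config, "sample_config"), n_per_model >= 0)
  if (stat_config$id == "reduced_single_haploid" &&
      config$n_seq[stat_config$singleton_pop] != 1L)
    stop("reduced_single_haploid statistics require a single sequence in population ",
         stat_config$singleton_pop)
  p <- length(stat_names(stat_config))
  rows_m <- vector("list", length(models))
  for (mi in seq_along(models)) {
    spec <- models[[mi]]
    stats <- matrix(NA_real_, n_per_model, p)
    pars <- vector("list", n_per_model)
    for (r in seq_len(n_per_model)) {
      set.seed(derive_seed(seed, mi, r))
      draw <- sample_prior(spec, priors, 1)
      plan <- build_demography(spec, draw)
      stats[r, ] <- simulate_stats(plan, config, draw$theta, stat_config)
      pars[[r]] <- draw
    }
    rows_m[[mi]] <- list(model = rep(spec$model_id, n_per_model),
                         params = if (n_per_model)
                           canonical_params(do.call(rbind, pars))
                         else canonical_params(data.frame(theta = numeric(0))),
                         stats = stats)
  }
  reference_table(model = unlist(lapply(rows_m, `[[`, "model")),
                  params = do.call(rbind, lapply(rows_m, `[[`, "params")),
                  stats = do.call(rbind, lapply(rows_m, `[[`, "stats")),
                  stat_config = stat_config,
                  priors = priors, config = config, seed = as.integer(seed))
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("ABC reference table: %d rows, %d statistics ('%s')\n",
              nrow(x$stats), ncol(x$stats), x$stat_config$id))
  tb <- table(x$model)
  cat("  rows per model:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.reference_table <- function(x, ...) {
  cbind(data.frame(model = as.character(x$model), stringsAsFactors = FALSE),
        x$params, as.data.frame(x$stats))
}

#' @export
dim.reference_table <- function(x) dim(x$stats)

#' Subset reference-table rows
#'
#' @param x a `reference_table`.
#' @param i row index (integer or logical).
#' @return a `reference_table` with the selected rows (model levels are
#'   preserved).
#' @export
`[.reference_table` <- function(x, i) subset_rows(x, i)

subset_rows <- function(table, keep) {
  structure(list(model = factor(as.character(table$model[keep]),
                                levels = levels(table$model)),
                 params = table$params[keep, , drop = FALSE],
                 stats = table$stats[keep, , drop = FALSE],
                 stat_config = table$stat_config,
                 priors = table$priors, config = table$config, seed = table$seed),
            class = "reference_table")
}

#' Reduce a full-statistics table to its means-only configuration
#'
#' Selects the across-locus mean columns of a `full_3pop` table, giving
#' the 13-statistic means-only configuration without re-simulating.
#'
#' @param table a `reference_table` with `full_3pop` statistics.
#' @return a `reference_table` with `means_only` statistics.
#' @export
reduce_to_means <- function(table) {
  stopifnot(inherits(table, "reference_table"),
            table$stat_config$id == "full_3pop")
  sc <- stat_config("means_only")
  stats <- table$stats[, stat_names(sc), drop = FALSE]
  structure(list(model = table$model, params = table$params, stats = stats,
                 stat_config = sc, priors = table$priors,
                 config = table$config, seed = table$seed),
            class = "reference_table")
}

#' Write / read a reference table
#'
#' `"tsv"` writes a portable one-header-line TSV (model label, canonical
#' parameter columns, statistic columns); `"parquet"` writes the same
#' columns through the `arrow` package. Reading reconstructs the table
#' given the statistic configuration (priors and sampling design are not
#' stored in the portable formats).
#'
#' @param table a `reference_table`.
#' @param path output file.
#' @param format `"tsv"` or `"parquet"`.
#' @export
write_reference_table <- function(table, path, format = c("tsv", "parquet")) {
  format <- match.arg(format)
  df <- as.data.frame(table)
  if (format == "tsv") {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for parquet output")
    arrow::write_parquet(df, path)
  }
  invisible(path)
}

#' @rdname write_reference_table
#' @param stat_config the [stat_config()] of the stored statistics.
#' @export
read_reference_table <- function(path, stat_config,
                                 format = c("tsv", "parquet")) {
  format <- match.arg(format)
  df <- if (format == "tsv")
    read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE)
  else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for parquet input")
    as.data.frame(arrow::read_parquet(path))
  }
  sn <- stat_names(stat_config)
  stopifnot(all(sn %in% names(df)))
  reference_table(model = df$model,
                  params = df[, intersect(names(df), PARAM_COLS), drop = FALSE],
                  stats = as.matrix(df[, sn, drop = FALSE]),
                  stat_config = stat_config)
}
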