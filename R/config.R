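## Run configuration and manifests ---------------------------------------

#' Read a run configuration
#'
#' YAML with keys `models` (character vector), `priors` (a preset name
#' or a path to a [read_prior_config()] file), `sample` (`n_seq`,
#' `n_loci`, `locus_length`), `stats` (`id`, optional `singleton_pop`),
#' `n_per_model`, `tolerance`, `nn` ([nn_control()] fields), and `seed`.
#' Omitted keys fall back to the defaults below.
#'
#' @param path YAML file.
#' @return a list of resolved components (class `run_config`).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  priors <- y$priors %||% "simulation"
  priors <- if (priors %in% c("simulation", "empirical")) prior_preset(priors)
            else read_prior_config(priors)
  smp <- y$sample %||% list()
  cfg <- sample_config(n_seq = unlist(smp$n_seq) %||% c(2, 2, 2),
                       n_loci = smp$n_loci %||% 1000,
                       locus_length = smp$locus_length %||% 500)
  st <- y$stats %||% list()
  sc <- stat_config(st$id %||% "full_3pop",
                    singleton_pop = st$singleton_pop %||% 3L)
  nn <- do.call(nn_control, y$nn %||% list())
  structure(list(models = y$models %||% MODEL_IDS,
                 priors = priors, config = cfg, stat_config = sc,
                 n_per_model = y$n_per_model %||% 1000L,
                 tolerance = y$tolerance %||% 0.005,
                 nn = nn, seed = y$seed %||% 1L,
                 raw = y),
            class = "run_config")
}

#' Write a JSON manifest describing a run's outputs
#'
#' Records the configuration fingerprint, seed, row counts and statistic
#' configuration so outputs are traceable to the exact settings that
#' produced them.
#'
#' @param path output JSON path.
#' @param config a `run_config` (or any serializable list).
#' @param extra named list of additional fields (row counts etc.).
#' @export
write_manifest <- function(path, config, extra = list()) {
  m <- c(list(package = "admixabc",
              version = as.character(utils::packageVersion("admixabc")),
              config_hash = str_hash(deparse(config$raw %||% config)),
              seed = config$seed %||% NA,
              stat_config = if (!is.null(config$stat_config)) config$stat_config$id else NA),
         extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
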