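## Coalescent simulation front-end ---------------------------------------

#' Sampling design of a multi-locus dataset
#'
#' @param n_seq per-population sample sizes in *sequences* (a diploid
#'   individual contributes 2, a single haploid contributes 1).
#' @param n_loci number of independent loci.
#' @param locus_length locus length in bp (enters only through theta and
#'   the exported formats; the infinite-sites engine works per locus).
#' @return an object of class `sample_config`.
#' @export
#' @examples
#' sample_config(c(2, 2, 2), n_loci = 200, locus_length = 500)
sample_config <- function(n_seq = c(2, 2, 2), n_loci = 1000, locus_length = 500) {
  stopifnot(length(n_seq) == 3, all(n_seq >= 1), n_loci >= 1, locus_length >= 1)
  structure(list(n_seq = as.integer(n_seq), n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length)),
            class = "sample_config")
}

#' @export
print.sample_config <- function(x, ...) {
  cat(sprintf("Sampling design: %d/%d/%d sequences, %d loci x %d bp\n",
              x$n_seq[1], x$n_seq[2], x$n_seq[3], x$n_loci, x$locus_length))
  invisible(x)
}

new_dataset <- function(loci, pops, config, provenance = NULL) {
  structure(list(loci = loci, pops = as.integer(pops), config = config,
                 provenance = provenance),
            class = "dataset")
}

#' @export
print.dataset <- function(x, ...) {
  S <- vapply(x$loci, nrow, 0L)
  cat(sprintf("Multi-locus dataset: %d loci, %d sequences (%s per population)\n",
              length(x$loci), length(x$pops),
              paste(tabulate(x$pops, 3), collapse = "/")))
  cat(sprintf("  segregating sites per locus: mean %.2f, range %d-%d\n",
              mean(S), min(S), max(S)))
  if (!is.null(x$provenance$model))
    cat("  simulated under model", x$provenance$model, "\n")
  invisible(x)
}

#' Simulate a multi-locus dataset under a demography plan
#'
#' Generates `config$n_loci` independent genealogies under the
#' structured coalescent described by `plan` and drops infinite-sites
#' mutations at rate `theta` per locus (ms scaling: times in 4Ne
#' generations, `theta = 4*Ne*mu*L`). Monomorphic loci are retained with
#' empty site matrices, since across-locus moments are taken over all
#' loci.
#'
#' @param plan a [build_demography()] plan.
#' @param config a [sample_config()].
#' @param theta per-locus scaled mutation rate (positive).
#' @param seed integer seed; identical inputs give identical datasets.
#' @return an object of class `dataset`: a list of site-by-sequence 0/1
#'   matrices (`loci`), a population assignment (`pops`), the `config`
#'   and a `provenance` record.
#' @export
#' @examples
#' pr <- prior_preset("simulation")
#' p <- sample_prior("ISO", pr)
#' d <- simulate_dataset(build_demography("ISO", p), sample_config(n_loci = 5),
#'                       theta = p$theta, seed = 1)
simulate_dataset <- function(plan, config, theta, seed) {
  stopifnot(inherits(plan, "demography_plan"), inherits(config, "sample_config"))
  stop_if_not_scalar(theta, "theta")
  if (theta <= 0) stop("theta must be positive")
  set.seed(as.integer(seed))
  loci <- .cpp_sim_loci(plan$merges, plan$epochs, plan$pulses,
                        config$n_seq, theta, config$n_loci)
  new_dataset(loci, rep(1:3, config$n_seq), config,
              provenance = list(model = plan$model_id, params = plan$params,
                                theta = theta, seed = as.integer(seed)))
}

## fused hot path: per-locus 13-statistic matrix straight from the engine
## (no seed handling here; the caller controls the RNG state)
simulate_locus_stats <- function(plan, config, theta) {
  .cpp_sim_locus_stats(plan$merges, plan$epochs, plan$pulses,
                       config$n_seq, theta, config$n_loci)
}

## simulate and compress in one go, restricted to the configured columns
simulate_stats <- function(plan, config, theta, stat_config) {
  m <- simulate_locus_stats(plan, config, theta)
  colnames(m) <- per_locus_stat_names()
  compress_moments(m[, stat_config$per_locus, drop = FALSE], stat_config)
}
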