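# Shared fixtures, memoized across test files (built once per run).

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

SIM_PRIORS <- prior_preset("simulation")
EMP_PRIORS <- prior_preset("empirical")

# single-population (panmictic) plan: both splits at essentially zero
panmictic_plan <- function() {
  p <- list(theta = 1, T1 = 1e-9, T2 = 2e-9)
  build_demography("ISO", p)
}

# small ISO table with full statistics: 600 rows, 100 loci x 500 bp,
# 1 diploid per population
iso_table_small <- function() {
  get_fixture("iso_small", function() {
    suppressWarnings(build_reference_table(
      "ISO", SIM_PRIORS, sample_config(c(2, 2, 2), 100, 500),
      n_per_model = 600, stat_config("full_3pop"), seed = 101))
  })
}

# 7-model means-only tables at two locus counts, for model-selection CV
cv_table <- function(n_loci) {
  get_fixture(paste0("cv_", n_loci), function() {
    suppressWarnings(build_reference_table(
      c("A", "B", "C", "D", "E", "F", "ISO"), SIM_PRIORS,
      sample_config(c(2, 2, 2), n_loci, 500),
      n_per_model = 400, stat_config("means_only"), seed = 202))
  })
}

# pure-noise multi-model table: statistics carry no model information
noise_table_7 <- function(n_per_model = 300, seed = 99) {
  mods <- c("A", "B", "C", "D", "E", "F", "ISO")
  set.seed(seed)
  params <- do.call(rbind, lapply(mods, function(m)
    sample_prior(m, SIM_PRIORS, n_per_model)[c("theta", "T1", "T2")]))
  reference_table(rep(mods, each = n_per_model), params,
                  matrix(rnorm(7 * n_per_model * 13), 7 * n_per_model, 13),
                  stat_config("means_only"), priors = SIM_PRIORS)
}

# pure-noise single-model table for the posterior-equals-prior oracle
noise_table_iso <- function(n = 1500, seed = 7) {
  set.seed(seed)
  params <- sample_prior("ISO", SIM_PRIORS, n)
  reference_table(rep("ISO", n), params, matrix(rnorm(n * 13), n, 13),
                  stat_config("means_only"), priors = SIM_PRIORS)
}

# the full desk-scale PODS experiment (shared between the coverage
# acceptance check and the prediction-error property)
desk_scale_cv <- function() {
  get_fixture("desk_cv", function() {
    tab <- suppressWarnings(build_reference_table(
      "ISO", SIM_PRIORS, sample_config(c(2, 2, 2), 200, 500),
      n_per_model = 5000, stat_config("full_3pop"), seed = 8271))
    suppressWarnings(cv_params(tab, n_pods = 100, tolerance = 0.005,
                               seed = 613))
  })
}

# maximum CDF discrepancy between a weighted sample and a reference
# sample (a weighted two-sample Kolmogorov-Smirnov statistic)
weighted_ks_stat <- function(x, w, ref) {
  grid <- sort(unique(c(x, ref)))
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  Fx <- approx(x[o], cw, grid, method = "constant", yleft = 0, yright = 1,
               ties = "ordered")$y
  Fr <- ecdf(ref)(grid)
  max(abs(Fx - Fr))
}

# Kish effective sample size of a weight vector
ess <- function(w) sum(w)^2 / sum(w^2)

# naive per-site reimplementation of the 13 per-locus statistics using
# classify_site (the brute-force oracle)
naive_locus_stats <- function(sites, pops) {
  out <- numeric(13)
  names(out) <- admixabc:::per_locus_stat_names()
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (k in seq_along(pairs)) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    cats <- character(0)
    for (s in seq_len(nrow(sites))) {
      cat1 <- classify_site(sites[s, pops == i], sites[s, pops == j])
      if (cat1 != "uninformative") cats <- c(cats, cat1)
    }
    if (length(cats)) {
      out[3 * k - 2] <- mean(cats == "fixed_difference")
      out[3 * k - 1] <- mean(cats == "shared_polymorphism")
      out[3 * k]     <- mean(cats %in% c("private_pop_i", "private_pop_j"))
    }
  }
  for (p in 1:3) {
    cols <- sites[, pops == p, drop = FALSE]
    out[9 + p] <- sum(apply(cols, 1, function(r) any(r != r[1])))
  }
  out[13] <- sum(apply(sites, 1, function(r) any(r != r[1])))
  out
}
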