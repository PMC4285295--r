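make_toy_table <- function(n_per_model = 300, sep = 5, seed = 41, p = 13) {
  # two well-separated models in statistic space
  set.seed(seed)
  stats <- rbind(matrix(rnorm(n_per_model * p, 0), n_per_model, p),
                 matrix(rnorm(n_per_model * p, sep), n_per_model, p))
  params <- data.frame(theta = runif(2 * n_per_model, 0.007, 0.35),
                       T1 = runif(2 * n_per_model, 0.4, 1),
                       T2 = runif(2 * n_per_model, 1, 4))
  reference_table(rep(c("A", "ISO"), each = n_per_model), params, stats,
                  stat_config("means_only"), priors = SIM_PRIORS)
}

test_that("rejection retains exactly round(tolerance * N) rows with deterministic ties", {
  tab <- make_toy_table(200)
  for (tol in c(0.01, 0.0775, 0.5, 1)) {
    acc <- abc_reject(rep(0, 13), tab, tolerance = tol)
    expect_equal(acc$n_accept, round(tol * 400))
    expect_equal(length(acc$indices), round(tol * 400))
  }
  acc <- abc_reject(rep(0, 13), tab, tolerance = 1)
  expect_equal(sort(acc$indices), 1:400)          # all rows retained
  expect_equal(acc$distances, sort(acc$distances)) # in distance order
  expect_true(all(acc$weights >= 0 & acc$weights <= 1))
  expect_error(abc_reject(rep(0, 13), tab, tolerance = 0))
  expect_error(abc_reject(rep(0, 13), tab, tolerance = 1e-9), "zero rows")
})

test_that("rescaling any statistic column leaves all downstream results unchanged", {
  tab <- make_toy_table(150)
  obs <- rep(0.5, 13)
  scaled <- tab
  scale_fac <- 1000
  scaled$stats[, 4] <- scaled$stats[, 4] * scale_fac
  obs2 <- obs; obs2[4] <- obs2[4] * scale_fac

  a1 <- abc_reject(obs, tab, tolerance = 0.1)
  a2 <- abc_reject(obs2, scaled, tolerance = 0.1)
  expect_equal(a1$indices, a2$indices)
  expect_equal(a1$weights, a2$weights)

  p1 <- model_posterior_mnlogistic(rep(2.5, 13), tab, tolerance = 0.3)
  obs3 <- rep(2.5, 13); obs3[4] <- obs3[4] * scale_fac
  p2 <- model_posterior_mnlogistic(obs3, scaled, tolerance = 0.3)
  expect_equal(p1$prob, p2$prob, tolerance = 1e-6)

  t1 <- tab[tab$model == "ISO"]
  t2 <- scaled[scaled$model == "ISO"]
  e1 <- estimate_parameters_nn(obs, t1, n_accept = 60, seed = 9, min_accept = 50)
  e2 <- estimate_parameters_nn(obs2, t2, n_accept = 60, seed = 9, min_accept = 50)
  expect_equal(e1$point, e2$point, tolerance = 1e-10)
})

test_that("rejection-based model probabilities are accepted-set frequencies", {
  tab <- make_toy_table(250)
  acc <- abc_reject(rep(0, 13), tab, tolerance = 0.05)   # deep inside model A
  post <- model_posterior_rejection(acc, tab)
  expect_equal(sum(post$prob), 1)
  expect_equal(unname(post$prob["A"]), 1)
  # no-information limit: full acceptance recovers the table's shares
  post_all <- model_posterior_rejection(abc_reject(rep(0, 13), tab, tolerance = 1), tab)
  expect_equal(unname(post_all$prob), c(0.5, 0.5))
  # constructed separation: observed at a model's centroid
  post_c <- model_posterior_rejection(abc_reject(rep(5, 13), tab, tolerance = 0.02), tab)
  expect_gt(post_c$prob["ISO"], 0.95)
})

test_that("multinomial-logistic model choice matches rejection on separable problems", {
  tab <- make_toy_table(250)
  # observed inside model A, tolerance just past the A rows: both methods
  # assign essentially all mass to A
  mnl <- model_posterior_mnlogistic(rep(0, 13), tab, tolerance = 0.55)
  rej <- model_posterior_rejection(abc_reject(rep(0, 13), tab, tolerance = 0.55), tab)
  expect_equal(sum(mnl$prob), 1, tolerance = 1e-9)
  expect_lt(max(abs(mnl$prob - rej$prob[names(mnl$prob)])), 0.1)
  expect_gt(mnl$prob["A"], 0.99)   # linearly separable
  expect_error(model_posterior_mnlogistic(rep(0, 13), tab, tolerance = 0.01),
               "fewer than 2 models")
})

test_that("minimum pairwise Bayes factors follow their definition", {
  mk <- function(p) structure(list(prob = p, method = "rejection", tolerance = 0.1),
                              class = "abc_model_posterior")
  expect_equal(bayes_factor_min(mk(c(A = 0.8, B = 0.1, C = 0.1)), "A"), 8)
  u <- rep(1 / 7, 7); names(u) <- c("A", "B", "C", "D", "E", "F", "ISO")
  expect_equal(bayes_factor_min(mk(u), "D"), 1)
  p <- c(A = 11 / 12, B = 1 / 12, C = 0)
  expect_gt(bayes_factor_min(mk(p), "A"), 10)   # strong support
  expect_equal(bayes_factor_min(mk(c(A = 1, B = 0)), "A"), 1e6)
  expect_error(bayes_factor_min(mk(u), "Z"), "unknown model")
})

test_that("HPD intervals match closed forms for uniform and normal samples", {
  set.seed(42)
  u <- runif(1e5)
  iv <- hpd_interval(u, mass = 0.95)
  expect_equal(unname(iv[2] - iv[1]), 0.95, tolerance = 0.01)
  z <- rnorm(1e5)
  iv <- hpd_interval(z, mass = 0.95)
  expect_equal(unname(iv), c(-1.96, 1.96), tolerance = 0.05)
  expect_equal(unname(hpd_interval(rep(3, 10))), c(3, 3))
  # weighting: weights that upweight the left half shift the interval
  x <- seq(0, 1, length.out = 1001)
  w <- ifelse(x < 0.5, 1, 0)
  iv <- hpd_interval(x, w, mass = 0.95)
  expect_lt(iv[2], 0.51)
})

test_that("the regression adjustment recovers an identity-mapped parameter", {
  set.seed(43)
  n <- 2000
  th <- sample_prior("ISO", SIM_PRIORS, n)
  stats <- cbind(th$theta + rnorm(n, 0, 1e-4), matrix(rnorm(n * 12), n, 12))
  tab <- reference_table(rep("ISO", n), th, stats, stat_config("means_only"),
                         priors = SIM_PRIORS)
  obs <- c(0.2, rep(0, 12))   # noise statistics at their central value
  post <- estimate_parameters_nn(obs, tab, n_accept = 1000, seed = 7)
  expect_lt(abs(post$point[["theta"]] - 0.2) / 0.2, 0.02)
  # adjusted draws always stay inside the prior support
  expect_true(all(post$samples$theta >= 0.007 & post$samples$theta <= 0.35))
  expect_true(all(post$samples$T1 >= 0.4 & post$samples$T1 <= 1))
  # reproducibility
  post2 <- estimate_parameters_nn(obs, tab, n_accept = 1000, seed = 7)
  expect_identical(post$point, post2$point)
})

test_that("estimation guards its preconditions", {
  tab <- make_toy_table(100)
  expect_error(estimate_parameters_nn(rep(0, 13), tab, tolerance = 0.5),
               "single-model")
  sub <- tab[tab$model == "ISO"]
  expect_error(estimate_parameters_nn(rep(0, 13), sub, tolerance = 0.1),
               "at least 50")
})
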