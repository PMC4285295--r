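test_that("PODS generation is counted, seeded and prior-consistent", {
  cfg <- sample_config(c(2, 2, 2), 30, 500)
  pods <- generate_pods("ISO", SIM_PRIORS, cfg, stat_config("means_only"),
                        n = 100, seed = 51)
  expect_equal(nrow(pods$stats), 100)
  expect_equal(nrow(pods$params), 100)
  pods2 <- generate_pods("ISO", SIM_PRIORS, cfg, stat_config("means_only"),
                         n = 100, seed = 51)
  expect_identical(pods$stats, pods2$stats)
  # truths are draws from the prior
  set.seed(1)
  ref <- sample_prior("ISO", SIM_PRIORS, 20000)
  for (p in c("theta", "T1", "T2"))
    expect_gt(suppressWarnings(ks.test(pods$params[[p]], ref[[p]])$p.value), 0.01)
})

test_that("prediction error is zero for perfect estimates and one at the prior baseline", {
  set.seed(52)
  truths <- sample_prior("ISO", SIM_PRIORS, 10000)
  pv <- vapply(truths, var, 0)
  expect_equal(unname(prediction_error(truths, truths, pv)), rep(0, 3))
  pm <- vapply(truths, mean, 0)
  const <- as.data.frame(lapply(pm, rep, nrow(truths)))
  eps <- prediction_error(const, truths, pv)
  expect_true(all(abs(eps - 1) < 0.05))
  expect_error(prediction_error(const, truths, c(theta = 0, T1 = 1, T2 = 1)),
               "zero prior variance")
})

test_that("coverage matches its construction for prior-posteriors and misses", {
  set.seed(53)
  n <- 400
  truths <- data.frame(x = runif(n))
  fake_post <- function(samp) {
    structure(list(point = c(x = median(samp)),
                   samples = data.frame(x = samp),
                   weights = rep(1, length(samp)),
                   hpd = matrix(hpd_interval(samp, mass = 0.95), 2, 1,
                                dimnames = list(c("lower", "upper"), "x"))),
              class = "abc_posterior")
  }
  # posterior == prior for every PODS: coverage ~ 0.95
  posts <- replicate(n, fake_post(runif(2000)), simplify = FALSE)
  cw <- coverage_and_width(posts, truths)
  expect_gt(cw$coverage["x"], 0.90)
  expect_equal(unname(cw$mean_width["x"]), 0.95, tolerance = 0.02)
  # intervals that exclude every truth: coverage 0
  posts2 <- replicate(n, fake_post(runif(2000, 2, 3)), simplify = FALSE)
  expect_equal(unname(coverage_and_width(posts2, truths)$coverage), 0)
})

test_that("leave-one-out model CV normalizes rows and sits at chance for noise tables", {
  tab <- noise_table_7(n_per_model = 200, seed = 54)
  cv <- leave_one_out_model_cv(tab, replicates_per_model = 25, tolerance = 0.2,
                               seed = 55)
  expect_equal(unname(rowSums(cv$confusion)), rep(1, 7), tolerance = 1e-6)
  expect_true(all(abs(cv$mean_true - 1 / 7) < 0.08))
  expect_true(all(cv$strong_support <= cv$n_replicates))
  expect_error(leave_one_out_model_cv(tab, replicates_per_model = 1000,
                                      tolerance = 0.1), "too few rows")
})
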