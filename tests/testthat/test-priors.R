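test_that("simulation preset respects Table-style marginal boxes and conditioning", {
  set.seed(1)
  for (m in c("A", "B", "D", "E")) {
    d <- sample_prior(m, SIM_PRIORS, 2000)
    expect_true(all(d$theta >= 0.007 & d$theta <= 0.35))
    expect_true(all(d$Tgf >= 0.1 & d$Tgf <= 0.5))
    expect_true(all(d$Tdur >= 0.01 & d$Tdur <= 0.1))
    expect_true(all(d$T1 >= 0.4 & d$T1 <= 1))
    expect_true(all(d$T2 >= 1 & d$T2 <= 4))
    expect_true(all(d$Tgf < d$T1))                  # conditioning honoured
    expect_true(all(d$Tgf + d$Tdur <= d$T1))        # window before sister split
    expect_true(all(d$Nm4 > 0))
  }
  d <- sample_prior("ISO", SIM_PRIORS, 2000)
  expect_named(d, c("theta", "T1", "T2"))
  expect_true(all(d$T1 < d$T2))
})

test_that("ancient-admixture models place the episode between the splits", {
  set.seed(2)
  for (pr in list(SIM_PRIORS, EMP_PRIORS)) {
    for (m in c("C", "F")) {
      d <- sample_prior(m, pr, 2000)
      expect_true(all(d$T1 >= 0.1 & d$T1 <= 4))
      expect_true(all(d$T2 >= d$T1 & d$T2 <= 4))
      expect_true(all(d$Tgf >= d$T1 & d$Tgf <= d$T2))
      if (pr$admixture_mode == "continuous_window")
        expect_true(all(d$Tgf + d$Tdur <= d$T2))
    }
  }
})

test_that("conditional priors match a rejection-sampling oracle (empirical, model C)", {
  set.seed(3)
  d <- sample_prior("C", EMP_PRIORS, 10000)
  expect_equal(mean(d$T2 > d$T1), 1)

  # oracle: the scheme "T1 ~ U(0.1,4), T2 ~ U(T1,4), Tgf ~ U(T1,T2)"
  # implies, in closed form, a uniform T1 marginal and standard-uniform
  # probability-integral transforms for each conditional; check all
  # three, plus a pairwise rejection oracle for one conditional stage
  expect_gt(suppressWarnings(
    ks.test(d$T1, "punif", 0.1, 4)$p.value), 0.01)
  v <- (d$T2 - d$T1) / (4 - d$T1)
  expect_gt(suppressWarnings(ks.test(v, "punif")$p.value), 0.01)
  expect_lt(abs(cor(v, d$T1)), 0.03)   # conditional transform independent of T1
  # single-stage rejection oracle: draws from the U(0.1, 4) box kept when
  # above a fixed T1 reproduce the sampler's T2 | T1 in a narrow T1 slice
  slice <- d$T1 > 1 & d$T1 < 1.1
  o_T2 <- runif(200000, 0.1, 4)
  o_T2 <- o_T2[o_T2 > 1.1]
  expect_gt(suppressWarnings(ks.test(d$T2[slice], o_T2)$p.value), 0.005)
  # Tgf given (T1, T2) is uniform on (T1, T2)
  u <- (d$Tgf - d$T1) / (d$T2 - d$T1)
  expect_gt(suppressWarnings(ks.test(u, "punif")$p.value), 0.01)
})

test_that("prior draws always satisfy the model invariants", {
  set.seed(4)
  for (pr in list(SIM_PRIORS, EMP_PRIORS))
    for (m in c("A", "B", "C", "D", "E", "F", "ISO")) {
      d <- sample_prior(m, pr, 500)
      for (i in seq_len(nrow(d)))
        expect_silent(validate_params(m, d[i, ], pr$admixture_mode))
    }
})

test_that("theta prior endpoints equal 4*Ne*mu*L over the stated Ne range", {
  mu <- 1.75e-9; L <- 500
  g <- SIM_PRIORS$groups$iso$theta
  expect_equal(g$min, 4 * 2000 * mu * L)
  expect_equal(g$max, 4 * 100000 * mu * L)
})

test_that("prior specs round-trip through YAML with identical samples", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_prior_config(EMP_PRIORS, path)
  re <- read_prior_config(path)
  set.seed(5); a <- sample_prior("C", EMP_PRIORS, 200)
  set.seed(5); b <- sample_prior("C", re, 200)
  expect_identical(a, b)
})

test_that("prior sampling is reproducible and errors on bad input", {
  set.seed(6); a <- sample_prior("A", SIM_PRIORS, 50)
  set.seed(6); b <- sample_prior("A", SIM_PRIORS, 50)
  expect_identical(a, b)
  expect_error(sample_prior("Z", SIM_PRIORS), "arg")
  expect_error(sample_prior(model_spec("A", "pulse"), SIM_PRIORS),
               "admixture mode")
})
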