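test_that("isolation plans contain exactly two merges and no gene flow", {
  p <- list(theta = 0.1, T1 = 0.5, T2 = 2)
  plan <- build_demography("ISO", p)
  expect_equal(nrow(plan$merges), 2)
  expect_equal(nrow(plan$epochs), 0)
  expect_equal(nrow(plan$pulses), 0)
  expect_equal(plan$merges[, "time"], c(0.5, 2), ignore_attr = TRUE)
})

test_that("continuous-window plans transcribe the admixture window", {
  p <- list(theta = 0.1, T1 = 0.6, T2 = 2, Tgf = 0.2, Tdur = 0.05, Nm4 = 1.5)
  plan <- build_demography("D", p)
  expect_equal(nrow(plan$epochs), 1)
  expect_equal(unname(plan$epochs[1, ]), c(0.2, 0.25, 2, 1, 1.5))
  # direction conventions: backward-time moves are recipient -> source
  dirs <- list(A = c(1, 2), B = c(1, 3), D = c(2, 1), E = c(3, 1))
  for (m in names(dirs)) {
    pl <- build_demography(m, p)
    expect_equal(unname(pl$epochs[1, c("pop", "dest")]), dirs[[m]])
  }
  pa <- list(theta = 0.1, T1 = 0.6, T2 = 2, Tgf = 1.0, Tdur = 0.05, Nm4 = 1.5)
  expect_equal(unname(build_demography("C", pa)$epochs[1, c("pop", "dest")]), c(1, 2))
  expect_equal(unname(build_demography("F", pa)$epochs[1, c("pop", "dest")]), c(2, 1))
})

test_that("pulse plans carry a single mass-migration event", {
  p <- list(theta = 0.1, T1 = 0.6, T2 = 2, Tgf = 0.2, F = 0.5)
  plan <- build_demography(model_spec("A", "pulse"), p)
  expect_equal(nrow(plan$pulses), 1)
  expect_equal(unname(plan$pulses[1, ]), c(0.2, 1, 2, 0.5))
})

test_that("invalid parameter/epoch combinations are rejected", {
  base <- list(theta = 0.1, T1 = 0.5, T2 = 2, Tgf = 0.45, Tdur = 0.2, Nm4 = 1)
  expect_error(build_demography("A", base), "window")
  expect_error(build_demography("A", modifyList(base, list(Tgf = 0.6, Tdur = 0.01))),
               "Tgf < T1")
  expect_error(build_demography("C", modifyList(base, list(Tgf = 0.2, Tdur = 0.01))),
               "Tgf >= T1")
  expect_error(build_demography("ISO", list(theta = -1, T1 = 0.5, T2 = 2)),
               "positive")
  expect_error(build_demography("ISO", list(theta = 1, T1 = 3, T2 = 2)),
               "T1 must precede")
})

test_that("a pulse of proportion zero is distributionally equivalent to isolation", {
  cfg <- sample_config(c(2, 2, 2), 400, 500)
  p <- list(theta = 0.15, T1 = 0.8, T2 = 2, Tgf = 0.3, F = 0)
  d_pulse <- simulate_dataset(build_demography(model_spec("A", "pulse"), p),
                              cfg, p$theta, seed = 11)
  d_iso <- simulate_dataset(build_demography("ISO", p[c("theta", "T1", "T2")]),
                            cfg, p$theta, seed = 12)
  s_pulse <- vapply(d_pulse$loci, nrow, 0L)
  s_iso <- vapply(d_iso$loci, nrow, 0L)
  ks <- suppressWarnings(ks.test(s_pulse, s_iso))
  expect_gt(ks$p.value, 0.01)
})

test_that("continuous gene flow with 4Nm -> 0 degenerates to isolation", {
  cfg <- sample_config(c(2, 2, 2), 400, 500)
  p <- list(theta = 0.15, T1 = 0.8, T2 = 2, Tgf = 0.3, Tdur = 0.05, Nm4 = 1e-12)
  d_mig <- simulate_dataset(build_demography("D", p), cfg, p$theta, seed = 13)
  d_iso <- simulate_dataset(build_demography("ISO", p[c("theta", "T1", "T2")]),
                            cfg, p$theta, seed = 14)
  ks <- suppressWarnings(ks.test(vapply(d_mig$loci, nrow, 0L),
                                 vapply(d_iso$loci, nrow, 0L)))
  expect_gt(ks$p.value, 0.01)
})
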