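test_that("site classification matches its definition and a brute-force enumeration", {
  expect_equal(classify_site(c(0, 0, 0), c(1, 1)), "fixed_difference")
  expect_equal(classify_site(c(0, 1), c(0, 1, 1)), "shared_polymorphism")
  expect_equal(classify_site(c(0, 1, 1), c(0, 0)), "private_pop_i")
  expect_equal(classify_site(c(1, 1), c(0, 1)), "private_pop_j")
  expect_equal(classify_site(c(1, 1), c(1, 1)), "uninformative")
  expect_error(classify_site(numeric(0), c(1)), "at least one")

  # exhaustive check over all 2^5 assignments for sample sizes (3, 2),
  # against an independent table-based classifier
  brute <- function(a, b) {
    na <- length(unique(a)); nb <- length(unique(b))
    if (na == 2 && nb == 2) "shared_polymorphism"
    else if (na == 2) "private_pop_i"
    else if (nb == 2) "private_pop_j"
    else if (a[1] != b[1]) "fixed_difference"
    else "uninformative"
  }
  for (code in 0:31) {
    bits <- as.integer(intToBits(code)[1:5])
    a <- bits[1:3]; b <- bits[4:5]
    expect_equal(classify_site(a, b), brute(a, b))
  }
})

test_that("the hand-built four-site locus reproduces the worked per-locus vector", {
  # pops of sizes (4, 4, 2); rows are sites, columns sequences
  m <- rbind(
    c(0, 0, 0, 0, 1, 1, 1, 1, 0, 0),  # fixed difference for pair (1,2)
    c(0, 0, 1, 1, 0, 1, 1, 1, 0, 0),  # shared polymorphism in pair (1,2)
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1),  # private to pop3
    c(0, 0, 0, 0, 0, 0, 0, 0, 1, 0))  # private to pop3
  pops <- rep(1:3, c(4, 4, 2))
  st <- locus_stats(m, pops = pops)
  expect_equal(unname(st[c("fixed_12", "shared_12", "private_12")]),
               c(0.5, 0.5, 0))
  expect_equal(unname(st["S_total"]), 4)
  # full hand-enumerated vector
  expect_equal(unname(st),
               c(0.5, 0.5, 0,        # pair (1,2): 2 informative sites
                 0, 0, 1,            # pair (1,3): sites 2,3,4 all private
                 0.25, 0, 0.75,      # pair (2,3): fixed, then 3 private
                 1, 1, 2, 4))
  expect_equal(unname(naive_locus_stats(m, pops)), unname(st))
})

test_that("statistics are invariant to phase, allele relabelling and within-population order", {
  set.seed(31)
  cfg <- sample_config(c(4, 4, 2), 20, 500)
  p <- sample_prior("A", SIM_PRIORS, 1)
  d <- simulate_dataset(build_demography("A", p), cfg, p$theta, seed = 32)
  for (l in d$loci) {
    if (nrow(l) == 0) next
    ref <- locus_stats(l, pops = d$pops)
    # allele relabelling at a random subset of sites
    flip <- runif(nrow(l)) < 0.5
    l2 <- l; l2[flip, ] <- 1L - l2[flip, ]
    expect_equal(locus_stats(l2, pops = d$pops), ref)
    # phase swap: exchange the two haplotypes of a diploid at random sites
    l3 <- l
    sw <- runif(nrow(l)) < 0.5
    tmp <- l3[sw, 1]; l3[sw, 1] <- l3[sw, 2]; l3[sw, 2] <- tmp
    expect_equal(locus_stats(l3, pops = d$pops), ref)
    # permuting sequences within a population
    perm <- c(sample(1:4), 4 + sample(1:4), 9:10)
    expect_equal(locus_stats(l[, perm, drop = FALSE], pops = d$pops), ref)
  }
})

test_that("category proportions sum to one whenever a pair has informative sites", {
  set.seed(33)
  for (r in 1:50) {
    m <- matrix(rbinom(8 * 7, 1, 0.4), 8, 7)
    pops <- rep(1:3, c(3, 2, 2))
    st <- locus_stats(m, pops = pops)
    for (k in 1:3) {
      tot <- sum(st[(3 * k - 2):(3 * k)])
      expect_true(tot == 0 || abs(tot - 1) < 1e-12)
    }
  }
})

test_that("moment compression emits the documented vector layouts", {
  set.seed(34)
  m13 <- matrix(runif(20 * 13), 20, 13)
  full <- compress_moments(m13, stat_config("full_3pop"))
  expect_length(full, 52)
  expect_equal(names(full)[1:4],
               c("fixed_12_mean", "fixed_12_var", "fixed_12_skew", "fixed_12_kurt"))
  mo <- compress_moments(m13, stat_config("means_only"))
  expect_length(mo, 13)
  expect_equal(unname(mo), unname(colMeans(m13)))
  m10 <- m13[, 1:10]
  red <- compress_moments(m10, stat_config("reduced_single_haploid"))
  expect_length(red, 40)

  # against direct formulas
  x <- m13[, 1]
  expect_equal(unname(full[1]), mean(x))
  expect_equal(unname(full[2]), var(x))
  ctr <- x - mean(x)
  expect_equal(unname(full[3]), mean(ctr^3) / mean(ctr^2)^1.5)
  expect_equal(unname(full[4]), mean(ctr^4) / mean(ctr^2)^2)

  # constant statistic: mean c, all higher moments zero
  mc <- cbind(rep(2.5, 10), matrix(runif(120), 10, 12))
  out <- compress_moments(mc, stat_config("full_3pop"))
  expect_equal(unname(out[1:4]), c(2.5, 0, 0, 0))
  expect_error(compress_moments(m13[1, , drop = FALSE], stat_config("full_3pop")),
               "at least 2 loci")
})

test_that("the reduced single-haploid configuration drops the uninformative statistics", {
  sc <- stat_config("reduced_single_haploid", singleton_pop = 3)
  expect_length(sc$per_locus, 10)
  expect_false(any(c("shared_13", "shared_23", "S_pop3") %in% sc$per_locus))
  sc1 <- stat_config("reduced_single_haploid", singleton_pop = 1)
  expect_false(any(c("shared_12", "shared_13", "S_pop1") %in% sc1$per_locus))

  m <- rbind(c(0, 1, 0, 0, 1), c(1, 1, 0, 1, 0))
  pops <- c(1, 1, 2, 2, 3)
  st <- locus_stats(m, sc, pops = pops)
  expect_length(st, 10)
  expect_equal(st, locus_stats(m, pops = pops)[sc$per_locus])
  expect_error(locus_stats(m, sc, pops = c(1, 1, 2, 3, 3)), "exactly one")
})

test_that("dataset statistics agree between configurations and empty loci are handled", {
  cfg <- sample_config(c(2, 2, 1), 30, 500)
  p <- sample_prior("ISO", SIM_PRIORS, 1)
  d <- simulate_dataset(build_demography("ISO", p), cfg, 0.05, seed = 35)
  expect_true(any(vapply(d$loci, nrow, 0L) == 0))  # theta small: empty loci occur
  sv <- dataset_stats(d, stat_config("full_3pop"))
  expect_length(sv, 52)
  expect_true(all(is.finite(sv)))
  red <- dataset_stats(d, stat_config("reduced_single_haploid", singleton_pop = 3))
  expect_length(red, 40)
  # a zero-site locus contributes zero proportions and zero counts
  empty <- matrix(0L, 0, 5)
  expect_equal(unname(locus_stats(empty, pops = c(1, 1, 2, 2, 3))), rep(0, 13))
})
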