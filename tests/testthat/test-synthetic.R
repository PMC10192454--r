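# Sporophytic self-incompatibility simulator.

test_that("dominance phenotype expresses the most dominant allele only", {
  expect_equal(si_phenotype(c(1, 3)), 1)
  expect_equal(si_phenotype(c(2, 2)), 2)
  expect_equal(si_phenotype(c(4, 2)), 2)
  expect_equal(si_phenotype(c(1, 3), model = "codominance"), c(1, 3))
})

test_that("compatibility needs disjoint expressed S-specificities", {
  # any selfing is incompatible: identical phenotype sets
  for (g in list(c(1, 1), c(2, 5), c(3, 4))) {
    expect_false(is_cross_compatible(g, g))
  }
  expect_false(is_cross_compatible(c(1, 2), c(1, 3)))  # shared dominant S1
  expect_true(is_cross_compatible(c(3, 4), c(1, 2)))   # 3 vs 1: disjoint
  # codominance: recessive alleles now block too
  expect_false(is_cross_compatible(c(1, 3), c(2, 3), model = "codominance"))
  expect_true(is_cross_compatible(c(1, 3), c(2, 3)))   # dominance: 1 vs 2
})

test_that("populations are deterministic under seed and sized as asked", {
  p <- sim_params(seed = 5L, n_genotypes = 10)
  pop1 <- make_population(p)
  pop2 <- make_population(p)
  expect_identical(pop1, pop2)
  expect_equal(nrow(pop1), 10L)
  expect_true(all(pop1$s1 >= 1 & pop1$s1 <= p$n_s_alleles))
  expect_true(all(pop1[names(kolacross:::SIM_TRAIT_MEANS)] > 0))
  expect_error(sim_params(n_s_alleles = 1), class = "kola_param_error")
  expect_error(sim_params(p_compat = 0.2, p_leak = 0.4),
               class = "kola_param_error")
})

test_that("compatible-pair fraction matches exhaustive enumeration (2 alleles)", {
  # Oracle: with 2 alleles under strict dominance, genotypes (1,1),(1,2) show
  # phenotype {1} with Hardy-Weinberg probability 3/4 and (2,2) shows {2} with
  # probability 1/4; ordered pairs are compatible iff phenotypes differ:
  # expected fraction 2 * (3/4) * (1/4) = 3/8.
  p <- sim_params(seed = 99L, n_genotypes = 400, n_s_alleles = 2)
  pop <- make_population(p)
  n <- nrow(pop)
  phen <- apply(cbind(pop$s1, pop$s2), 1, si_phenotype)
  # brute-force enumeration over all ordered pairs via the phenotype rule
  brute <- outer(phen, phen, function(a, b) a != b)
  diag(brute) <- FALSE
  # same enumeration through the public predicate on a subsample
  idx <- seq_len(40)
  for (i in idx) for (j in idx) {
    if (i == j) next
    expect_identical(
      is_cross_compatible(c(pop$s1[i], pop$s2[i]), c(pop$s1[j], pop$s2[j])),
      brute[i, j]
    )
  }
  frac <- sum(brute) / (n * (n - 1))
  # 400 genotypes: phenotype frequency within ~3 binomial SDs of 3/4
  expect_lt(abs(mean(phen == 1) - 0.75), 3 * sqrt(0.75 * 0.25 / n))
  expect_lt(abs(frac - 3 / 8), 0.06)
})

test_that("simulated counts conserve flowers and respect degenerate probabilities", {
  sim <- canned_sim()
  poll <- sim$dataset$pollinations
  expect_true(all(poll$n_pod + poll$n_pseudo + poll$n_dropped ==
                    poll$n_pollinated))

  # degenerate: p_compat = 1, p_leak = 0, no pseudo-pods
  p <- sim_params(seed = 1L, n_genotypes = 8, p_compat = 1, p_leak = 0,
                  p_pseudo_incompat = 0, p_pseudo_compat = 0, env_cv = 0)
  pop <- make_population(p)
  design <- make_crossing_design(pop, n_singles = 10, seed = 1L)
  s <- simulate_crossing_trial(pop, design, p)
  cs <- compatibility_summary(s$dataset)
  compat <- s$truth$compatible[match(cs$cross_label, s$truth$cross_label)]
  expect_true(all(cs$pod_set_pct[compat] == 100))
  expect_true(all(cs$pod_set_pct[!compat] == 0))
})

test_that("repeat simulation under a fixed seed is identical and substreams are stable", {
  p <- sim_params(seed = 7L, n_genotypes = 8)
  pop <- make_population(p)
  design <- make_crossing_design(pop, n_singles = 6, seed = 7L)
  s1 <- simulate_crossing_trial(pop, design, p)
  s2 <- simulate_crossing_trial(pop, design, p)
  expect_identical(s1$dataset$pollinations, s2$dataset$pollinations)
  expect_identical(s1$dataset$traits, s2$dataset$traits)

  # adding crosses must not perturb existing ones (keyed substreams)
  extra <- c(design, paste(pop$id[1], pop$id[3], sep = " × "))
  extra <- extra[!duplicated(vapply(extra, kolacross:::cross_key, ""))]
  s3 <- simulate_crossing_trial(pop, extra, p)
  shared <- s1$dataset$pollinations$cross_label
  sub <- s3$dataset$pollinations[
    s3$dataset$pollinations$cross_label %in% shared, ]
  rownames(sub) <- NULL
  expect_equal(sub, s1$dataset$pollinations, ignore_attr = TRUE)
})

test_that("all selfs are incompatible and pod counts are monotone in p_compat", {
  sim <- canned_sim()
  selfs <- sim$truth$is_self
  expect_true(all(!sim$truth$compatible[selfs]))

  p_lo <- sim_params(seed = 31L, n_genotypes = 8, p_compat = 0.5)
  p_hi <- sim_params(seed = 31L, n_genotypes = 8, p_compat = 0.9)
  pop <- make_population(p_lo)
  design <- make_crossing_design(pop, n_singles = 10, seed = 31L)
  lo <- simulate_crossing_trial(pop, design, p_lo)
  hi <- simulate_crossing_trial(pop, design, p_hi)
  compat_labels <- lo$truth$cross_label[lo$truth$compatible]
  pods <- function(s) sum(s$dataset$pollinations$n_pod[
    s$dataset$pollinations$cross_label %in% compat_labels])
  expect_gte(pods(hi), pods(lo))
})

test_that("mean pod set of compatible crosses sits in the binomial band", {
  # 50 compatible-cross equivalents at p = 0.8, 20 flowers x 3 replicates
  p <- sim_params(seed = 13L, n_genotypes = 40, p_compat = 0.8,
                  n_s_alleles = 12)
  pop <- make_population(p)
  design <- make_crossing_design(pop, n_singles = 150, selfs = FALSE,
                                 seed = 13L)
  s <- simulate_crossing_trial(pop, design, p)
  compat <- s$truth$cross_label[s$truth$compatible]
  stopifnot(length(compat) >= 50)
  compat <- compat[1:50]
  poll <- s$dataset$pollinations[
    s$dataset$pollinations$cross_label %in% compat, ]
  phat <- sum(poll$n_pod) / sum(poll$n_pollinated)
  # 99% two-sided binomial interval around 0.8 at n = 50 * 60 flowers
  half <- stats::qnorm(0.995) * sqrt(0.8 * 0.2 / (50 * 60))
  expect_lt(abs(phat - 0.8), half)
})

test_that("unknown genotypes in a design are lookup errors", {
  p <- sim_params(seed = 2L, n_genotypes = 4)
  pop <- make_population(p)
  expect_error(
    simulate_crossing_trial(pop, "SIM/1 × SIM/99", p),
    "SIM/99", class = "kola_lookup_error"
  )
})
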