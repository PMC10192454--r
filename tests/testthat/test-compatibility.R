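# Pod-set percentages, the 0-5 class scale, GLM contrasts, class distributions.

test_that("pod set and pseudo-pod set percentages", {
  expect_equal(pod_set_percent(0, 20), 0)
  expect_equal(pod_set_percent(20, 20), 100)
  expect_equal(pod_set_percent(7, 20), 35)
  expect_equal(pseudo_pod_set_percent(5, 20), 25)
  expect_true(is.na(pod_set_percent(0, 0)))  # undefined, never 0
  expect_error(pod_set_percent(5, 4), class = "kola_validation_error")
  expect_error(pod_set_percent(-1, 4), class = "kola_validation_error")
})

test_that("class scale maps printed extremes as reported", {
  expect_equal(compatibility_class(0), 0L)
  expect_equal(compatibility_class(97.0), 5L)   # largest DCC pod set
  expect_equal(compatibility_class(21.3), 2L)   # smallest DCS pod set
  expect_equal(compatibility_class(48.7), 3L)   # largest MX2 self
  expect_equal(compatibility_class(13.7), 1L)   # smallest MX2 self
  expect_equal(compatibility_class(20.5), 2L)   # the printed 20-21 gap
  expect_equal(compatibility_class_name(c(0, 50, 97)),
               c("incompatible", "moderate", "very high"))
  expect_error(compatibility_class(101), class = "kola_domain_error")
  expect_error(compatibility_class(-0.1), class = "kola_domain_error")
})

test_that("class scale partitions [0,100]: every value gets exactly one class", {
  grid <- c(0, 1e-9, seq(0.1, 100, by = 0.1), 20, 40, 60, 80, 100,
            20 + 1e-9, 40 - 1e-9)
  cl <- compatibility_class(grid)
  expect_false(anyNA(cl))
  expect_true(all(cl %in% 0:5))
  # band membership: class k > 0 iff value in (20(k-1), 20k]
  k <- cl[cl > 0]
  v <- grid[cl > 0]
  expect_true(all(v > 20 * (k - 1) & v <= 20 * k))
  expect_true(all(grid[cl == 0] == 0))
})

test_that("replicate aggregation modes agree when counts are balanced", {
  poll <- make_poll_df()
  pooled <- compatibility_summary(poll, aggregate = "pooled")
  bymean <- compatibility_summary(poll, aggregate = "mean")
  # equal n_pollinated per replicate: pooling equals averaging percentages
  expect_equal(pooled$pod_set_pct, bymean$pod_set_pct)
  expect_equal(pooled$pod_set_pct, c(70, 10))
  expect_equal(pooled$compat_class, c(4L, 1L))
  expect_equal(pooled$cross_type, c("SCC", "SCS"))
})

test_that("trait tables with printed percentages summarise directly", {
  g <- kola_fixture("gx1_self")
  cs <- compatibility_summary(g)
  expect_equal(nrow(cs), 28L)
  expect_equal(cs$pod_set_pct, g$pod_set)
  expect_equal(sort(unique(cs$compat_class)), c(1L, 2L, 3L))
})

test_that("GLM contrast: null case, strong case, and 2x2 G equivalence", {
  # identical success proportions -> statistic ~ 0, p ~ 1
  poll <- data.frame(
    cross_label = c("A1 × A2", "A3 × A4", "B1/1 × B1/1", "B1/2 × B1/2"),
    replicate = 1L, n_pollinated = 20L,
    n_pod = c(10L, 10L, 10L, 10L), n_pseudo = 0L, n_dropped = 10L
  )
  ct <- cross_type_podset_test(poll, groups = c("SCC", "SCS"))
  expect_lt(abs(ct$statistic), 1e-8)
  expect_equal(ct$p_value, 1, tolerance = 1e-6)

  # 70% vs 30%, 20 crosses per group, 60 flowers each -> overwhelming
  set.seed(404)
  mk <- function(labels, p) {
    do.call(rbind, lapply(seq_along(labels), function(i) {
      pods <- rbinom(3, 20, p)
      data.frame(cross_label = labels[i], replicate = 1:3,
                 n_pollinated = 20L, n_pod = pods, n_pseudo = 0L,
                 n_dropped = 20L - pods)
    }))
  }
  dcc <- mk(sprintf("B1/%d × B1/%d × B1/%d × B1/%d",
                    1:20, 21:40, 41:60, 61:80), 0.7)
  dcs <- mk(sprintf("B1/%d × B1/%d × B1/%d × B1/%d",
                    101:120, 121:140, 101:120, 121:140), 0.3)
  ct2 <- cross_type_podset_test(rbind(dcc, dcs), groups = c("DCC", "DCS"))
  expect_lt(ct2$p_value, 0.001)
  expect_gt(ct2$group_pct[["DCC"]], ct2$group_pct[["DCS"]])

  # one cross per group: GLM deviance equals the classical 2x2 G on pooled
  # counts, computed here independently from the log-likelihood definition
  one <- data.frame(cross_label = c("A1 × A2", "B1 × B1"), replicate = 1L,
                    n_pollinated = c(50L, 40L), n_pod = c(31L, 12L),
                    n_pseudo = 0L, n_dropped = c(19L, 28L))
  ct3 <- cross_type_podset_test(one, groups = c("SCC", "SCS"))
  s <- c(31, 12); n <- c(50, 40)
  ll <- function(x, nn, p) sum(x * log(p) + (nn - x) * log(1 - p))
  g_oracle <- 2 * (ll(s, n, s / n) - ll(s, n, sum(s) / sum(n)))
  expect_equal(ct3$statistic, g_oracle, tolerance = 1e-10)
})

test_that("GLM contrast is invariant to group label order and flags separation", {
  sim <- canned_sim()
  poll <- sim$dataset$pollinations
  a <- cross_type_podset_test(poll, groups = c("SCC", "SCS"))
  b <- cross_type_podset_test(poll, groups = c("SCS", "SCC"))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
  expect_gte(a$statistic, 0)

  # complete separation: one group all failures
  sep <- data.frame(cross_label = c("A1 × A2", "A3 × A4", "B1 × B1",
                                    "B2 × B2"),
                    replicate = 1L, n_pollinated = 20L,
                    n_pod = c(15L, 12L, 0L, 0L), n_pseudo = 0L,
                    n_dropped = c(5L, 8L, 20L, 20L))
  ct <- cross_type_podset_test(sep, groups = c("SCC", "SCS"))
  expect_true(ct$separation)
  expect_true(is.finite(ct$statistic))
  expect_lt(ct$p_value, 0.001)
})

test_that("contrast errors: missing group counts", {
  poll <- make_poll_df()
  expect_error(cross_type_podset_test(poll, groups = c("DCC", "DCS")),
               class = "kola_contrast_error")
})

test_that("class distribution test: concentration, uniformity, pairwise ties", {
  # everything in one class
  res <- class_distribution_test(rep(4L, 30))
  expect_equal(res$df, 5)
  expect_lt(res$p_value, 0.001)
  # oracle: closed-form chi-square with df 5 for 30 obs in one of 6 cells
  expect_equal(res$statistic, sum((c(30, 0, 0, 0, 0, 0) - 5)^2 / 5))

  # exactly uniform
  res2 <- class_distribution_test(rep(0:5, each = 5))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  expect_true(all(res2$pairwise$p_holm == 1))
})
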