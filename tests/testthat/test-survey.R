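test_that("the degenerate design reduces to the classical standard error of the mean", {
  set.seed(5)
  y <- stats::rnorm(37, mean = 70, sd = 12)
  d <- tibble::tibble(y = y, s = 1, p = seq_along(y), w = 3.7)
  est <- svy_mean(svy_design(d, "s", "p", "w"), "y")
  expect_equal(est$estimate, mean(y), tolerance = 1e-12)
  expect_equal(est$se, stats::sd(y) / sqrt(length(y)), tolerance = 1e-12)
  expect_identical(est$n_obs, length(y))

  d3 <- tibble::tibble(y = c(1, 2, 3), s = 1, p = 1:3, w = 1)
  est3 <- svy_mean(svy_design(d3, "s", "p", "w"), "y")
  expect_equal(est3$estimate, 2.0)
  expect_equal(est3$se, 1 / sqrt(3), tolerance = 1e-12)
})

test_that("weighted means follow the weights", {
  d <- tibble::tibble(y = c(10, 20), s = 1, p = 1:2, w = c(1, 3))
  expect_equal(svy_mean(svy_design(d, "s", "p", "w"), "y")$estimate, 17.5)
})

make_cluster_fixture <- function(n = 300, n_strata = 3, seed = 1234) {
  set.seed(seed)
  s <- sample(seq_len(n_strata), n, replace = TRUE)
  p <- sample(1:2, n, replace = TRUE)
  tibble::tibble(
    s = s, p = p,
    w = stats::runif(n, 0.5, 8),
    y = 70 + 2 * s + 3 * (p == 1) + stats::rnorm(n, 0, 9),
    age = sample(18:85, n, replace = TRUE)
  )
}

test_that("variance agrees with the independent term-by-term oracle to 1e-10 relative", {
  d <- make_cluster_fixture()
  des <- svy_design(d, "s", "p", "w")
  est <- svy_mean(des, "y")
  oracle <- oracle_mean_se(d, "s", "p", "w", "y")
  expect_equal(est$estimate, oracle$estimate, tolerance = 1e-12)
  expect_equal(est$se^2, oracle$variance, tolerance = 1e-10)

  # same agreement under a domain and missing outcome values
  d2 <- d
  d2$y[sample.int(nrow(d2), 25)] <- NA
  des2 <- subset_design(svy_design(d2, "s", "p", "w"), age > 40)
  est2 <- svy_mean(des2, "y")
  oracle2 <- oracle_mean_se(d2, "s", "p", "w", "y", domain = d2$age > 40)
  expect_equal(est2$estimate, oracle2$estimate, tolerance = 1e-12)
  expect_equal(est2$se^2, oracle2$variance, tolerance = 1e-10)
  expect_identical(est2$n_obs, sum(d2$age > 40 & !is.na(d2$y)))
})

test_that("estimates and standard errors are invariant to rescaling all weights", {
  d <- make_cluster_fixture(seed = 77)
  base <- svy_mean(svy_design(d, "s", "p", "w"), "y")
  d$w <- d$w * 1000
  scaled <- svy_mean(svy_design(d, "s", "p", "w"), "y")
  expect_equal(scaled$estimate, base$estimate, tolerance = 1e-12)
  expect_equal(scaled$se, base$se, tolerance = 1e-12)
})

test_that("domain estimation differs from naive row deletion", {
  # constructed so one PSU holds only out-of-domain (young) respondents:
  # deleting rows before building the design silently removes that PSU
  # from its stratum's between-PSU comparison, changing the variance
  set.seed(4242)
  d <- tibble::tibble(
    s = rep(1:3, each = 9),
    p = rep(rep(1:3, each = 3), times = 3),
    w = stats::runif(27, 1, 5),
    age = c(rep(25, 3), sample(41:80, 24, replace = TRUE)),  # PSU (1,1) all young
    y = stats::rnorm(27, 75, 8)
  )
  domain_est <- svy_mean(subset_design(svy_design(d, "s", "p", "w"), age > 40), "y")
  deleted <- d[d$age > 40, , drop = FALSE]
  deleted_est <- svy_mean(svy_design(deleted, "s", "p", "w"), "y")
  # the point estimate is identical; the variance is not, because deletion
  # forgets that stratum 1 had three PSUs
  expect_equal(domain_est$estimate, deleted_est$estimate, tolerance = 1e-12)
  expect_gt(abs(domain_est$se - deleted_est$se), 1e-6)
})

test_that("subsets compose like their conjunction and an all-true subset is the identity", {
  d <- make_cluster_fixture(seed = 9)
  des <- svy_design(d, "s", "p", "w")
  a_then_b <- subset_design(subset_design(des, age > 40), y > 70)
  both <- subset_design(des, age > 40 & y > 70)
  expect_identical(a_then_b$domain, both$domain)
  expect_equal(svy_mean(a_then_b, "y"), svy_mean(both, "y"))

  all_true <- subset_design(des, rep(TRUE, nrow(d)))
  expect_equal(svy_mean(all_true, "y"), svy_mean(des, "y"))
  expect_error(subset_design(des, age > 1000), "empty domain")
})

test_that("grouped estimation equals one-at-a-time domain estimation, in category order", {
  d <- make_cluster_fixture(seed = 31)
  d$g <- factor(sample(c("A", "B", "C"), nrow(d), replace = TRUE),
                levels = c("A", "B", "C"))
  des <- svy_design(d, "s", "p", "w")
  by <- svy_mean_by(des, "y", "g")
  expect_identical(as.character(by$g), c("A", "B", "C"))
  for (lv in levels(d$g)) {
    manual <- svy_mean(subset_design(des, g == lv), "y")
    row <- by[by$g == lv, ]
    expect_equal(row$estimate, manual$estimate, tolerance = 1e-12)
    expect_equal(row$se, manual$se, tolerance = 1e-12)
  }
})

test_that("a category with no usable observations is flagged, not dropped", {
  d <- make_cluster_fixture(seed = 8)
  d$g <- factor(rep("A", nrow(d)), levels = c("A", "Empty"))
  by <- svy_mean_by(svy_design(d, "s", "p", "w"), "y", "g")
  expect_identical(nrow(by), 2L)
  expect_identical(by$n_obs[by$g == "Empty"], 0L)
  expect_true(is.na(by$estimate[by$g == "Empty"]))
})

test_that("lonely-PSU strata follow the chosen policy", {
  d <- tibble::tibble(
    y = c(1, 2, 3, 4, 5), s = c(1, 1, 1, 1, 2), p = c(1, 1, 2, 2, 1), w = 1
  )
  expect_error(svy_design(d, "s", "p", "w"), "lonely PSU")
  cent <- svy_mean(svy_design(d, "s", "p", "w", lonely_psu = "centered"), "y")
  cert <- svy_mean(svy_design(d, "s", "p", "w", lonely_psu = "certainty"), "y")
  expect_gt(cent$se, cert$se)  # the centered policy adds the lone stratum's term
  expect_equal(cent$estimate, cert$estimate)
})

test_that("design construction validates weights and design columns", {
  d <- tibble::tibble(y = c(1, 2), s = 1, p = 1:2, w = c(1, 0))
  expect_error(svy_design(d, "s", "p", "w"), "strictly positive")
  d <- tibble::tibble(y = c(1, 2, 3, 4), s = 1, p = c(1, 2, 1, 2),
                      w = c(1, 1, 1, NA))
  expect_warning(des <- svy_design(d, "s", "p", "w"), "missing weight")
  expect_identical(nrow(des$data), 3L)
  expect_error(svy_design(d, "s", "p", "nope"), "not found")
  d2 <- tibble::tibble(y = 1:4, s = c(1, 1, 2, 2), p = c(1, 2, 1, 2), w = 1)
  expect_error(svy_design(d2, "s", "p", "w", nested = FALSE), "repeat across strata")
  des2 <- svy_design(d2, "s", "p", "w", nested = TRUE)
  expect_identical(nrow(des2$psu_census), 4L)
})

test_that("naive means are plain arithmetic per category", {
  d <- tibble::tibble(y = c(5, 5, 7, NA),
                      g = factor(c("A", "A", "B", "B")))
  res <- naive_mean_by(d, "y", "g")
  expect_equal(res$mean, c(5, 7))
  expect_identical(res$n, c(2L, 1L))
  overall <- naive_mean_by(d, "y")
  expect_equal(overall$mean, mean(c(5, 5, 7)))
})

test_that("one informative sample shows the designed naive bias and weighted recovery", {
  spec <- fx_spec()
  pop <- fx_population()
  truth <- attr(pop, "truth")
  samp <- draw_sample(pop, spec, seed = 314)
  est <- svy_mean(svy_design(samp), "Y")
  expect_lt(abs(est$estimate - truth$population_mean), 4 * est$se)
  # the unweighted mean misses by more than the weighted one here
  expect_gt(abs(mean(samp$Y) - truth$population_mean),
            abs(est$estimate - truth$population_mean))
})

test_that("tidy, glance and autoplot expose the design and estimates", {
  d <- make_cluster_fixture(seed = 3)
  d$g <- factor(sample(c("A", "B"), nrow(d), replace = TRUE))
  des <- subset_design(svy_design(d, "s", "p", "w"), age > 40)
  td <- tidy(des)
  expect_identical(nrow(td), nrow(des$psu_census))
  expect_identical(sum(td$n_domain), sum(des$domain))
  gl <- glance(des)
  expect_identical(gl$n_domain, sum(des$domain))
  by <- svy_mean_by(des, "y", "g")
  expect_false(inherits(tidy(by), "svy_estimate"))
  p <- autoplot(by)
  expect_s3_class(p, "ggplot")
  cmp <- compare_means(des, "y", "g")
  expect_identical(names(cmp), c("g", "raw_mean", "adj_mean", "adj_se", "n_obs"))
  raw <- naive_mean_by(d[des$domain, ], "y", "g")
  expect_equal(cmp$raw_mean, raw$mean[match(cmp$g, raw$g)])
})
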