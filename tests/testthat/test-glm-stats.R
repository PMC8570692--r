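test_that("design encoding keeps A/B/mixtures and drops C and D", {
  trials <- make_trials(c(1, 0.85, 0.5, 0.15, 0, NA, NA),
                        group = "air_puff")
  trials$odor[6:7] <- c("C", "D")
  d <- encode_design(trials)
  expect_identical(nrow(d), 5L)
  expect_equal(d$mixture, c(1, 0.85, 0.5, 0.15, 0))
  expect_equal(d$group, rep(1L, 5))
  expect_equal(d$interaction, d$mixture)
  # pure denatonium, no-air-puff row encodes as (1, 0, 0, 0)
  d0 <- encode_design(make_trials(0))
  expect_equal(unlist(d0[1, c("mixture", "group", "interaction")]),
               c(mixture = 0, group = 0, interaction = 0))
  bad <- trials; bad$odor[1] <- "E"
  expect_error(encode_design(bad), "unknown odor")
})

test_that("Poisson GLM handles constants and validates counts", {
  d <- data.frame(mixture = rep(c(0, 0.5, 1), 20), group = rep(0:1, 30))
  fit <- fit_poisson_glm(rep(4, 60), d)
  expect_equal(unname(fit$coefficients["intercept"]), log(4), tolerance = 1e-6)
  expect_equal(unname(abs(fit$coefficients[c("mixture", "group", "interaction")])),
               rep(0, 3), tolerance = 1e-6)
  expect_error(fit_poisson_glm(c(rep(1, 59), -1), d), "non-negative")
  expect_error(fit_poisson_glm(c(rep(1, 59), 1.5), d), "integers")
})

test_that("GLM estimates equal a brute-force Newton likelihood maximizer", {
  set.seed(33)
  for (i in 1:5) {
    d <- data.frame(mixture = sample(c(0, 0.15, 0.5, 0.85, 1), 50, TRUE),
                    group = sample(0:1, 50, TRUE))
    mu <- exp(log(5) + 0.4 * d$mixture + 0.3 * d$group)
    y <- rpois(50, mu)
    fit <- fit_poisson_glm(y, d)
    oracle <- brute_poisson_mle(y, d)
    expect_equal(fit$coefficients[names(oracle)], oracle, tolerance = 1e-8)
  }
})

test_that("saturated two-cell design reproduces the count-ratio rate ratio", {
  d <- data.frame(mixture = rep(c(0, 1), each = 30), group = 0)
  y <- c(rep(2, 30), rep(6, 30))
  fit <- fit_poisson_glm(y, d)
  expect_equal(unname(exp(fit$coefficients["mixture"])), 3, tolerance = 1e-6)
})

test_that("z statistics respect the odor-relabeling symmetry", {
  set.seed(44)
  d <- data.frame(mixture = rep(c(0, 0.15, 0.5, 0.85, 1), 200),
                  group = rep(0:1, 500))
  y <- rpois(1000, exp(1 + 0.5 * d$mixture + 0.2 * d$group +
                         0.1 * d$mixture * d$group))
  f1 <- fit_poisson_glm(y, d)
  d2 <- transform(d, mixture = 1 - mixture)
  f2 <- fit_poisson_glm(y, d2)
  b1 <- f1$coefficients; b2 <- f2$coefficients
  expect_equal(unname(b2["mixture"]), unname(-b1["mixture"]), tolerance = 1e-8)
  expect_equal(unname(b2["interaction"]), unname(-b1["interaction"]),
               tolerance = 1e-8)
  expect_equal(unname(b2["intercept"]), unname(b1["intercept"] + b1["mixture"]),
               tolerance = 1e-8)
  expect_equal(unname(b2["group"]), unname(b1["group"] + b1["interaction"]),
               tolerance = 1e-8)
  expect_equal(abs(unname(f2$z["mixture"])), abs(unname(f1$z["mixture"])),
               tolerance = 1e-6)
})

test_that("CS-response correlation and its bootstrap CI behave", {
  x <- c(1, 2, 3, 4, 5)
  res <- cs_response_correlation(x, x, n_boot = 200, seed = 1)
  expect_equal(res$r, 1)
  # independent vectors: r near 0
  set.seed(8)
  a <- rnorm(1000); b <- rnorm(1000)
  res0 <- cs_response_correlation(a, b, n_boot = 500, seed = 2)
  expect_lt(abs(res0$r), 0.1)
  expect_true(res0$ci_low <= res0$r && res0$r <= res0$ci_high)
  expect_error(cs_response_correlation(1:2, 2:3), "at least 3")
  expect_error(cs_response_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("bootstrap CI covers a true correlation at near-nominal rate", {
  cover <- vapply(1:60, function(s) {
    set.seed(s)
    z <- rnorm(300)
    x <- z + rnorm(300)
    y <- 0.75 * z + rnorm(300)
    # var(x) = 2, var(y) = 0.75^2 + 1, cov = 0.75
    rho <- 0.75 / (sqrt(2) * sqrt(0.75^2 + 1))
    ci <- cs_response_correlation(x, y, n_boot = 400, seed = s)
    ci$ci_low <= rho && rho <= ci$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("count aggregation reproduces printed-fraction arithmetic", {
  cs <- count_summary(5, 10, 35)
  expect_equal(cs$fraction_responsive_pct, 100 * 15 / 35)
  expect_identical(cs$fraction_responsive_reported, 43)
  expect_identical(count_summary(0, 0, 20)$fraction_responsive_reported, 0)
  expect_error(count_summary(10, 15, 20), "exceeds")

  units <- data.frame(
    group = rep(c("air_puff", "no_air_puff"), c(35, 20)),
    direction = c(rep("increase", 5), rep("decrease", 10), rep("none", 20),
                  rep("increase", 2), rep("none", 18))
  )
  agg <- aggregate_counts(units)
  ap <- agg[agg$group == "air_puff", ]
  expect_identical(ap$fraction_responsive_reported, 43)
  # conservation: categories partition each group's units
  tab <- table(units$group, units$direction)
  for (g in rownames(tab)) {
    row <- agg[agg$group == g, ]
    expect_identical(row$n_increase + row$n_decrease +
                       sum(units$group == g & units$direction == "none"),
                     row$n_total)
  }
})
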