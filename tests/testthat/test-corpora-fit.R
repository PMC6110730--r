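test_that("truncation keeps records from the age of first ovulation", {
  d <- data.frame(age = c(2, 4, 6), corpora = c(0, 1, 3))
  expect_equal(truncate_to_first_ovulation(d)$age, c(4, 6))
  # a zero-corpora record at the first-ovulation age is retained
  d2 <- data.frame(age = c(4, 4, 6), corpora = c(0, 2, 3))
  expect_equal(nrow(truncate_to_first_ovulation(d2)), 3L)
  d3 <- data.frame(age = c(2, 4), corpora = c(0, 0))
  expect_error(truncate_to_first_ovulation(d3), "all corpora counts are zero")
})

test_that("exact linear and quadratic relationships are recovered", {
  d <- data.frame(age = 1:10, corpora = 2 * (1:10))
  fit <- suppressWarnings(corpora_fit(corpora ~ age, d))
  expect_equal(fit$model, "linear")
  expect_equal(coef(fit)[["beta1"]], 2, tolerance = 1e-8)

  d2 <- data.frame(age = 1:20, corpora = 40 * (1:20) - (1:20)^2)
  fit2 <- suppressWarnings(corpora_fit(corpora ~ age, d2))
  expect_equal(fit2$model, "quadratic")
  expect_equal(coef(fit2)[["beta1"]], 40, tolerance = 1e-6)
  expect_equal(coef(fit2)[["beta2"]], -1, tolerance = 1e-6)
})

test_that("age-independent corpora are classified as no correlation", {
  d <- physprr:::with_seed(7, data.frame(age = 1:50,
                                         corpora = rnorm(50, 5, 3)))
  fit <- corpora_fit(corpora ~ age, d)
  # independent least-squares refit of the quadratic via normal equations
  X <- cbind(1, d$age, d$age^2)
  beta <- solve(crossprod(X), crossprod(X, d$corpora))
  res <- d$corpora - X %*% beta
  r2 <- 1 - sum(res^2) / sum((d$corpora - mean(d$corpora))^2)
  adj <- 1 - (1 - r2) * (50 - 1) / (50 - 3)
  expect_equal(unname(fit$adj_r2[["quadratic"]]), adj, tolerance = 1e-10)
  expect_lte(fit$adj_r2_best, 0.1)
  expect_equal(fit$model, "none")
  expect_error(ovarian_activity(fit), "no usable")
})

test_that("degenerate inputs are rejected", {
  expect_error(corpora_fit(corpora ~ age,
                           data.frame(age = c(1, 2, 3), corpora = c(1, 2, 3))),
               "at least 4")
  expect_error(corpora_fit(corpora ~ age,
                           data.frame(age = c(1, 1, 2, 2), corpora = 1:4)),
               "3 distinct ages")
})

test_that("ovarian activity is the clipped slope of the fitted curve", {
  d <- data.frame(age = 1:30, corpora = 40 * (1:30) - (1:30)^2)
  fit <- suppressWarnings(corpora_fit(corpora ~ age, d))
  act <- ovarian_activity(fit, ages = c(10, 25))
  expect_equal(act$activity, c(20, 0))  # m(x) = 40 - 2x, clipped at 20

  # numeric-derivative oracle on the unclipped region
  d2 <- simulate_species(cfg_senescent(n = 500, seed = 21))
  fit2 <- corpora_fit(corpora ~ age, truncate_to_first_ovulation(d2))
  expect_equal(fit2$model, "quadratic")
  ages <- seq(fit2$a_b + 1, min(fit2$a_max - 1,
                                -coef(fit2)[["beta1"]] / (2 * coef(fit2)[["beta2"]]) - 1))
  h <- 1e-3
  deriv <- unname((predict(fit2, ages + h) - predict(fit2, ages - h)) / (2 * h))
  expect_equal(ovarian_activity(fit2, ages = ages)$activity, deriv,
               tolerance = 1e-6)

  lin <- suppressWarnings(corpora_fit(corpora ~ age,
                                      data.frame(age = 1:10, corpora = 2 * (1:10))))
  expect_true(all(ovarian_activity(lin, ages = 1:10)$activity == 2))
})

test_that("the senescence rate matches its closed forms", {
  parab <- function(b1, b2, ages) {
    data.frame(age = ages, corpora = b1 * ages + b2 * ages^2)
  }
  # activity zero exactly at the oldest age: rho = 1
  f1 <- suppressWarnings(corpora_fit(corpora ~ age, parab(24, -1, 2:12)))
  expect_equal(senescence_rate(f1), 1, tolerance = 1e-9)
  # activity zero at the midpoint of the adult span: rho = 2
  f2 <- suppressWarnings(corpora_fit(corpora ~ age, parab(14, -1, 2:12)))
  expect_equal(senescence_rate(f2), 2, tolerance = 1e-9)
  # worked example: 40x - x^2 on ages 5..15 gives 2*1*10/30
  f3 <- suppressWarnings(corpora_fit(corpora ~ age, parab(40, -1, 5:15)))
  expect_equal(senescence_rate(f3), 2 / 3, tolerance = 1e-9)
  # errors when there is no declining quadratic activity
  f4 <- suppressWarnings(corpora_fit(corpora ~ age,
                                     data.frame(age = 1:10, corpora = 2 * (1:10))))
  expect_error(senescence_rate(f4), "quadratic")
})

test_that("the senescence rate is invariant to rescaling corpora", {
  for (i in 1:5) {
    d <- simulate_species(cfg_senescent(n = 400, seed = 30 + i))
    d <- truncate_to_first_ovulation(d)
    f <- corpora_fit(corpora ~ age, d)
    if (f$model != "quadratic" || coef(f)[["beta2"]] >= 0) next
    d2 <- transform(d, corpora = corpora * 3.7)
    expect_equal(senescence_rate(corpora_fit(corpora ~ age, d2)),
                 senescence_rate(f), tolerance = 1e-9)
  }
})

test_that("record exclusion refits the model", {
  d <- data.frame(id = 1:12, age = c(2:12, 30),
                  corpora = c(14 * (2:12) - (2:12)^2, 500))
  f <- suppressWarnings(corpora_fit(corpora ~ age, d))
  rho_excl <- suppressWarnings(senescence_rate(f, exclude = 12))
  expect_equal(rho_excl, 2, tolerance = 1e-9)
})

test_that("constant ovulation is mostly classified linear", {
  picks <- vapply(1:100, function(i) {
    d <- simulate_species(cfg_constant(n = 500, seed = 100 + i))
    corpora_fit(corpora ~ age, truncate_to_first_ovulation(d))$model
  }, character(1))
  # AIC's 2-unit penalty admits a spurious quadratic with probability
  # P(chi2_1 > 2) ~= 0.16, so linear dominates without being universal
  expect_gt(mean(picks == "linear"), 0.7)
  expect_false(any(picks == "none"))
})

test_that("the fitted vertex recovers the cessation age", {
  # ovulation declines linearly from 1 at maturity 5 to 0 at age 20 and
  # deaths occur at the cessation age, so the cumulative curve is an exact
  # parabola with vertex 20 over the whole observed span
  vertices <- vapply(1:100, function(i) {
    cfg <- sim_config(500, data.frame(age = c(5, 20), rate = c(1, 0)),
                      survival = 20, maturity_age = 5, seed = 200 + i)
    f <- corpora_fit(corpora ~ age,
                     truncate_to_first_ovulation(simulate_species(cfg)))
    b <- coef(f)
    if (f$best != "quadratic" || b[["beta2"]] >= 0) return(NA_real_)
    -b[["beta1"]] / (2 * b[["beta2"]])
  }, numeric(1))
  expect_gt(mean(!is.na(vertices)), 0.9)
  med <- median(vertices, na.rm = TRUE)
  expect_gte(med, 18.5)
  expect_lte(med, 21.5)
})

test_that("activity is non-negative and non-increasing for declining fits", {
  for (i in 1:10) {
    d <- simulate_species(cfg_senescent(n = 400, seed = 300 + i))
    f <- corpora_fit(corpora ~ age, truncate_to_first_ovulation(d))
    if (f$model != "quadratic" || coef(f)[["beta2"]] >= 0) next
    act <- ovarian_activity(f)
    expect_true(all(act$activity >= 0))
    expect_true(all(diff(act$activity) <= 1e-12))
  }
})

test_that("model methods behave like a standard fitted model", {
  d <- simulate_species(cfg_senescent(n = 300, seed = 17))
  f <- corpora_fit(corpora ~ age, truncate_to_first_ovulation(d))
  expect_output(print(f), "classification")
  expect_output(print(summary(f)), "Quadratic fit")
  expect_length(fitted(f), f$n)
  expect_equal(unname(fitted(f) + residuals(f)),
               truncate_to_first_ovulation(d)$corpora)
  sim <- simulate(f, nsim = 2, seed = 1)
  expect_identical(dim(sim), c(f$n, 2L))
  expect_identical(sim, simulate(f, nsim = 2, seed = 1))
})
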