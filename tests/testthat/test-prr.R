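test_that("age M matches its closed forms", {
  # constant fecundity on [0, 10]: 95% of the mass by age 9.5
  s <- data.frame(age = 0:10, activity = rep(1, 11))
  expect_equal(age_m(s), 9.5)
  # linear decline to zero at x0: M = x0 (1 - sqrt(0.05))
  s2 <- data.frame(age = seq(0, 10, 0.5),
                   activity = 1 - seq(0, 10, 0.5) / 10)
  expect_equal(age_m(s2), 10 * (1 - sqrt(0.05)), tolerance = 1e-6)
  expect_error(age_m(data.frame(age = 0:3, activity = rep(0, 4))),
               "no positive mass")
})

test_that("age M agrees with a fine-grid integration oracle", {
  s <- data.frame(age = 10:13, activity = rep(1, 4))
  grid <- seq(10, 13, by = 1e-4)
  mfine <- approx(s$age, s$activity, xout = grid)$y
  cum <- cumsum(c(0, diff(grid) * (head(mfine, -1) + tail(mfine, -1)) / 2))
  oracle <- grid[which(cum >= 0.95 * cum[length(cum)])[1]]
  expect_equal(age_m(s), oracle, tolerance = 0.01)
})

test_that("PrR matches its closed forms and limits", {
  lt <- structure(data.frame(age = 0:10, lx = rep(1, 11)),
                  class = c("life_table", "data.frame"), r = 0)
  expect_equal(compute_prr(lt, 5), 0.5)   # uniform death at 10, M = 5
  expect_equal(compute_prr(lt, 10), 0)    # M at the oldest age
  expect_equal(compute_prr(lt, 12), 0)    # M beyond the oldest age
  expect_error(compute_prr(lt, -1), "below")
})

test_that("PrR equals the person-years enumeration oracle", {
  lt <- structure(data.frame(age = 0:3, lx = c(1, 0.75, 0.5, 0.25)),
                  class = c("life_table", "data.frame"), r = 0)
  expect_equal(compute_prr(lt, 2), oracle_prr(lt, 2), tolerance = 1e-10)
  physprr:::with_seed(42, {
    for (i in 1:100) {
      rlt <- random_life_table(8)
      M <- runif(1, min(rlt$age), max(rlt$age) + 1)
      expect_equal(compute_prr(rlt, M), oracle_prr(rlt, M),
                   tolerance = 1e-10)
    }
  })
})

test_that("PrR lies in [0,1] and decreases as M grows", {
  physprr:::with_seed(43, {
    for (i in 1:20) {
      rlt <- random_life_table(8)
      Ms <- seq(min(rlt$age), max(rlt$age), length.out = 6)
      prrs <- vapply(Ms, function(M) compute_prr(rlt, M), numeric(1))
      expect_true(all(prrs >= 0 & prrs <= 1))
      expect_true(all(diff(prrs) < 0))
      expect_equal(prrs[1], 1)
    }
  })
})

test_that("PrR is non-decreasing in the growth rate", {
  for (i in 1:20) {
    d <- simulate_species(cfg_senescent(n = 400, seed = 500 + i))
    tr <- truncate_to_first_ovulation(d)
    ct <- build_cohorts(tr$age)
    M <- min(tr$age) + 0.6 * diff(range(tr$age))
    prrs <- vapply(c(-0.1, 0, max_feasible_growth(ct)), function(r) {
      compute_prr(survival_from_cohorts(ct, r), M)
    }, numeric(1))
    expect_true(all(diff(prrs) >= -1e-12))
  }
})

test_that("the significance test ranks the observed value correctly", {
  d <- simulate_species(cfg_senescent(n = 800, seed = 77))
  lt <- survival_from_cohorts(build_cohorts(truncate_to_first_ovulation(d)$age), 0)
  s0 <- prr_significance(lt, 0, n_pops = 100, n_ind = 300, seed = 1)
  expect_true(all(s0$null_prr > 0))
  expect_equal(s0$p_upper, 1)           # every null PrR exceeds 0
  expect_lt(s0$p_value, 0.05)           # but the lower tail is extreme
  # an observed value at the null median is unremarkable
  for (seed in 1:3) {
    s <- prr_significance(lt, 0.2, n_pops = 200, n_ind = 500, seed = seed)
    s2 <- prr_significance(lt, median(s$null_prr), n_pops = 200,
                           n_ind = 500, seed = seed)
    expect_gte(s2$p_value, 0.9)
  }
  # deterministic given a seed
  sa <- prr_significance(lt, 0.2, n_pops = 50, n_ind = 200, seed = 9)
  sb <- prr_significance(lt, 0.2, n_pops = 50, n_ind = 200, seed = 9)
  expect_identical(sa$null_prr, sb$null_prr)
})

test_that("pregnancy-rate fecundity mirrors ovarian activity", {
  d <- data.frame(species = "p", id = 1:10, age = rep(5, 10),
                  corpora = 1:10, pregnant = rep(1, 10))
  expect_true(all(fecundity_from_pregnancy(d, bandwidth = 2)$activity == 1))
  expect_error(fecundity_from_pregnancy(d[, 1:4]), "no pregnancy")

  # pregnancies cease at age 20: the smoothed rate is 0 past 20 + bandwidth
  d2 <- simulate_species(cfg_senescent(n = 2000, seed = 3,
                                       pregnancy_rate = 0.8))
  sched <- fecundity_from_pregnancy(d2, bandwidth = 3)
  expect_true(all(sched$activity[sched$age > 23] == 0))

  # age M from pregnancy agrees with age M from ovarian activity when
  # both cease together at the end of the observed span
  d3 <- simulate_species(cfg_senescent(n = 2000, seed = 3, survival = 20,
                                       pregnancy_rate = 0.8))
  tr <- truncate_to_first_ovulation(d3)
  fit <- corpora_fit(corpora ~ age, tr)
  m_act <- age_m(ovarian_activity(fit))
  m_preg <- age_m(fecundity_from_pregnancy(d3, bandwidth = 3))
  expect_lte(abs(m_preg - m_act), 2)
})

test_that("the full pipeline identifies the three archetypes", {
  # reproductive cessation at half the adult span with long survival after
  res <- analyze_species(simulate_species(cfg_senescent(n = 1000, seed = 11)),
                         n_pops = 200, n_ind = 500, seed = 11)
  expect_equal(res$classification, "quadratic")
  expect_gt(res$rho, 1)
  stable <- res$scenarios[res$scenarios$scenario == "stable", ]
  expect_lt(stable$p_value, 0.05)
  expect_match(res$conclusion, "post-reproductive lifespans")
  expect_true(all(diff(res$scenarios$prr[order(res$scenarios$r)]) >= -1e-12))

  # constant ovulation until death: linear for most seeds, never senescent
  out <- lapply(1:5, function(i) {
    analyze_species(simulate_species(cfg_constant(n = 1000, seed = i)),
                    n_pops = 50, n_ind = 300, seed = i)
  })
  kinds <- vapply(out, `[[`, character(1), "classification")
  expect_gt(mean(kinds == "linear"), 0.5)
  for (r in out[kinds == "linear"]) {
    expect_null(r$scenarios)            # no PrR for non-senescent species
    expect_equal(r$conclusion, "No reproductive senescence")
  }

  # corpora unrelated to age
  res3 <- analyze_species(noise_dataset(seed = 7), seed = 7)
  expect_equal(res3$classification, "none")
  expect_match(res3$conclusion, "not a good measure")
  expect_output(print(res3), "conclusion")
})
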