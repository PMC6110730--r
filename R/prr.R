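#' Age at which 95% of population fecundity is completed (age M)
#'
#' Integrates the age-specific fecundity schedule (trapezoidal rule, with
#' the schedule linear within grid steps so the crossing is solved exactly)
#' and returns the smallest age at which the cumulative integral reaches
#' `quantile` of the total. Age M marks the onset of the post-reproductive
#' window; it depends only on the fecundity schedule and is therefore
#' identical across population growth scenarios.
#'
#' @param schedule An [ovarian_activity()] schedule, or any data frame
#'   whose first two columns are an increasing age grid and a non-negative
#'   rate.
#' @param quantile Completed-fecundity quantile defining M (default 0.95).
#' @return Age M in years.
#' @examples
#' s <- data.frame(age = 0:10, activity = rep(1, 11))
#' age_m(s)  # 9.5
#' @export
age_m <- function(schedule, quantile = 0.95) {
  stopifnot(is.data.frame(schedule), ncol(schedule) >= 2L,
            is.numeric(quantile), length(quantile) == 1L,
            quantile > 0, quantile <= 1)
  x <- schedule[[1L]]
  m <- pmax(0, schedule[[2L]])
  stopifnot(is.numeric(x), !is.unsorted(x, strictly = TRUE))
  k <- length(x)
  if (k < 2L) stop("schedule needs at least two grid points")
  cumk <- c(0, cumsum(diff(x) * (m[-k] + m[-1L]) / 2))
  total <- cumk[k]
  if (total <= 0) stop("fecundity schedule has no positive mass")
  target <- quantile * total
  j <- which(cumk >= target * (1 - 1e-12))[1L]
  if (j == 1L) return(x[1L])
  need <- target - cumk[j - 1L]
  if (need <= 0) return(x[j - 1L])
  h <- x[j] - x[j - 1L]
  m1 <- m[j - 1L]
  m2 <- m[j]
  a <- (m2 - m1) / (2 * h)
  t <- if (abs(a) < 1e-14) {
    need / m1
  } else {
    (-m1 + sqrt(m1^2 + 4 * a * need)) / (2 * a)
  }
  x[j - 1L] + min(max(t, 0), h)
}

# Expected person-years lived above age x per female alive at the youngest
# table age: integral of l from x to omega, with l linear between yearly
# nodes (deaths spread uniformly within the year) and survivors to the
# final table age dying at that age.
person_years_above <- function(lt, x) {
  ages <- lt$age
  lx <- lt$lx
  omega <- ages[length(ages)]
  if (x >= omega) return(0)
  if (x <= ages[1L]) {
    xs <- ages
    ls <- lx
  } else {
    keep <- ages > x
    xs <- c(x, ages[keep])
    ls <- c(stats::approx(ages, lx, xout = x)$y, lx[keep])
  }
  k <- length(xs)
  sum(diff(xs) * (ls[-k] + ls[-1L]) / 2)
}

#' Post-reproductive representation
#'
#' The proportion of adult female-years in the population lived by
#' post-reproductive females: \eqn{PrR = T(M)/T(B)}, where \eqn{T(x)} is
#' the expected number of female-years lived above age \eqn{x} per female
#' reaching the age of adulthood \eqn{B} (the youngest life-table age),
#' with deaths spread uniformly within each year of age. Returns 0 when
#' \eqn{M} is at or beyond the oldest table age.
#'
#' @param lt A [survival_from_cohorts()] life table.
#' @param M Age at completed fecundity, from [age_m()]; must be at least
#'   the youngest table age.
#' @return PrR, a proportion in \[0, 1\].
#' @examples
#' lt <- structure(data.frame(age = 0:10, lx = rep(1, 11)),
#'                 class = c("life_table", "data.frame"))
#' compute_prr(lt, 5)  # 0.5: all females die at 10, post-reproductive from 5
#' @export
compute_prr <- function(lt, M) {
  stopifnot(is.data.frame(lt), all(c("age", "lx") %in% names(lt)),
            is.numeric(M), length(M) == 1L, is.finite(M))
  B <- lt$age[1L]
  omega <- lt$age[nrow(lt)]
  if (M < B - 1e-9) stop("age M is below the youngest life-table age")
  if (M >= omega) return(0)
  prr <- person_years_above(lt, max(M, B)) / person_years_above(lt, B)
  min(1, max(0, prr))
}

#' Monte-Carlo significance test for Phys-PrR
#'
#' Tests an observed post-reproductive representation against the null
#' hypothesis that reproductive senescence equals somatic senescence, i.e.
#' that age-specific fecundity is proportional to survivorship
#' (\eqn{m_0(x) \propto l(x)}), in which case any post-reproductive
#' representation arises from sampling noise alone. For each of `n_pops`
#' null populations, `n_ind` individual ages are drawn from the standing
#' age distribution implied by the life table and its growth rate
#' (\eqn{c(x) \propto l(x) e^{-rx}}, the same cross-sectional law the
#' estimator assumes), an empirical life table is rebuilt with the full
#' cohort-binning pipeline so that binning noise is inside the null, and a
#' null PrR is computed at the null age M derived from \eqn{m_0}.
#'
#' The upper-tail p-value uses an add-one pseudocount,
#' \eqn{p^+ = (1 + \#\{PrR_0 \ge PrR_{obs}\}) / (n_{pops} + 1)}, and the
#' reported two-tailed p doubles the smaller tail.
#'
#' @param lt Life table for the species and growth scenario.
#' @param observed_prr Observed Phys-PrR in \[0, 1\].
#' @param n_pops,n_ind Number of simulated populations and of individuals
#'   per population.
#' @param seed Optional integer seed.
#' @return An object of class `"prr_test"`: list with `p_value`
#'   (two-tailed), `p_upper`, `p_lower`, `null_prr` (the simulated null
#'   values), `null_m`, and the simulation sizes.
#' @export
prr_significance <- function(lt, observed_prr, n_pops = 1000, n_ind = 1000,
                             seed = NULL) {
  stopifnot(inherits(lt, "data.frame"), all(c("age", "lx") %in% names(lt)),
            is.numeric(observed_prr), length(observed_prr) == 1L,
            observed_prr >= 0, observed_prr <= 1,
            n_pops >= 1, n_ind >= 2)
  r <- attr(lt, "r")
  if (is.null(r)) r <- 0
  m0 <- data.frame(age = lt$age, activity = lt$lx)
  M0 <- age_m(m0)
  w <- lt$lx * exp(-r * lt$age)
  null_prr <- numeric(n_pops)
  n_retry <- 0L
  with_seed(seed, {
    for (k in seq_len(n_pops)) {
      repeat {
        a <- sample(lt$age, n_ind, replace = TRUE, prob = w)
        lt_k <- tryCatch({
          ct <- build_cohorts(a)
          r_k <- if (r > 0) min(r, max_feasible_growth(ct, cap = r)) else r
          survival_from_cohorts(ct, r_k)
        }, error = function(e) NULL)
        if (!is.null(lt_k)) break
        n_retry <- n_retry + 1L
        if (n_retry > n_pops + 100L) {
          stop("null simulation failed repeatedly to build life tables")
        }
      }
      null_prr[k] <- compute_prr(lt_k, max(M0, lt_k$age[1L]))
    }
  })
  p_upper <- (1 + sum(null_prr >= observed_prr - 1e-12)) / (n_pops + 1)
  p_lower <- 1 - p_upper + 1 / (n_pops + 1)
  structure(
    list(p_value = min(1, 2 * min(p_upper, p_lower)),
         p_upper = p_upper, p_lower = p_lower,
         null_prr = null_prr, null_m = M0,
         observed_prr = observed_prr,
         n_pops = n_pops, n_ind = n_ind, seed = seed, n_retry = n_retry),
    class = "prr_test"
  )
}

#' @export
print.prr_test <- function(x, digits = 4, ...) {
  cat("Phys-PrR significance test (", x$n_pops, " null populations of ",
      x$n_ind, " individuals)\n", sep = "")
  cat("  observed PrR: ", format(x$observed_prr, digits = digits), "\n")
  cat("  null PrR median [IQR]: ",
      format(stats::median(x$null_prr), digits = digits), " [",
      paste(format(stats::quantile(x$null_prr, c(0.25, 0.75)),
                   digits = digits), collapse = ", "), "]\n", sep = "")
  cat("  two-tailed p = ", format(x$p_value, digits = digits),
      " (upper tail ", format(x$p_upper, digits = digits), ")\n", sep = "")
  invisible(x)
}

#' Age-specific fecundity from pregnancy records
#'
#' Smooths per-record pregnancy indicators into an age-specific pregnancy
#' rate by a moving-window average: at each grid age the proportion
#' pregnant among records within `bandwidth` years. The result is usable
#' wherever an activity schedule is (e.g. in [age_m()]), allowing the
#' physiological fecundity measure to be validated against direct
#' observations of pregnancy.
#'
#' @param dataset Corpora data frame with a `pregnant` column of 0/1 flags.
#' @param bandwidth Half-width of the smoothing window in years.
#' @param ages Optional grid; defaults to whole years over the observed
#'   range.
#' @return An `"activity_schedule"` data frame with columns `age` and
#'   `activity` (pregnancy rate in \[0, 1\]).
#' @export
fecundity_from_pregnancy <- function(dataset, bandwidth = 5, ages = NULL) {
  stopifnot(is.data.frame(dataset))
  if (!"pregnant" %in% names(dataset) || nrow(dataset) == 0L) {
    stop("dataset has no pregnancy records")
  }
  stopifnot(bandwidth > 0)
  if (is.null(ages)) {
    ages <- seq(floor(min(dataset$age)), ceiling(max(dataset$age)))
  }
  rate <- vapply(ages, function(x) {
    sel <- abs(dataset$age - x) <= bandwidth
    if (!any(sel)) return(0)
    mean(dataset$pregnant[sel])
  }, numeric(1))
  structure(data.frame(age = ages, activity = pmin(1, pmax(0, rate))),
            class = c("activity_schedule", "data.frame"),
            a_b = min(ages), a_max = max(ages))
}

#' Full per-species physiological analysis
#'
#' Runs the complete pipeline behind one row of the species results table:
#' truncation to the age of first ovulation, age-corpora model fit and
#' classification, and — for species with declining ovarian activity —
#' the relative senescence rate, cohort life tables under three population
#' growth scenarios (shrinking r = -0.1, stable r = 0, growing r = the
#' largest feasible rate up to 0.1), age M, Phys-PrR per scenario and its
#' Monte-Carlo significance.
#'
#' The conclusion label follows the classification: species whose best
#' model explains essentially no variance are flagged as corpora not
#' measuring ovarian activity; a linear relationship means no reproductive
#' senescence; a declining quadratic means reproductive senescence, with
#' post-reproductive lifespans added when the stable-scenario PrR differs
#' significantly from the null.
#'
#' @param dataset Corpora data frame (`age`, `corpora`, optionally
#'   `species`, `id`, `pregnant`).
#' @param n_pops,n_ind Simulation sizes for [prr_significance()].
#' @param seed Optional master seed; per-scenario sub-seeds are derived
#'   from it.
#' @param alpha Significance level for the conclusion label.
#' @param growth_shrinking Shrinking-scenario growth rate (default -0.1).
#' @param growth_cap Cap for the growing scenario (default 0.1).
#' @return An object of class `"species_result"` with the fit, `rho`,
#'   cohort table, `age_m`, a `scenarios` data frame (r, PrR, p-values)
#'   and the `conclusion` label.
#' @export
analyze_species <- function(dataset, n_pops = 1000, n_ind = 1000,
                            seed = NULL, alpha = 0.05,
                            growth_shrinking = -0.1, growth_cap = 0.1) {
  species <- if ("species" %in% names(dataset) && nrow(dataset) > 0L) {
    as.character(dataset$species[1L])
  } else "unknown"
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  trunc <- stage("truncation", truncate_to_first_ovulation(dataset))
  fit <- stage("model fit", corpora_fit(corpora ~ age, trunc))
  res <- list(species = species, classification = fit$model, fit = fit,
              rho = NA_real_, cohorts = NULL, r_max = NA_real_,
              age_m = NA_real_, scenarios = NULL, seed = seed,
              alpha = alpha, n = nrow(trunc))
  declining <- fit$model == "quadratic" &&
    fit$coefficients[["beta2"]] < 0 &&
    fit$coefficients[["beta1"]] + 2 * fit$coefficients[["beta2"]] * fit$a_b > 0
  if (fit$model == "none") {
    res$conclusion <- "Corpora are not a good measure of ovarian activity"
    return(structure(res, class = "species_result"))
  }
  if (!declining) {
    res$conclusion <- "No reproductive senescence"
    return(structure(res, class = "species_result"))
  }
  res$rho <- stage("senescence rate", senescence_rate(fit))
  cohorts <- stage("cohort binning", build_cohorts(trunc$age))
  res$cohorts <- cohorts
  res$r_max <- max_feasible_growth(cohorts, cap = growth_cap)
  act <- stage("ovarian activity", ovarian_activity(fit))
  res$age_m <- stage("age M", age_m(act))
  rs <- c(shrinking = growth_shrinking, stable = 0, growing = res$r_max)
  scen <- lapply(names(rs), function(s) {
    lt <- stage(paste("life table,", s),
                survival_from_cohorts(cohorts, rs[[s]]))
    prr <- compute_prr(lt, max(res$age_m, lt$age[1L]))
    sig <- stage(paste("significance,", s),
                 prr_significance(lt, prr, n_pops = n_pops, n_ind = n_ind,
                                  seed = derive_seed(seed, s)))
    data.frame(scenario = s, r = rs[[s]], prr = prr,
               p_value = sig$p_value, p_upper = sig$p_upper,
               stringsAsFactors = FALSE)
  })
  res$scenarios <- do.call(rbind, scen)
  res$life_tables <- lapply(setNames(names(rs), names(rs)),
                            function(s) survival_from_cohorts(cohorts, rs[[s]]))
  stable <- res$scenarios[res$scenarios$scenario == "stable", ]
  # a significant *excess* of post-reproductive years: the upper tail must
  # be the small one, not a significantly low PrR
  res$conclusion <- if (stable$p_value < alpha && stable$p_upper <= 0.5) {
    "Reproductive senescence and post-reproductive lifespans"
  } else {
    "Reproductive senescence"
  }
  structure(res, class = "species_result")
}

#' @export
print.species_result <- function(x, digits = 2, ...) {
  cat("Species: ", x$species, "  (n = ", x$n, ")\n", sep = "")
  cat("  age-corpora relationship:", x$classification, "\n")
  if (is.finite(x$rho)) {
    cat("  relative rate of reproductive senescence:",
        format(round(x$rho, digits), nsmall = digits), "\n")
  }
  if (!is.null(x$scenarios)) {
    s <- x$scenarios
    fmt <- function(v) format(round(v, digits), nsmall = digits)
    star <- ifelse(s$p_value < x$alpha, "*", "")
    cat("  age M: ", format(round(x$age_m, 1), nsmall = 1),
        " yr;  Phys-PrR stable [shrinking - growing]: ",
        fmt(s$prr[s$scenario == "stable"]), star[s$scenario == "stable"],
        " [", fmt(s$prr[s$scenario == "shrinking"]),
        star[s$scenario == "shrinking"], " - ",
        fmt(s$prr[s$scenario == "growing"]), star[s$scenario == "growing"],
        "]\n", sep = "")
  }
  cat("  conclusion:", x$conclusion, "\n")
  invisible(x)
}
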