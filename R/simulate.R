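#' Configuration for a synthetic corpora dataset
#'
#' Describes an individual-based model of a female toothed-whale population:
#' an age-dependent annual ovulation rate (piecewise linear between knots),
#' a survival model, a maturity age, and an exponential population growth
#' rate that shapes the standing age distribution from which dead females
#' are sampled.
#'
#' @param n Number of females to sample.
#' @param ovulation_knots Two-column data frame or matrix of `(age, rate)`
#'   knots defining the annual ovulation rate \eqn{\lambda(x)} in
#'   ovulations/year. The rate is interpolated linearly between knots and
#'   held constant beyond the first and last knot. All rates must be
#'   non-negative.
#' @param survival Either a single number \eqn{\omega} (every female
#'   survives to exactly age \eqn{\omega}) or a numeric vector of per-year
#'   death probabilities starting at age 0; females still alive after the
#'   last scheduled year die in that year, so `length(survival)` is the
#'   maximum age.
#' @param maturity_age Age at first possible ovulation (years). Corpora
#'   accumulate from this age onwards.
#' @param growth_rate Per-year exponential population growth rate `r`. The
#'   standing age distribution sampled from is proportional to
#'   \eqn{l(x) e^{-rx}}: in a growing population young females are
#'   over-represented.
#' @param age_error_sd Standard deviation (years) of Gaussian age
#'   estimation error applied to the sampled ages (see [apply_age_error()]).
#' @param pregnancy_rate Optional maximum per-female pregnancy probability.
#'   When given, each record carries a `pregnant` flag drawn with
#'   probability `pregnancy_rate * lambda(age)/max(lambda)`, so pregnancy
#'   and ovulation cease at the same age.
#' @param species_label Species label written into the dataset.
#' @param seed Optional integer seed making [simulate_species()]
#'   deterministic.
#'
#' @return An object of class `"sim_config"`.
#' @seealso [simulate_species()]
#' @export
sim_config <- function(n,
                       ovulation_knots,
                       survival,
                       maturity_age = 0,
                       growth_rate = 0,
                       age_error_sd = 0,
                       pregnancy_rate = NULL,
                       species_label = "synthetic",
                       seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  kn <- as.data.frame(ovulation_knots)
  if (ncol(kn) < 2L) stop("`ovulation_knots` needs (age, rate) columns")
  kn <- data.frame(age = as.numeric(kn[[1L]]), rate = as.numeric(kn[[2L]]))
  if (any(!is.finite(kn$age)) || any(!is.finite(kn$rate))) {
    stop("ovulation knots must be finite")
  }
  if (is.unsorted(kn$age, strictly = TRUE)) {
    stop("ovulation knot ages must be strictly increasing")
  }
  if (any(kn$rate < 0)) stop("ovulation rate must be non-negative everywhere")
  if (length(survival) == 1L) {
    stopifnot(is.finite(survival), survival >= 1)
  } else {
    if (any(!is.finite(survival)) || any(survival < 0) || any(survival > 1)) {
      stop("per-year death probabilities must lie in [0, 1]")
    }
  }
  stopifnot(maturity_age >= 0, age_error_sd >= 0)
  if (!is.null(pregnancy_rate)) {
    stopifnot(pregnancy_rate >= 0, pregnancy_rate <= 1)
  }
  structure(
    list(n = as.integer(n), ovulation_knots = kn, survival = survival,
         maturity_age = maturity_age, growth_rate = growth_rate,
         age_error_sd = age_error_sd, pregnancy_rate = pregnancy_rate,
         species_label = species_label, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  omega <- if (length(x$survival) == 1L) x$survival else length(x$survival)
  cat("Synthetic corpora-dataset configuration\n")
  cat("  species:      ", x$species_label, "\n")
  cat("  n females:    ", x$n, "\n")
  cat("  maturity age: ", x$maturity_age, "yr\n")
  cat("  max age:      ", omega, "yr\n")
  cat("  growth rate:  ", x$growth_rate, "/yr\n")
  cat("  ovulation knots:\n")
  print(x$ovulation_knots, row.names = FALSE)
  invisible(x)
}

# Piecewise-linear cumulative ovulation rate: returns a vectorised function
# F with F(x) = integral of lambda from the first knot age to x, with
# lambda held constant beyond the outermost knots.
lambda_cumulative <- function(knots) {
  a <- knots$age
  r <- knots$rate
  k <- length(a)
  lam <- stats::approxfun(a, r, rule = 2)
  cumk <- if (k > 1L) c(0, cumsum(diff(a) * (r[-k] + r[-1L]) / 2)) else 0
  function(x) {
    i <- findInterval(x, a)
    out <- numeric(length(x))
    below <- i == 0L
    out[below] <- (x[below] - a[1L]) * r[1L]
    above <- i == k
    out[above] <- cumk[k] + (x[above] - a[k]) * r[k]
    mid <- !below & !above
    if (any(mid)) {
      xi <- x[mid]
      ii <- i[mid]
      out[mid] <- cumk[ii] + (xi - a[ii]) * (r[ii] + lam(xi)) / 2
    }
    out
  }
}

# Survivorship l(x) at integer ages 0..omega implied by a sim_config
# survival model: l(x) = P(alive at exact age x).
survivorship_from_config <- function(config) {
  s <- config$survival
  if (length(s) == 1L) {
    omega <- as.integer(floor(s))
    lx <- rep(1, omega + 1L)
  } else {
    omega <- length(s)
    lx <- c(1, cumprod(1 - s))
  }
  list(age = 0:omega, lx = lx)
}

#' Simulate a cross-sectional corpora dataset
#'
#' Draws `n` dead females from the standing age distribution implied by the
#' configuration's survival model and growth rate
#' (\eqn{c(x) \propto l(x) e^{-rx}}), and gives each a cumulative corpora
#' count drawn as a Poisson variate with mean equal to the integrated
#' ovulation rate from maturity to her age. Ages are whole years, the
#' resolution at which published corpora tables report them. When the
#' configuration specifies an age estimation error, the ages are then
#' perturbed with [apply_age_error()].
#'
#' @param config A [sim_config()] object.
#' @param seed Optional seed overriding `config$seed`.
#'
#' @return A data frame with columns `species`, `id`, `age`, `corpora` and,
#'   if `pregnancy_rate` was set, `pregnant`; the generating seed is
#'   attached as attribute `"seed"`.
#' @examples
#' cfg <- sim_config(200, data.frame(age = c(5, 20), rate = c(1, 0)),
#'                   survival = 35, maturity_age = 5, seed = 1)
#' head(simulate_species(cfg))
#' @export
simulate_species <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  surv <- survivorship_from_config(config)
  w <- surv$lx * exp(-config$growth_rate * surv$age)
  if (sum(w) <= 0) stop("survival schedule leaves no mass to sample from")
  Fcum <- lambda_cumulative(config$ovulation_knots)
  F0 <- Fcum(config$maturity_age)
  out <- with_seed(seed, {
    age <- sample(surv$age, config$n, replace = TRUE, prob = w)
    mu <- pmax(0, Fcum(age) - F0)
    corpora <- stats::rpois(config$n, mu)
    d <- data.frame(species = config$species_label,
                    id = seq_len(config$n),
                    age = as.numeric(age),
                    corpora = corpora,
                    stringsAsFactors = FALSE)
    if (!is.null(config$pregnancy_rate)) {
      lam <- stats::approxfun(config$ovulation_knots$age,
                              config$ovulation_knots$rate, rule = 2)
      peak <- max(config$ovulation_knots$rate)
      p <- if (peak > 0) config$pregnancy_rate * lam(age) / peak else 0
      p[age < config$maturity_age] <- 0
      d$pregnant <- stats::rbinom(config$n, 1L, pmin(1, pmax(0, p)))
    }
    if (config$age_error_sd > 0) {
      d <- apply_age_error(d, config$age_error_sd,
                           seed = derive_seed(seed, "age_error"))
    }
    d
  })
  attr(out, "seed") <- seed
  attr(out, "config") <- config
  out
}

#' Perturb ages with estimation error
#'
#' Adds zero-mean Gaussian noise with standard deviation `sd` to every age;
#' perturbed ages that fall below the dataset's minimum observed age are
#' redrawn, so the age support is preserved. Corpora counts are unchanged.
#' This re-creates the robustness check of the pipeline against errors in
#' age estimates from dentinal growth layers.
#'
#' @param dataset A corpora data frame with an `age` column.
#' @param sd Standard deviation of the age error in years (`sd = 0` returns
#'   the input unchanged).
#' @param seed Optional integer seed.
#' @return The dataset with perturbed ages.
#' @export
apply_age_error <- function(dataset, sd, seed = NULL) {
  stopifnot(is.data.frame(dataset), "age" %in% names(dataset))
  stopifnot(is.numeric(sd), length(sd) == 1L, is.finite(sd), sd >= 0)
  if (sd == 0 || nrow(dataset) == 0L) return(dataset)
  min_age <- min(dataset$age)
  with_seed(seed, {
    new_age <- dataset$age + stats::rnorm(nrow(dataset), 0, sd)
    for (iter in 1:1000) {
      low <- which(new_age < min_age)
      if (!length(low)) break
      new_age[low] <- dataset$age[low] + stats::rnorm(length(low), 0, sd)
    }
    new_age[new_age < min_age] <- min_age
    dataset$age <- new_age
    dataset
  })
}

#' Read and write corpora datasets as CSV
#'
#' The on-disk dialect is a plain CSV with header
#' `species,id,age,corpora[,pregnant]`, optionally preceded by `#`-prefixed
#' metadata lines recording the generating seed.
#'
#' @param dataset Corpora data frame.
#' @param path File path.
#' @return `read_corpora_csv()` returns the data frame;
#'   `write_corpora_csv()` returns `path` invisibly.
#' @export
write_corpora_csv <- function(dataset, path) {
  stopifnot(is.data.frame(dataset))
  con <- file(path, open = "wt")
  on.exit(close(con))
  seed <- attr(dataset, "seed")
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(dataset, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_corpora_csv
#' @export
read_corpora_csv <- function(path) {
  if (!file.exists(path)) stop("corpora file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  d <- utils::read.csv(text = lines[!grepl("^#", lines)],
                       stringsAsFactors = FALSE)
  req <- c("species", "id", "age", "corpora")
  if (!all(req %in% names(d))) {
    stop("corpora CSV must have columns: ", paste(req, collapse = ", "))
  }
  seed_line <- grep("^# seed:", meta, value = TRUE)
  if (length(seed_line)) {
    attr(d, "seed") <- as.numeric(sub("^# seed:\\s*", "", seed_line[1L]))
  }
  d
}
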