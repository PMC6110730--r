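#' Restrict a corpora dataset to ages from first ovulation
#'
#' Published corpora tables include immature females; the pipeline analyses
#' only records from the age of first ovulation, defined as the smallest
#' age at which any record has a non-zero corpora count. Records at exactly
#' that age with zero corpora are retained (they inform the intercept).
#'
#' @param dataset Data frame with `age` and `corpora` columns.
#' @return The restricted data frame.
#' @export
truncate_to_first_ovulation <- function(dataset) {
  stopifnot(is.data.frame(dataset),
            all(c("age", "corpora") %in% names(dataset)))
  if (nrow(dataset) == 0L) stop("empty dataset")
  if (all(dataset$corpora == 0)) {
    stop("all corpora counts are zero: no age of first ovulation exists")
  }
  first <- min(dataset$age[dataset$corpora > 0])
  dataset[dataset$age >= first, , drop = FALSE]
}

#' Fit age-corpora models and classify the species
#'
#' Fits ordinary least squares models `corpora ~ age` and
#' `corpora ~ age + age^2` and selects between them by AIC (Gaussian
#' likelihood, the usual 2k penalty). The linear model is the null: a
#' constant ovulation rate accumulates corpora linearly with age, whereas
#' reproductive senescence bends the relationship (negative quadratic
#' term). AIC ties resolve to the linear null. When the selected model's
#' adjusted R-squared is at most 0.1 the species is classified `"none"`:
#' corpora are not a usable measure of ovarian activity.
#'
#' @param formula A formula of the form `corpora ~ age` naming the count
#'   and age columns in `data`.
#' @param data Data frame holding the (already truncated) records; must
#'   have at least 4 records and 3 distinct ages.
#'
#' @return An object of class `"corpora_fit"` with components
#'   \describe{
#'     \item{model}{`"none"`, `"linear"` or `"quadratic"`.}
#'     \item{fits}{the two underlying `lm` objects.}
#'     \item{aic, adj_r2}{named vectors of per-model diagnostics.}
#'     \item{a_b, a_max}{first and last age in the data (years).}
#'   }
#'   Supports `print()`, `summary()`, `coef()`, `predict()`, `fitted()`,
#'   `residuals()`, `simulate()` and `plot()`.
#' @examples
#' d <- data.frame(age = 1:20, corpora = 40 * (1:20) - (1:20)^2)
#' fit <- corpora_fit(corpora ~ age, d)
#' fit
#' coef(fit)
#' @export
corpora_fit <- function(formula = corpora ~ age, data) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L) stop("formula must be of the form corpora ~ age")
  y <- mf[[1L]]
  x <- mf[[2L]]
  if (length(y) < 4L) stop("need at least 4 records to fit corpora models")
  if (length(unique(x)) < 3L) {
    stop("need at least 3 distinct ages (quadratic unidentifiable)")
  }
  d <- data.frame(.corpora = y, .age = x)
  fit_lin <- stats::lm(.corpora ~ .age, data = d)
  fit_quad <- stats::lm(.corpora ~ .age + I(.age^2), data = d)
  aic <- c(linear = stats::AIC(fit_lin), quadratic = stats::AIC(fit_quad))
  adj_r2 <- c(linear = summary(fit_lin)$adj.r.squared,
              quadratic = summary(fit_quad)$adj.r.squared)
  # linear is the null: quadratic must beat it outright
  best <- if (aic[["quadratic"]] < aic[["linear"]] - 1e-9) "quadratic" else "linear"
  model <- if (adj_r2[[best]] <= 0.1) "none" else best
  sel <- if (best == "quadratic") fit_quad else fit_lin
  beta <- unname(stats::coef(sel))
  coefs <- if (best == "quadratic") {
    c(beta0 = beta[1L], beta1 = beta[2L], beta2 = beta[3L])
  } else {
    c(beta0 = beta[1L], beta1 = beta[2L])
  }
  structure(
    list(model = model, best = best, fits = list(linear = fit_lin, quadratic = fit_quad),
         coefficients = coefs, aic = aic, adj_r2 = adj_r2,
         adj_r2_best = unname(adj_r2[[best]]),
         a_b = min(x), a_max = max(x), n = length(y),
         data = data, formula = formula, call = match.call()),
    class = "corpora_fit"
  )
}

selected_lm <- function(object) {
  object$fits[[if (object$model == "none") object$best else object$model]]
}

#' @export
print.corpora_fit <- function(x, digits = 4, ...) {
  cat("Age-corpora model fit (", x$n, " records, ages ",
      format(x$a_b), "-", format(x$a_max), ")\n", sep = "")
  cat("  classification:", x$model,
      if (x$model == "none") paste0("(best model adj-R2 = ",
                                    format(x$adj_r2_best, digits = digits),
                                    " <= 0.1)"), "\n")
  cat("  AIC: linear ", format(x$aic[["linear"]], digits = digits),
      ", quadratic ", format(x$aic[["quadratic"]], digits = digits), "\n", sep = "")
  cat("  adj-R2 (", x$best, "): ",
      format(x$adj_r2_best, digits = digits), "\n", sep = "")
  cat("  coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.corpora_fit <- function(object, ...) object$coefficients

#' @export
fitted.corpora_fit <- function(object, ...) fitted(selected_lm(object))

#' @export
residuals.corpora_fit <- function(object, ...) residuals(selected_lm(object))

#' Predicted corpora counts
#'
#' Expected cumulative corpora count under the selected model at the given
#' ages.
#'
#' @param object A [corpora_fit()] object.
#' @param ages Numeric ages at which to predict; defaults to the observed
#'   ages.
#' @param ... Unused.
#' @return Numeric vector of expected counts.
#' @export
predict.corpora_fit <- function(object, ages = NULL, ...) {
  if (is.null(ages)) return(fitted(object))
  stopifnot(is.numeric(ages))
  predict(selected_lm(object), newdata = data.frame(.age = ages))
}

#' @export
simulate.corpora_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(selected_lm(object), nsim = nsim, seed = seed, ...)
}

#' @export
summary.corpora_fit <- function(object, ...) {
  rho <- tryCatch(senescence_rate(object), error = function(e) NA_real_)
  structure(list(fit = object, rho = rho), class = "summary.corpora_fit")
}

#' @export
print.summary.corpora_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (is.finite(x$rho)) {
    cat("  relative rate of reproductive senescence:",
        format(x$rho, digits = digits), "\n")
  }
  cat("\nLinear fit:\n")
  print(summary(x$fit$fits$linear)$coefficients, digits = digits)
  cat("\nQuadratic fit:\n")
  print(summary(x$fit$fits$quadratic)$coefficients, digits = digits)
  invisible(x)
}

#' @export
plot.corpora_fit <- function(x, ...) {
  d <- data.frame(age = x$data[[all.vars(x$formula)[2L]]],
                  corpora = x$data[[all.vars(x$formula)[1L]]])
  plot(d$age, d$corpora, xlab = "age (yr)", ylab = "corpora count",
       main = paste0("age-corpora fit (", x$model, ")"), ...)
  ages <- seq(x$a_b, x$a_max, length.out = 200)
  lines(ages, predict(x, ages), lwd = 2)
  invisible(x)
}

#' Age-specific ovarian activity
#'
#' The instantaneous rate of new corpora formation implied by the fitted
#' age-corpora curve: its first derivative with respect to age,
#' \eqn{m(x) = \beta_1 + 2 \beta_2 x} for the quadratic model and the
#' constant slope for the linear model. Negative values are an artefact of
#' the quadratic form and are clipped to zero. Activity is a physiological
#' proxy for age-specific fecundity.
#'
#' @param fit A [corpora_fit()] object classified `"linear"` or
#'   `"quadratic"`.
#' @param ages Optional age grid; defaults to a regular grid over the
#'   observed adult span with the clipping kink included as a node, so the
#'   schedule is exactly piecewise linear.
#' @param step Grid spacing in years for the default grid.
#' @return A data frame of class `"activity_schedule"` with columns `age`
#'   and `activity` (ovulations/year).
#' @export
ovarian_activity <- function(fit, ages = NULL, step = 0.25) {
  stopifnot(inherits(fit, "corpora_fit"))
  if (fit$model == "none") {
    stop("no usable age-corpora relationship: activity undefined")
  }
  b <- fit$coefficients
  if (is.null(ages)) {
    ages <- seq(fit$a_b, fit$a_max, by = step)
    if (ages[length(ages)] < fit$a_max) ages <- c(ages, fit$a_max)
    if (fit$model == "quadratic" && b[["beta2"]] != 0) {
      kink <- -b[["beta1"]] / (2 * b[["beta2"]])
      if (kink > fit$a_b && kink < fit$a_max) ages <- sort(c(ages, kink))
    }
  }
  stopifnot(is.numeric(ages), !is.unsorted(ages, strictly = TRUE))
  m <- if (fit$model == "quadratic") {
    pmax(0, b[["beta1"]] + 2 * b[["beta2"]] * ages)
  } else {
    rep(max(0, b[["beta1"]]), length(ages))
  }
  structure(data.frame(age = ages, activity = m),
            class = c("activity_schedule", "data.frame"),
            a_b = fit$a_b, a_max = fit$a_max)
}

#' Relative rate of reproductive senescence
#'
#' Compares the decline of ovarian activity with age to the somatic
#' lifespan: both axes are normalised, activity to 1 at the age of first
#' ovulation \eqn{a_B} and age to the unit interval over
#' \eqn{[a_B, a_{max}]}. The statistic is the magnitude of the normalised
#' activity slope,
#' \deqn{\rho = 2 |\beta_2| (a_{max} - a_B) / m(a_B).}
#' \eqn{\rho = 1} means ovarian activity declines linearly to zero exactly
#' at the oldest observed age (reproductive senescence tracking somatic
#' senescence); \eqn{\rho > 1} means activity ceases before the end of
#' life, the physiological signature of a post-reproductive lifespan.
#'
#' @param fit A [corpora_fit()] object with a quadratic model and negative
#'   curvature.
#' @param exclude Optional vector of record `id`s (or row indices when the
#'   data have no `id` column) to drop before refitting; used for outlier
#'   sensitivity checks.
#' @return The rate \eqn{\rho} (unitless).
#' @examples
#' d <- data.frame(age = 5:15, corpora = 40 * (5:15) - (5:15)^2)
#' senescence_rate(corpora_fit(corpora ~ age, d))  # 2*1*10/30
#' @export
senescence_rate <- function(fit, exclude = NULL) {
  stopifnot(inherits(fit, "corpora_fit"))
  if (!is.null(exclude)) {
    d <- fit$data
    keep <- if ("id" %in% names(d)) !(d$id %in% exclude) else
      !(seq_len(nrow(d)) %in% exclude)
    fit <- corpora_fit(fit$formula, d[keep, , drop = FALSE])
  }
  if (fit$model != "quadratic") {
    stop("senescence rate requires a quadratic age-corpora relationship")
  }
  b <- fit$coefficients
  if (b[["beta2"]] >= 0) {
    stop("quadratic term is non-negative: no declining ovarian activity")
  }
  m_b <- b[["beta1"]] + 2 * b[["beta2"]] * fit$a_b
  if (m_b <= 0) {
    stop("ovarian activity at the age of first ovulation is not positive")
  }
  unname(2 * abs(b[["beta2"]]) * (fit$a_max - fit$a_b) / m_b)
}
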