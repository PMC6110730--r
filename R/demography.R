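#' Monotone age cohorts from cross-sectional ages
#'
#' Constructs variable-width age cohorts whose counts decrease
#' monotonically with age, the prerequisite for reading survivorship off a
#' cross-sectional (standing) age sample. Bins are built in reverse from
#' the oldest individual: the oldest bin holds only the female(s) at the
#' maximum observed age, and each successive younger bin is extended one
#' whole-year age at a time until it holds strictly more females than the
#' previously formed (older) bin. If the final (youngest) bin cannot exceed
#' its neighbour, its count is smoothed up to equal the second-youngest
#' bin's count. Ages are floored to whole years.
#'
#' @param ages Numeric vector of ages (years); at least two records and two
#'   distinct whole-year ages are required.
#' @return An object of class `"cohort_table"`: a data frame with one row
#'   per bin (youngest first) and columns `lower`, `upper` (whole-year age
#'   limits partitioning the observed range), `count` (after smoothing) and
#'   `raw_count`.
#' @examples
#' build_cohorts(c(3, 7, 9))      # counts 2, 1
#' build_cohorts(1:10)            # counts 4, 3, 2, 1
#' @export
build_cohorts <- function(ages) {
  stopifnot(is.numeric(ages), all(is.finite(ages)), all(ages >= 0))
  if (length(ages) < 2L) stop("need at least 2 records to build cohorts")
  ages <- floor(ages)
  tab <- table(ages)
  uq <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  k <- length(uq)
  if (k < 2L) stop("need at least 2 distinct whole-year ages")
  # scan from oldest: first bin = all females at the maximum age
  lower <- uq[k]
  count <- cnt[k]
  prev <- cnt[k]
  cur <- 0
  cur_lower <- NA_real_
  for (i in (k - 1L):1L) {
    cur <- cur + cnt[i]
    cur_lower <- uq[i]
    if (cur > prev) {
      lower <- c(lower, cur_lower)
      count <- c(count, cur)
      prev <- cur
      cur <- 0
      cur_lower <- NA_real_
    }
  }
  raw <- count
  smoothed <- FALSE
  if (cur > 0) {
    # leftover youngest bin could not exceed its neighbour: smooth up
    lower <- c(lower, cur_lower)
    raw <- c(raw, cur)
    count <- c(count, max(cur, prev))
    smoothed <- cur < prev
  }
  ord <- order(lower)
  lower <- lower[ord]
  count <- count[ord]
  raw <- raw[ord]
  upper <- c(lower[-1L] - 1, max(uq))
  structure(
    data.frame(lower = lower, upper = upper, count = count, raw_count = raw),
    class = c("cohort_table", "data.frame"),
    smoothed = smoothed
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Age cohorts (youngest to oldest", if (isTRUE(attr(x, "smoothed")))
    ", youngest bin smoothed" else "", "):\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%g, %g]  count %g%s\n", x$lower[i], x$upper[i], x$count[i],
                if (x$count[i] != x$raw_count[i])
                  sprintf(" (raw %g)", x$raw_count[i]) else ""))
  }
  invisible(x)
}

# Per-age relative standing counts implied by a cohort table: the cohort
# count is anchored at the cohort's youngest age and survival declines
# evenly (linearly) across the ages represented in each cohort, down to the
# next older cohort's count. Guarantees a non-increasing schedule whenever
# the bin counts are monotone, which build_cohorts enforces.
cohort_age_counts <- function(cohorts) {
  stopifnot(inherits(cohorts, "cohort_table") || is.data.frame(cohorts))
  anchors_x <- cohorts$lower
  anchors_c <- cohorts$count
  grid <- seq(min(cohorts$lower), max(cohorts$upper))
  if (length(anchors_x) == 1L) {
    return(data.frame(age = grid, count = rep(anchors_c, length(grid))))
  }
  chat <- stats::approx(anchors_x, anchors_c, xout = grid, rule = 2)$y
  data.frame(age = grid, count = chat)
}

#' Survivorship from age cohorts under a growth scenario
#'
#' Converts a monotone cohort table into a yearly survivorship schedule
#' \eqn{l(x)}. The per-age standing counts \eqn{\hat c_x} (cohort counts
#' anchored at each cohort's youngest age, with survival spread evenly
#' through the ages represented in the cohort) are corrected for
#' exponential population growth by the stable-population identity
#' \eqn{l(x) \propto \hat c_x e^{r x}} and normalised so that survivorship
#' at the youngest represented age is 1. A growth rate that would make
#' survivorship increase anywhere is infeasible and raises an error.
#'
#' @param cohorts A [build_cohorts()] table (or a data frame with `lower`,
#'   `upper`, `count` columns; width-1 rows give per-age counts directly).
#' @param r Per-year exponential population growth rate.
#' @return An object of class `"life_table"`: a data frame with columns
#'   `age` and `lx`, and attributes `r`, `B` (youngest age) and `omega`
#'   (oldest age).
#' @examples
#' ct <- data.frame(lower = 0:3, upper = 0:3, count = 4:1)
#' survival_from_cohorts(ct, r = 0)$lx  # 1, 0.75, 0.5, 0.25
#' @export
survival_from_cohorts <- function(cohorts, r = 0) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r))
  chat <- cohort_age_counts(cohorts)
  lx <- chat$count * exp(r * chat$age)
  lx <- lx / lx[1L]
  if (any(diff(lx) > 1e-10)) {
    stop("growth rate r = ", format(r),
         " is infeasible: survivorship would increase with age")
  }
  lx <- cummin(lx)  # remove floating-point jitter only
  structure(
    data.frame(age = chat$age, lx = lx),
    class = c("life_table", "data.frame"),
    r = r, B = chat$age[1L], omega = chat$age[length(chat$age)]
  )
}

#' @export
print.life_table <- function(x, digits = 4, ...) {
  cat("Life table: ages ", attr(x, "B"), "-", attr(x, "omega"),
      ", growth rate r = ", format(attr(x, "r")), "\n", sep = "")
  print(data.frame(age = x$age, lx = round(x$lx, digits)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.life_table <- function(x, ...) {
  plot(x$age, x$lx, type = "l", lwd = 2, ylim = c(0, 1),
       xlab = "age (yr)", ylab = "survivorship l(x)",
       main = paste0("survivorship (r = ", format(attr(x, "r")), ")"), ...)
  invisible(x)
}

#' Largest feasible population growth rate
#'
#' The largest exponential growth rate \eqn{r \le} `cap` for which the
#' growth-corrected survivorship \eqn{\hat c_x e^{r x}} remains
#' non-increasing given the age structure of the data: the minimum over
#' adjacent ages of \eqn{\ln(\hat c_x / \hat c_{x+1})}, capped at `cap` and
#' floored at 0. Used as the "growing population" scenario.
#'
#' @inheritParams survival_from_cohorts
#' @param cap Upper bound on the growth rate (default 0.1/yr).
#' @return The feasible growth rate (per year).
#' @export
max_feasible_growth <- function(cohorts, cap = 0.1) {
  stopifnot(is.numeric(cap), length(cap) == 1L, cap >= 0)
  chat <- cohort_age_counts(cohorts)
  k <- nrow(chat)
  if (k < 2L) return(cap)
  ratios <- log(chat$count[-k] / chat$count[-1L])
  min(cap, max(0, min(ratios)))
}
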