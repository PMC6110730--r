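# Generator configurations for the three archetype populations used across
# the suite: reproductive senescence at half the adult span, constant
# ovulation until death, and corpora unrelated to age.

cfg_senescent <- function(n = 1000, seed = NULL, survival = 35,
                          pregnancy_rate = NULL) {
  sim_config(n, data.frame(age = c(5, 20), rate = c(1, 0)),
             survival = survival, maturity_age = 5,
             pregnancy_rate = pregnancy_rate,
             species_label = "senescent", seed = seed)
}

cfg_constant <- function(n = 500, seed = NULL) {
  sim_config(n, data.frame(age = c(0, 30), rate = c(1, 1)), survival = 30,
             species_label = "constant", seed = seed)
}

noise_dataset <- function(n = 200, seed = 7) {
  physprr:::with_seed(seed, data.frame(
    species = "noise", id = seq_len(n),
    age = sample(1:50, n, replace = TRUE),
    corpora = rpois(n, 5)))
}

# Random strictly decreasing life table on <= max_ages yearly ages.
random_life_table <- function(max_ages = 8) {
  k <- sample(2:max_ages, 1)
  B <- sample(0:5, 1)
  lx <- cumprod(c(1, runif(k - 1, 0.3, 0.95)))
  structure(data.frame(age = B + 0:(k - 1), lx = lx),
            class = c("life_table", "data.frame"),
            r = 0, B = B, omega = B + k - 1)
}

# Brute-force person-years oracle: T(x) summed over the death distribution
# implied by the life table (uniform deaths within each year; survivors to
# the final age die at that age). Independent of compute_prr's trapezoids.
oracle_person_years <- function(lt, x) {
  ages <- lt$age
  lx <- lt$lx
  k <- length(ages)
  total <- 0
  for (i in seq_len(k - 1)) {
    d <- lx[i] - lx[i + 1]
    y0 <- ages[i]
    y1 <- ages[i + 1]
    if (y1 <= x) next
    total <- total + d * (if (y0 >= x) (y0 + y1) / 2 - x else (y1 - x)^2 / (2 * (y1 - y0)))
  }
  if (ages[k] > x) total <- total + lx[k] * (ages[k] - x)
  total
}

oracle_prr <- function(lt, M) {
  if (M >= max(lt$age)) return(0)
  oracle_person_years(lt, M) / oracle_person_years(lt, min(lt$age))
}
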