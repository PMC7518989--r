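# Small builders shared across the test files.

# temperature series from a bare tmax vector
make_series <- function(tmax, start = as.Date("2013-07-01")) {
  temperature_series(start + seq_along(tmax) - 1L, tmax)
}

# minimal city profile, convenient round numbers
make_profile <- function(beds = 1000, staff = 2000, hospitals = 10,
                         ac_rate = 0.8, income = 2000, allowance = 500,
                         insurance = 0.9, pop_under14 = 1e6,
                         pop_15_64 = 7e6, pop_over65 = 2e6) {
  city_profile(pop_under14 = pop_under14, pop_15_64 = pop_15_64,
               pop_over65 = pop_over65, hospitals = hospitals, beds = beds,
               staff = staff, ac_rate = ac_rate, income = income,
               allowance = allowance, insurance = insurance)
}

# full parameter set; neutral tables unless given
make_params <- function(profile = make_profile(), beta_morb = 100,
                        r_base = 10, mu = 0.02, af0 = 0.4,
                        weights = list(beds = 0.8, allowance = 0.8),
                        ma = table_function(c(35, 45), c(1, 1)),
                        hdaf = table_function(c(0, 30), c(1, 1)),
                        background_rate = 114, initial_ap = 1000) {
  model_params(
    exposure = exposure_params(beta_morb = beta_morb, r_base = r_base,
                               mu = mu),
    adaptation = adaptation_params(af0 = af0, weights = weights,
                                   reference = profile),
    ma = ma, hdaf = hdaf,
    background_rate = background_rate, initial_ap = initial_ap)
}

# random admissible parameter draw for property tests (given RNG state)
random_params <- function(profile) {
  ma <- table_function(c(35, 37.6, 39, 41, 43),
                       c(1, 1, cumprod(1 + runif(3, 0.05, 0.6))))
  hdaf <- table_function(c(0, 5, 10, 20),
                         c(1, cumprod(1 + runif(3, 0.02, 0.3))))
  make_params(profile = profile,
              beta_morb = runif(1, 10, 800),
              r_base = runif(1, 0, 100),
              mu = runif(1, 0.001, 0.1),
              af0 = runif(1, 0.1, 0.8),
              weights = list(beds = runif(1, 0.2, 1),
                             allowance = runif(1, 0.2, 1),
                             staff = 0.3, income = 0.3),
              ma = ma, hdaf = hdaf,
              initial_ap = runif(1, 0, 5e5))
}
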