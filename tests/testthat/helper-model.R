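# shared fixtures, built in code

# flat-hazard life table over an age range (no closure, for closed forms)
flat_life_table <- function(q, ages = 50:100) {
  life_table(ages, rep(q, length(ages)))
}

# one-band incidence schedule covering the whole model age range
one_band_config <- function(rate_per_1e5, base = crc_basecase()) {
  base$incidence <- data.frame(age_start = 50, age_end = 120,
                               rate = rate_per_1e5)
  base
}

# the base-case model is reused across test files; compute it once
.crcscreen_test_cache <- new.env(parent = emptyenv())

cached_base_model <- function() {
  if (is.null(.crcscreen_test_cache$fit)) {
    .crcscreen_test_cache$fit <- crc_model()
  }
  .crcscreen_test_cache$fit
}

cached_life_table <- function() {
  if (is.null(.crcscreen_test_cache$lt)) {
    .crcscreen_test_cache$lt <- default_life_table()
  }
  .crcscreen_test_cache$lt
}

# independent brute-force residual-life-expectancy oracle: explicit loop over
# survival products, no reuse of the package's cumprod path
rle_oracle <- function(table, age) {
  i <- which(table$age == age)
  total <- 0
  surv <- 1
  for (j in i:nrow(table)) {
    surv <- surv * (1 - table$qx[j])
    total <- total + surv
  }
  total
}
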