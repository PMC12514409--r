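#' Seeded per-individual microsimulation
#'
#' Simulates `n` individuals through exactly the same annual event sequence
#' and rates as the deterministic cohort recursion in [run_cohort()], as an
#' independent stochastic cross-check: the cohort engine computes the
#' expectation of this process, so summary outputs must agree within
#' Monte-Carlo error.  Results are scaled to the configured cohort size and
#' carry standard errors for the key outputs.
#'
#' @param config A validated `crc_config`.
#' @param strategy Strategy id or `crc_schedule`.
#' @param life_table A `life_table`; defaults to the synthetic standard table.
#' @param n Number of simulated individuals.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List of summary outputs (`cases`, `crc_deaths`, `lyl`, `lyl_disc`,
#'   `fits`, `colo_total`, `colo_ther`, `bleeding`, `perforation`,
#'   `perf_deaths`), each scaled to cohort size, plus a `se` list of
#'   Monte-Carlo standard errors on the same scale, and `n`.
#' @export
microsim_oracle <- function(config, strategy = "none", life_table = NULL,
                            n = 10000, seed = 1) {
  stopifnot(n >= 1)
  viol <- validate_config(config)
  if (nrow(viol)) stop("invalid configuration", call. = FALSE)
  sched <- if (inherits(strategy, "crc_schedule")) strategy
           else strategy_schedule(strategy, config)
  arm <- sched$strategy_id
  lt <- if (is.null(life_table)) default_life_table() else life_table
  eco <- config$economics
  if (max(lt$age) < eco$horizon_age) stop("life table shorter than horizon")
  set.seed(seed)

  start <- eco$start_age; stop_age <- eco$screening_stop_age
  horizon <- eco$horizon_age; r <- eco$discount_rate
  K <- sched$post_normal_hiatus; S <- sched$surveillance_interval
  cure_years <- config$options$cure_years
  pm_basis <- config$options$perforation_mortality_basis
  fit_arm <- arm %in% c("fit_colo", "fit_ai")
  direct_arm <- arm %in% c("colo", "ai_colo")
  red <- effective_incidence_reduction(sched, config$efficacy, config$compliance)
  persists <- direct_arm && isTRUE(config$options$colonoscopy_protection_persists)
  lyl_offset0 <- identical(config$options$discount_lyl_from, "death_year")
  pr <- config$complications$polypectomy_rate
  br <- config$complications$bleeding_rate
  fr <- config$complications$perforation_rate
  pm <- config$complications$perforation_mortality
  sdist <- cumsum(config$stages$distribution)
  mort <- config$stages$annual_mortality

  # per-individual state
  alive <- rep(TRUE, n)
  dx_stage <- integer(n)        # 0 = susceptible
  dx_years <- integer(n)
  cured <- rep(FALSE, n)
  # screening sub-state: 0 due/pool; k in 1..K hiatus/wait; 100+k surveillance
  # counter; 99 surveillance due
  scr <- integer(n)
  # per-individual tallies
  got_crc <- rep(FALSE, n)
  lyl_i <- numeric(n); lyl_disc_i <- numeric(n)
  fits_i <- integer(n); colo_i <- integer(n); ther_i <- integer(n)
  bleed_i <- integer(n); perf_i <- integer(n); pdeath_i <- rep(FALSE, n)

  for (t in 0:(horizon - start)) {
    age <- start + t
    if (!any(alive)) break
    qx <- lt_qx(lt, age)
    # (1) other-cause death
    idx <- which(alive)
    die <- idx[stats::runif(length(idx)) < qx]
    alive[die] <- FALSE
    # (2) screening
    did_colo <- integer(0)
    did_ther <- logical(0)
    screening_on <- arm != "none" && age < stop_age
    if (screening_on) {
      sus <- which(alive & dx_stage == 0L & !cured)
      if (fit_arm && (t %% sched$fit_interval) == 0) {
        due <- sus[scr[sus] == 0L]
        takers <- due[stats::runif(length(due)) < config$compliance$fit]
        fits_i[takers] <- fits_i[takers] + 1L
        prev <- annual_incidence(age, config$incidence)
        ppos <- fit_positivity(config$tests$fit_sensitivity,
                               config$tests$fit_specificity, prev)
        pos <- takers[stats::runif(length(takers)) < ppos]
        goers <- pos[stats::runif(length(pos)) <
                       config$compliance$colonoscopy_after_positive]
        did_colo <- goers
        if (identical(config$options$fit_reoffer, "per_hiatus")) {
          resting <- setdiff(takers, goers)
          scr[resting] <- K
        }
      } else if (direct_arm) {
        due <- sus[scr[sus] == 0L]
        did_colo <- due[stats::runif(length(due)) <
                          config$compliance$colonoscopy_primary]
      }
      # surveillance visits due
      sdue <- sus[scr[sus] == 99L]
      comp_s <- if (fit_arm) config$compliance$colonoscopy_after_positive
                else config$compliance$colonoscopy_primary
      satt <- sdue[stats::runif(length(sdue)) < comp_s]
      did_colo <- c(did_colo, satt)
      if (length(did_colo)) {
        colo_i[did_colo] <- colo_i[did_colo] + 1L
        did_ther <- stats::runif(length(did_colo)) < pr
        ther_i[did_colo[did_ther]] <- ther_i[did_colo[did_ther]] + 1L
        # destination sub-state
        scr[did_colo[did_ther]] <- 100L + S
        scr[did_colo[!did_ther]] <- K
        # complications
        bl <- did_colo[stats::runif(length(did_colo)) < br]
        bleed_i[bl] <- bleed_i[bl] + 1L
        pf <- did_colo[stats::runif(length(did_colo)) < fr]
        perf_i[pf] <- perf_i[pf] + 1L
        dead_p <- switch(pm_basis,
          per_perforation = pf[stats::runif(length(pf)) < pm],
          per_colonoscopy = did_colo[stats::runif(length(did_colo)) < pm],
          per_polypectomy = {
            th <- did_colo[did_ther]
            th[stats::runif(length(th)) < pm]
          })
        if (length(dead_p)) {
          alive[dead_p] <- FALSE
          pdeath_i[dead_p] <- TRUE
          ex <- residual_life_expectancy(lt, age)
          dly <- discounted_life_years(lt, age, r,
                                       offset = if (lyl_offset0) 0 else t)
          lyl_i[dead_p] <- lyl_i[dead_p] + ex      # non-cancer ledger kept
          lyl_disc_i[dead_p] <- lyl_disc_i[dead_p] + dly
        }
      }
    } else if (arm != "none" && age >= stop_age) {
      scr[alive & scr == 99L] <- 0L
    }
    # (3) incidence
    sus <- which(alive & dx_stage == 0L & !cured)
    h <- annual_incidence(age, config$incidence)
    r_t <- if (arm == "none") 0 else if (age < stop_age || persists) red else 0
    h_eff <- h * (1 - r_t)
    newdx <- sus[stats::runif(length(sus)) < h_eff]
    if (length(newdx)) {
      got_crc[newdx] <- TRUE
      u <- stats::runif(length(newdx))
      dx_stage[newdx] <- 1L + findInterval(u, sdist)
      dx_stage[newdx][dx_stage[newdx] > 4L] <- 4L
      dx_years[newdx] <- 0L
    }
    # (4) CRC death among cases diagnosed in earlier cycles
    prev_cases <- which(alive & dx_stage > 0L & !cured & dx_years >= 1L)
    if (length(prev_cases)) {
      pdie <- mort[dx_stage[prev_cases]]
      dies <- prev_cases[stats::runif(length(prev_cases)) < pdie]
      if (length(dies)) {
        alive[dies] <- FALSE
        ex <- residual_life_expectancy(lt, age)
        dly <- discounted_life_years(lt, age, r,
                                     offset = if (lyl_offset0) 0 else t)
        lyl_i[dies] <- lyl_i[dies] + ex
        lyl_disc_i[dies] <- lyl_disc_i[dies] + dly
      }
      survivors <- setdiff(prev_cases, dies)
      to_cure <- survivors[dx_years[survivors] >= cure_years]
      cured[to_cure] <- TRUE
      dx_stage[to_cure] <- 0L
    }
    live_cases <- alive & dx_stage > 0L & !cured
    dx_years[live_cases] <- dx_years[live_cases] + 1L
    # advance screening counters
    hw <- alive & dx_stage == 0L & !cured & scr >= 1L & scr <= K
    scr[hw] <- scr[hw] - 1L
    sv <- alive & dx_stage == 0L & !cured & scr > 100L
    scr[sv] <- scr[sv] - 1L
    scr[alive & scr == 100L] <- 99L
  }
  scale <- eco$cohort_size / n
  crc_death <- lyl_i > 0 & got_crc & !pdeath_i
  stat <- function(x) sum(x) * scale
  se_of <- function(x) stats::sd(x) / sqrt(n) * eco$cohort_size
  # life-years ledgers split by cause of death
  lyl_crc <- ifelse(pdeath_i, 0, lyl_i)
  lyl_disc_crc <- ifelse(pdeath_i, 0, lyl_disc_i)
  list(
    cases = stat(got_crc),
    crc_deaths = stat(crc_death),
    lyl = sum(lyl_crc) * scale,
    lyl_disc = sum(lyl_disc_crc) * scale,
    fits = stat(fits_i),
    colo_total = stat(colo_i),
    colo_ther = stat(ther_i),
    bleeding = stat(bleed_i),
    perforation = stat(perf_i),
    perf_deaths = stat(pdeath_i),
    se = list(
      cases = se_of(as.numeric(got_crc)),
      lyl = se_of(lyl_crc),
      lyl_disc = se_of(lyl_disc_crc),
      fits = se_of(as.numeric(fits_i)),
      colo_total = se_of(as.numeric(colo_i))
    ),
    n = n
  )
}
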