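#' Run the deterministic cohort model for one strategy
#'
#' Advances the expected-value (mass) cohort recursion in annual cycles from
#' the entry age to the life-table horizon.  Within each cycle events occur
#' in a fixed order: (1) other-cause death from the life table, (2) scheduled
#' screening events and their complications (while below the screening stop
#' age), (3) CRC incidence among the susceptible, reduced according to the
#' strategy, with stage assignment at diagnosis, (4) stage-specific CRC death
#' among prevalent cases, with exit to the cured state after surviving
#' `cure_years` annual cycles, and (5) accrual of life-years-lost and
#' counters.  Diagnosed patients are no longer screened; cured patients are
#' not re-screened or surveilled.
#'
#' Screening sub-states of the susceptible pool implement the pathway rules:
#' FIT arms re-offer an annual FIT, refer positives to colonoscopy, place
#' polyp-free colonoscopies on a ten-year hiatus before FIT resumes, and
#' place polypectomies on three-yearly surveillance until no more polyps are
#' found; direct arms colonoscope the due pool, repeat after ten years when
#' clean, and use the same surveillance loop.
#'
#' @param config A validated `crc_config`.
#' @param strategy Strategy id (see [crc_strategies()]) or a `crc_schedule`.
#' @param life_table A `life_table` covering `start_age` to `horizon_age`;
#'   defaults to the synthetic standard table.
#' @return A `crc_trace`: one row per cycle with occupancy, new diagnoses by
#'   stage, deaths by cause, procedure and complication counts, and
#'   (un)discounted life-years-lost accruals.  The configuration and strategy
#'   are attached as attributes.
#' @examples
#' tr <- run_cohort(crc_basecase(), "none")
#' sum(tr$newdx_total)  # lifetime CRC cases in the unscreened cohort
#' @export
run_cohort <- function(config, strategy = "none", life_table = NULL) {
  viol <- validate_config(config)
  if (nrow(viol)) {
    stop("invalid configuration: ",
         paste(sprintf("%s (%s)", viol$field, viol$rule), collapse = "; "),
         call. = FALSE)
  }
  sched <- if (inherits(strategy, "crc_schedule")) strategy
           else strategy_schedule(strategy, config)
  arm <- sched$strategy_id
  lt <- if (is.null(life_table)) default_life_table() else life_table
  eco <- config$economics
  if (max(lt$age) < eco$horizon_age) {
    stop("life table ends at age ", max(lt$age),
         ", shorter than the model horizon ", eco$horizon_age, call. = FALSE)
  }
  start <- eco$start_age
  stop_age <- eco$screening_stop_age
  horizon <- eco$horizon_age
  r <- eco$discount_rate
  K <- sched$post_normal_hiatus
  S <- sched$surveillance_interval
  cure_years <- config$options$cure_years
  pm_basis <- config$options$perforation_mortality_basis
  fit_arm <- arm %in% c("fit_colo", "fit_ai")
  direct_arm <- arm %in% c("colo", "ai_colo")

  red <- effective_incidence_reduction(sched, config$efficacy, config$compliance)
  persists <- direct_arm && isTRUE(config$options$colonoscopy_protection_persists)
  lyl_offset0 <- identical(config$options$discount_lyl_from, "death_year")

  pool <- eco$cohort_size           # due/eligible susceptibles
  hiatus <- numeric(K)              # FIT arms: years until FIT resumes
  wait <- numeric(K)                # direct arms: years until next colonoscopy
  surv <- numeric(S)                # years until surveillance visit
  surv_due <- 0                     # surveillance visit due now
  D <- matrix(0, nrow = 4, ncol = cure_years)  # diagnosed, stage x years since dx
  cured <- 0
  n_cyc <- horizon - start + 1
  cols <- c("cycle", "age", "fits", "colo_diag", "colo_ther", "colo_total",
            "bleeding", "perforation", "perf_death",
            "newdx_s1", "newdx_s2", "newdx_s3", "newdx_s4", "newdx_total",
            "deaths_other", "deaths_crc", "deaths_perf",
            "lyl", "lyl_disc", "lyl_perf", "lyl_perf_disc",
            "susceptible", "diagnosed", "cured", "alive")
  out <- matrix(0, nrow = n_cyc, ncol = length(cols),
                dimnames = list(NULL, cols))

  for (t in 0:(n_cyc - 1L)) {
    age <- start + t
    qx <- lt_qx(lt, age)
    # (1) other-cause death
    alive <- pool + sum(hiatus) + sum(wait) + sum(surv) + surv_due + sum(D) + cured
    d_other <- alive * qx
    p_surv <- 1 - qx
    pool <- pool * p_surv; hiatus <- hiatus * p_surv; wait <- wait * p_surv
    surv <- surv * p_surv; surv_due <- surv_due * p_surv
    D <- D * p_surv; cured <- cured * p_surv

    # (2) screening
    fits <- colo_diag <- colo_ther <- 0
    screening_on <- arm != "none" && age < stop_age
    if (screening_on) {
      pr <- config$complications$polypectomy_rate
      if (fit_arm && (t %% sched$fit_interval) == 0) {
        fits <- pool * config$compliance$fit
        prev <- annual_incidence(age, config$incidence)  # undetected-disease proxy
        ppos <- fit_positivity(config$tests$fit_sensitivity,
                               config$tests$fit_specificity, prev)
        colo_index <- fits * ppos * config$compliance$colonoscopy_after_positive
        if (identical(config$options$fit_reoffer, "per_hiatus")) {
          # every tested person leaves the pool; negatives (and positives who
          # skip colonoscopy) rest for the hiatus before the next FIT
          pool <- pool - fits
          hiatus[K] <- hiatus[K] + (fits - colo_index)
        } else {
          pool <- pool - colo_index
        }
        ther_i <- colo_index * pr
        diag_i <- colo_index - ther_i
        surv[S] <- surv[S] + ther_i
        hiatus[K] <- hiatus[K] + diag_i
      } else if (direct_arm) {
        colo_index <- pool * config$compliance$colonoscopy_primary
        pool <- pool - colo_index
        ther_i <- colo_index * pr
        diag_i <- colo_index - ther_i
        surv[S] <- surv[S] + ther_i
        wait[K] <- wait[K] + diag_i
      } else {
        ther_i <- diag_i <- 0
      }
      comp_s <- if (fit_arm) config$compliance$colonoscopy_after_positive
                else config$compliance$colonoscopy_primary
      colo_s <- surv_due * comp_s
      surv_due <- surv_due - colo_s
      ther_s <- colo_s * pr
      diag_s <- colo_s - ther_s
      surv[S] <- surv[S] + ther_s
      if (fit_arm) hiatus[K] <- hiatus[K] + diag_s else wait[K] <- wait[K] + diag_s
      colo_ther <- ther_i + ther_s
      colo_diag <- diag_i + diag_s
    } else if (arm != "none" && age >= stop_age && surv_due > 0) {
      # surveillance programme has ended; mass rejoins the general pool
      pool <- pool + surv_due
      surv_due <- 0
    }
    colo_total <- colo_diag + colo_ther
    cc <- expected_complications(colo_total, config$complications,
                                 colonoscopy_therapeutic = colo_ther,
                                 basis = pm_basis)
    pd <- cc$perforation_death
    if (pd > 0 && colo_total > 0) {
      # procedure deaths come out of this cycle's post-colonoscopy masses
      dest <- surv[S] + hiatus[K] + wait[K]
      frac <- pd / dest
      surv[S] <- surv[S] * (1 - frac)
      hiatus[K] <- hiatus[K] * (1 - frac)
      wait[K] <- wait[K] * (1 - frac)
    }

    # (3) CRC incidence among susceptibles
    h <- annual_incidence(age, config$incidence)
    r_t <- if (arm == "none") 0
           else if (age < stop_age || persists) red
           else 0
    h_eff <- h * (1 - r_t)
    sus_total <- pool + sum(hiatus) + sum(wait) + sum(surv) + surv_due
    newdx_total <- sus_total * h_eff
    keep <- 1 - h_eff
    pool <- pool * keep; hiatus <- hiatus * keep; wait <- wait * keep
    surv <- surv * keep; surv_due <- surv_due * keep
    newdx <- newdx_total * config$stages$distribution

    # (4) CRC death among prevalent cases; cure after cure_years survived
    mort <- config$stages$annual_mortality
    d_crc_s <- D * mort
    d_crc <- sum(d_crc_s)
    Dsurv <- D - d_crc_s
    cured <- cured + sum(Dsurv[, cure_years])
    D <- cbind(newdx, Dsurv[, -cure_years, drop = FALSE])

    # (5) accruals
    ex <- residual_life_expectancy(lt, age)
    dly <- discounted_life_years(lt, age, r, offset = if (lyl_offset0) 0 else t)
    sus_end <- pool + sum(hiatus) + sum(wait) + sum(surv) + surv_due
    alive_end <- sus_end + sum(D) + cured
    out[t + 1L, ] <- c(t, age, fits, colo_diag, colo_ther, colo_total,
                       cc$bleeding, cc$perforation, pd,
                       newdx, newdx_total,
                       d_other, d_crc, pd,
                       d_crc * ex, d_crc * dly, pd * ex, pd * dly,
                       sus_end, sum(D), cured, alive_end)

    # advance screening counters
    pool <- pool + hiatus[1] + wait[1]
    hiatus <- c(hiatus[-1], 0)
    wait <- c(wait[-1], 0)
    surv_due <- surv_due + surv[1]
    surv <- c(surv[-1], 0)
  }
  trace <- as.data.frame(out)
  attr(trace, "config") <- config
  attr(trace, "strategy") <- sched
  attr(trace, "life_table") <- lt
  class(trace) <- c("crc_trace", "data.frame")
  trace
}

#' @export
print.crc_trace <- function(x, ...) {
  sched <- attr(x, "strategy")
  cat(sprintf("Cohort trace: strategy %s, %d annual cycles (ages %d-%d)\n",
              sched$strategy_id, nrow(x), min(x$age), max(x$age)))
  cat(sprintf("  CRC cases %.1f, cancer deaths %.1f, cancer life years lost %.1f (%.1f discounted)\n",
              sum(x$newdx_total), sum(x$deaths_crc), sum(x$lyl), sum(x$lyl_disc)))
  cat(sprintf("  FITs %.0f, colonoscopies %.0f (%.0f therapeutic), perforations %.2f\n",
              sum(x$fits), sum(x$colo_total), sum(x$colo_ther), sum(x$perforation)))
  invisible(x)
}

#' Export a cohort trace as a tidy long table
#'
#' @param trace A `crc_trace`.
#' @param path Optional CSV path; when given, the long table is written there.
#' @return Data frame with columns `cycle`, `age`, `measure`, `value`.
#' @export
trace_long <- function(trace, path = NULL) {
  measures <- setdiff(names(trace), c("cycle", "age"))
  long <- do.call(rbind, lapply(measures, function(m) {
    data.frame(cycle = trace$cycle, age = trace$age, measure = m,
               value = trace[[m]], stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) utils::write.csv(long, path, row.names = FALSE)
  long
}

#' Life-years-lost accrual for a block of cancer deaths
#'
#' Undiscounted loss is `deaths` times the residual life expectancy at the
#' age of death; the discounted loss anchors the discounting at model start
#' via the death-cycle offset.
#'
#' @param deaths_crc Cancer deaths (expected count).
#' @param age_at_death Age at death.
#' @param table A `life_table`.
#' @param r Annual discount rate.
#' @param offset Years from model start to the death cycle.
#' @return Named vector `c(undiscounted, discounted)`.
#' @export
life_years_lost_accrual <- function(deaths_crc, age_at_death, table, r = 0,
                                    offset = 0) {
  stopifnot(deaths_crc >= 0)
  ex <- residual_life_expectancy(table, age_at_death)
  dly <- discounted_life_years(table, age_at_death, r, offset)
  c(undiscounted = deaths_crc * ex, discounted = deaths_crc * dly)
}
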