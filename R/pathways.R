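#' Age-specific annual CRC incidence
#'
#' Looks up the piecewise-constant annual incidence hazard for an age from a
#' quinquennial band schedule.  Bands are half-open: `[age_start, age_end)`,
#' so a band boundary belongs to the later band.  Rates are stored per
#' 100,000 per year and returned per person-year.
#'
#' @param age Age in years (vectorized).
#' @param schedule Incidence band data frame with columns `age_start`,
#'   `age_end`, `rate` (per 100,000), as in `crc_basecase()$incidence`.
#' @return Annual incidence hazard(s) per person-year.
#' @examples
#' annual_incidence(52, crc_basecase()$incidence) * 1e5  # 55.9
#' annual_incidence(74, crc_basecase()$incidence) * 1e5  # 253.2 (70-74 band)
#' @export
annual_incidence <- function(age, schedule) {
  out <- vapply(age, function(a) {
    i <- which(schedule$age_start <= a & a < schedule$age_end)
    if (length(i) != 1) stop("age ", a, " not covered by the incidence schedule",
                             call. = FALSE)
    schedule$rate[i] / 1e5
  }, numeric(1))
  out
}

#' FIT positivity rate
#'
#' Probability of a positive faecal immunochemical test: the sum of true
#' positives among the diseased and false positives among the disease-free,
#' `sens * prevalence + (1 - spec) * (1 - prevalence)`.
#'
#' @param sens Test sensitivity.
#' @param spec Test specificity.
#' @param prevalence Point prevalence of undetected disease among those tested.
#' @return Positivity probability.
#' @examples
#' fit_positivity(0.73, 0.919, 0)      # 0.081 = 1 - specificity
#' fit_positivity(0.73, 0.919, 0.004)  # 0.0836
#' @export
fit_positivity <- function(sens, spec, prevalence) {
  stopifnot(all(c(sens, spec, prevalence) >= 0), all(c(sens, spec, prevalence) <= 1))
  sens * prevalence + (1 - spec) * (1 - prevalence)
}

#' Effective incidence reduction of a strategy
#'
#' The fraction by which a strategy reduces CRC incidence among the
#' (partially compliant) target population.  FIT-based arms use the bundled
#' FIT-pathway efficacy times FIT compliance times follow-up-colonoscopy
#' compliance (protection is only realized by those who test *and* attend
#' the follow-up; the latter factor is 1 in the base case); for the AI
#' follow-up arm the bundle is scaled by the ratio of AI to conventional
#' colonoscopy efficacy, since the pathway's preventive effect runs through
#' the follow-up colonoscopy.  Direct colonoscopy arms use the colonoscopy
#' efficacy times primary-colonoscopy compliance.  No screening reduces
#' nothing by contract.
#'
#' @param strategy A strategy id or `crc_schedule`.
#' @param efficacy `efficacy` block of a configuration.
#' @param compliance `compliance` block of a configuration.
#' @return Reduction fraction in \[0, 1\].
#' @examples
#' cfg <- crc_basecase()
#' effective_incidence_reduction("ai_colo", cfg$efficacy, cfg$compliance)
#' # 0.489 * 0.989 = 0.4836
#' @export
effective_incidence_reduction <- function(strategy, efficacy, compliance) {
  id <- if (inherits(strategy, "crc_schedule")) strategy$strategy_id else strategy
  id <- match.arg(id, crc_strategies())
  switch(id,
    none = 0,
    fit_colo = efficacy$fit * compliance$fit *
      compliance$colonoscopy_after_positive,
    fit_ai = efficacy$fit * (efficacy$ai_colonoscopy / efficacy$colonoscopy) *
      compliance$fit * compliance$colonoscopy_after_positive,
    colo = efficacy$colonoscopy * compliance$colonoscopy_primary,
    ai_colo = efficacy$ai_colonoscopy * compliance$colonoscopy_primary
  )
}

#' Expected colonoscopy complications
#'
#' Bleeding and perforation are charged per colonoscopy performed; deaths
#' follow the configured attachment basis for the perforation mortality
#' figure (per perforation event by default, switchable to per colonoscopy
#' or per polypectomy).
#'
#' @param colonoscopy_total Total colonoscopies (expected count).
#' @param rates `complications` block of a configuration.
#' @param colonoscopy_therapeutic Therapeutic (polypectomy) subset, needed
#'   only for the `per_polypectomy` mortality basis.
#' @param basis Attachment basis for perforation mortality.
#' @return List with `bleeding`, `perforation`, `perforation_death`.
#' @export
expected_complications <- function(colonoscopy_total, rates,
                                   colonoscopy_therapeutic = colonoscopy_total,
                                   basis = c("per_perforation", "per_colonoscopy",
                                             "per_polypectomy")) {
  basis <- match.arg(basis)
  stopifnot(colonoscopy_total >= 0)
  bleeding <- rates$bleeding_rate * colonoscopy_total
  perforation <- rates$perforation_rate * colonoscopy_total
  perforation_death <- switch(basis,
    per_perforation = rates$perforation_mortality * perforation,
    per_colonoscopy = rates$perforation_mortality * colonoscopy_total,
    per_polypectomy = rates$perforation_mortality * colonoscopy_therapeutic
  )
  list(bleeding = bleeding, perforation = perforation,
       perforation_death = perforation_death)
}

#' Expected surveillance colonoscopies per entrant
#'
#' Pushes a unit mass through the adenoma-surveillance loop: a colonoscopy
#' every `interval` years while polyps are found (probability `p` per visit),
#' exit to the ten-year track otherwise.  With full attendance the expected
#' number of visits is the geometric sum `1/(1-p)`; the function evaluates
#' the state machine over a finite horizon so the identity can be checked
#' directly.
#'
#' @param p Per-visit polyp-finding (polypectomy) probability.
#' @param compliance Attendance probability per scheduled visit.
#' @param interval Years between surveillance visits.
#' @param cycles Annual cycles to run.
#' @return Expected colonoscopies per unit mass entering surveillance.
#' @examples
#' expected_surveillance_visits(0.73)  # ~ 1/(1 - 0.73) = 3.704
#' @export
expected_surveillance_visits <- function(p, compliance = 1, interval = 3,
                                         cycles = 200) {
  stopifnot(p >= 0, p < 1, compliance >= 0, compliance <= 1)
  surv <- numeric(interval)  # surv[k]: visit due in k years
  surv[interval] <- 1
  due <- 0
  visits <- 0
  for (t in seq_len(cycles)) {
    att <- due * compliance
    visits <- visits + att
    due <- due - att
    surv[interval] <- surv[interval] + att * p  # polyps found: back on the loop
    # polyp-free attendees exit the loop entirely
    due <- due + surv[1]
    surv <- c(surv[-1], 0)
  }
  visits
}
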