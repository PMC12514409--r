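#' Present-value discount factor
#'
#' @param t Years from model start (>= 0).
#' @param r Annual discount rate (fraction, >= 0).
#' @return `(1 + r)^(-t)` (vectorized over `t`).
#' @examples
#' discount_factor(1, 0.03)   # 0.970874
#' discount_factor(25, 0.03)  # 0.477606
#' @export
discount_factor <- function(t, r) {
  stopifnot(all(t >= 0), r >= 0)
  (1 + r)^(-t)
}

#' Discounted cost breakdown of a cohort trace
#'
#' Converts a [run_cohort()] trace into discounted cost totals by category.
#' Per cycle: FIT kits at the kit cost; colonoscopies at the procedure cost
#' plus (by default) one consultation fee per attendance; therapeutic
#' colonoscopies at the histopathology fee (the polypectomy category);
#' bleeding and perforation episodes at their hospitalization costs; and new
#' stage-s diagnoses charged the stage-s care lump sum in the diagnosis year.
#' AI-assisted and conventional colonoscopy share the same unit cost.  Every
#' cycle's outlay is multiplied by [discount_factor()] at the configured
#' rate; the procedure *counts* reported alongside remain undiscounted.
#'
#' @param trace A `crc_trace`.
#' @param costs `costs` block of a configuration (defaults to the trace's own).
#' @param r Annual discount rate (defaults to the trace's configuration).
#' @param consultation_per_colonoscopy Charge the consultation fee per
#'   colonoscopy attendance.
#' @param histopathology_per_therapeutic Charge histopathology per
#'   therapeutic colonoscopy.
#' @return Object of class `crc_costs`: per-category totals, grand `total`,
#'   and the per-cycle `ledger` data frame.
#' @export
accumulate_costs <- function(trace, costs = NULL, r = NULL,
                             consultation_per_colonoscopy = NULL,
                             histopathology_per_therapeutic = NULL) {
  cfg <- attr(trace, "config")
  if (is.null(costs)) {
    if (is.null(cfg)) stop("trace has no configuration; supply costs", call. = FALSE)
    costs <- cfg$costs
  }
  if (is.null(r)) {
    if (is.null(cfg)) stop("trace has no configuration; supply r", call. = FALSE)
    r <- cfg$economics$discount_rate
  }
  if (is.null(consultation_per_colonoscopy)) {
    consultation_per_colonoscopy <-
      is.null(cfg) || isTRUE(cfg$options$consultation_per_colonoscopy)
  }
  if (is.null(histopathology_per_therapeutic)) {
    histopathology_per_therapeutic <-
      is.null(cfg) || isTRUE(cfg$options$histopathology_per_therapeutic)
  }
  d <- discount_factor(trace$cycle, r)
  colo_unit <- costs$colonoscopy +
    if (consultation_per_colonoscopy) costs$consultation else 0
  poly_unit <- if (histopathology_per_therapeutic) costs$histopathology else 0
  ledger <- data.frame(
    cycle = trace$cycle,
    age = trace$age,
    fit = trace$fits * costs$fit_kit * d,
    colonoscopy = trace$colo_total * colo_unit * d,
    polypectomy = trace$colo_ther * poly_unit * d,
    bleeding = trace$bleeding * costs$bleeding_episode * d,
    perforation = trace$perforation * costs$perforation_episode * d,
    care_stage1 = trace$newdx_s1 * costs$care_stage1 * d,
    care_stage2 = trace$newdx_s2 * costs$care_stage2 * d,
    care_stage3 = trace$newdx_s3 * costs$care_stage3 * d,
    care_stage4 = trace$newdx_s4 * costs$care_stage4 * d
  )
  cats <- setdiff(names(ledger), c("cycle", "age"))
  totals <- vapply(ledger[cats], sum, numeric(1))
  structure(c(as.list(totals), list(total = sum(totals), ledger = ledger)),
            class = "crc_costs")
}

#' @export
print.crc_costs <- function(x, ...) {
  cats <- setdiff(names(x), c("total", "ledger"))
  cat("Discounted cost breakdown (US $)\n")
  for (ct in cats) cat(sprintf("  %-12s %15s\n", ct, format(round(x[[ct]]), big.mark = ",")))
  cat(sprintf("  %-12s %15s\n", "total", format(round(x$total), big.mark = ",")))
  invisible(x)
}
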