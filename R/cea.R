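#' Per-strategy outcome summary
#'
#' Collapses a trace and its cost breakdown into the per-strategy totals the
#' comparison table is built from: lifetime CRC cases (undiscounted count),
#' discounted cancer-related life years lost, discounted total cost, and
#' undiscounted procedure and complication counts.
#'
#' @param trace A `crc_trace`.
#' @param costs A `crc_costs` for the same run (computed when missing).
#' @return Object of class `crc_outcome`.
#' @export
strategy_outcome <- function(trace, costs = NULL) {
  if (is.null(costs)) costs <- accumulate_costs(trace)
  sched <- attr(trace, "strategy")
  structure(list(
    strategy_id = sched$strategy_id,
    crc_cases = sum(trace$newdx_total),
    cancer_lyl = sum(trace$lyl_disc),
    cancer_lyl_undiscounted = sum(trace$lyl),
    total_cost = costs$total,
    procedures = list(
      fit = sum(trace$fits),
      colonoscopy_total = sum(trace$colo_total),
      colonoscopy_diagnostic = sum(trace$colo_diag),
      colonoscopy_therapeutic = sum(trace$colo_ther)
    ),
    complications = list(
      bleeding = sum(trace$bleeding),
      perforation = sum(trace$perforation),
      perforation_death = sum(trace$perf_death)
    ),
    cost_breakdown = costs
  ), class = "crc_outcome")
}

#' CRC cases prevented by a strategy
#'
#' @param baseline_cases Cases without screening.
#' @param strategy_cases Cases under the strategy.
#' @return `baseline - strategy` (never clipped; may be negative).
#' @export
cases_prevented <- function(baseline_cases, strategy_cases) {
  stopifnot(baseline_cases >= 0, strategy_cases >= 0)
  baseline_cases - strategy_cases
}

# half-up rounding to `digits` decimals (R's round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Proportion of CRC cases prevented
#'
#' @param prevented Cases prevented.
#' @param baseline_cases Cases without screening (> 0).
#' @return Percentage, rounded half-up to one decimal.
#' @examples
#' proportion_prevented(120, 3233)  # 3.7
#' @export
proportion_prevented <- function(prevented, baseline_cases) {
  if (baseline_cases <= 0) stop("baseline cases must be > 0", call. = FALSE)
  round_half_up(100 * prevented / baseline_cases, 1)
}

#' Life years saved by a strategy
#'
#' The difference in cancer-related life years lost between the no-screening
#' model and the strategy's model.
#'
#' @param baseline_lyl Life years lost without screening.
#' @param strategy_lyl Life years lost under the strategy.
#' @return `baseline - strategy`.
#' @export
life_years_saved <- function(baseline_lyl, strategy_lyl) {
  stopifnot(baseline_lyl >= 0, strategy_lyl >= 0)
  baseline_lyl - strategy_lyl
}

#' Additional cost of a strategy over no screening
#'
#' @param strategy_total Discounted total cost of the strategy.
#' @param baseline_total Discounted total cost without screening.
#' @return `strategy - baseline`.
#' @export
additional_cost <- function(strategy_total, baseline_total) {
  stopifnot(strategy_total >= 0, baseline_total >= 0)
  strategy_total - baseline_total
}

#' Incremental cost-effectiveness ratio with dominance flag
#'
#' `(cost_a - cost_b) / (effect_a - effect_b)`, where effect is life years
#' saved versus no screening.  When `a` is both cheaper and more effective
#' than `b` it dominates (the ICER is reported negative, flag `"dominant"`);
#' when costlier and less effective it is `"dominated"`; equal effectiveness
#' gives flag `"undefined"` and no division.
#'
#' @param a,b Lists with components `total_cost` and `effect` (life years
#'   saved), e.g. rows of a [comparison_table()].
#' @return List with `value` (NA when undefined) and `flag` (one of `""`,
#'   `"dominant"`, `"dominated"`, `"undefined"`).
#' @export
icer <- function(a, b) {
  dc <- a$total_cost - b$total_cost
  de <- a$effect - b$effect
  if (de == 0) {
    return(list(value = NA_real_, flag = "undefined"))
  }
  flag <- if (dc < 0 && de > 0) "dominant"
          else if (dc > 0 && de < 0) "dominated"
          else ""
  list(value = dc / de, flag = flag)
}

#' Total cost per life year saved
#'
#' @param total Discounted total cost.
#' @param lys Life years saved (>= 0).
#' @return `total / lys`; `NA` with an `"undefined"` flag attribute when
#'   `lys = 0` (the no-screening column).
#' @export
cost_per_life_year_saved <- function(total, lys) {
  stopifnot(lys >= 0)
  if (lys == 0) {
    return(structure(NA_real_, flag = "undefined"))
  }
  total / lys
}

#' Build the strategy comparison table
#'
#' Derives, for each strategy against the no-screening baseline: cases
#' prevented, proportion prevented, life years saved, additional cost, total
#' cost per life year saved, and the ICER versus no screening — plus the full
#' pairwise ICER/dominance matrix.  All derived rows are computed from
#' unrounded inputs; presentation rounding happens only in the print method.
#'
#' @param outcomes List of `crc_outcome` objects (or a list of lists with
#'   fields `strategy_id`, `crc_cases`, `cancer_lyl`, `total_cost`), which
#'   must include the `none` baseline.  Input order is irrelevant; rows come
#'   out in canonical strategy order.
#' @return Object of class `crc_comparison`: `$table` (one row per strategy)
#'   and `$icer_matrix` / `$icer_flags` (pairwise, row vs column).
#' @export
comparison_table <- function(outcomes) {
  ids <- vapply(outcomes, function(o) o$strategy_id, character(1))
  if (!"none" %in% ids) stop("comparison requires the no-screening baseline",
                             call. = FALSE)
  ord <- order(match(ids, crc_strategies()))
  outcomes <- outcomes[ord]
  ids <- ids[ord]
  base <- outcomes[[which(ids == "none")]]
  tab <- do.call(rbind, lapply(outcomes, function(o) {
    prevented <- cases_prevented(base$crc_cases, o$crc_cases)
    lys <- life_years_saved(base$cancer_lyl, o$cancer_lyl)
    data.frame(
      strategy = o$strategy_id,
      crc_cases = o$crc_cases,
      cancer_lyl = o$cancer_lyl,
      cases_prevented = prevented,
      proportion_prevented = proportion_prevented(prevented, base$crc_cases),
      life_years_saved = lys,
      total_cost = o$total_cost,
      additional_cost = additional_cost(o$total_cost, base$total_cost),
      cost_per_lys = as.numeric(cost_per_life_year_saved(o$total_cost, lys)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  effects <- stats::setNames(tab$life_years_saved, tab$strategy)
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  fl <- matrix("", n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ic <- icer(list(total_cost = tab$total_cost[i], effect = effects[i]),
                 list(total_cost = tab$total_cost[j], effect = effects[j]))
      m[i, j] <- ic$value
      fl[i, j] <- ic$flag
    }
  }
  tab$icer_vs_none <- m[, "none"]
  tab$icer_flag <- fl[, "none"]
  structure(list(table = tab, icer_matrix = m, icer_flags = fl,
                 baseline = "none"), class = "crc_comparison")
}

#' @export
print.crc_comparison <- function(x, ...) {
  tab <- x$table
  fmt_int <- function(v) format(round(v), big.mark = ",", scientific = FALSE)
  out <- data.frame(
    strategy = tab$strategy,
    `CRC cases` = fmt_int(tab$crc_cases),
    `LYL (disc.)` = fmt_int(tab$cancer_lyl),
    `prevented` = fmt_int(tab$cases_prevented),
    `prevented %` = sprintf("%.1f", tab$proportion_prevented),
    `LY saved` = fmt_int(tab$life_years_saved),
    `total cost` = fmt_int(tab$total_cost),
    `add. cost` = fmt_int(tab$additional_cost),
    `cost/LYS` = ifelse(is.na(tab$cost_per_lys), "-", fmt_int(tab$cost_per_lys)),
    `ICER vs none` = ifelse(is.na(tab$icer_vs_none), "-",
                            paste0(fmt_int(tab$icer_vs_none),
                                   ifelse(tab$icer_flag == "dominant", " (dominant)", ""))),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  print(out, row.names = FALSE, right = TRUE)
  invisible(x)
}

#' Reference per-strategy totals fixture
#'
#' Per-strategy lifetime CRC cases, discounted cancer-related life years
#' lost, and discounted total costs for the five strategies, as published in
#' the health-economics literature for a 100,000-person Hong Kong cohort.
#' These are *inputs* here: they exercise only the comparison arithmetic
#' ([comparison_table()] and friends), independently of the cohort engine,
#' and serve as a regression fixture for the derived rows (cases prevented,
#' proportions, life years saved, additional costs, ICERs, dominance).
#'
#' @return List of outcome records suitable for [comparison_table()].
#' @export
reference_totals <- function() {
  path <- system.file("extdata", "reference_outcomes.csv", package = "crcscreen")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    list(strategy_id = df$strategy[i],
         crc_cases = as.numeric(df$crc_cases[i]),
         cancer_lyl = as.numeric(df$cancer_life_years_lost[i]),
         total_cost = as.numeric(df$total_cost[i]))
  })
}

#' Export a comparison as CSV or JSON
#'
#' @param comparison A `crc_comparison`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  if (grepl("\\.json$", path)) {
    js <- jsonlite::toJSON(list(table = comparison$table,
                                icer_matrix = comparison$icer_matrix,
                                icer_flags = comparison$icer_flags),
                           dataframe = "rows", auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null")
    writeLines(js, path)
  } else {
    utils::write.csv(comparison$table, path, row.names = FALSE)
  }
  invisible(path)
}
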