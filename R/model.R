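#' Fit the full screening comparison model
#'
#' The package's main entry point: runs the deterministic cohort model for
#' each requested strategy under one configuration and life table, costs the
#' traces, and assembles the strategy comparison (effectiveness, costs,
#' pairwise ICERs and dominance).
#'
#' @param config A `crc_config` (default the base case).
#' @param strategies Strategy ids to run; the `none` baseline is always
#'   included.
#' @param life_table A `life_table`; defaults to the synthetic standard table.
#' @return Object of class `crc_model` with components `outcomes` (named list
#'   of `crc_outcome`), `comparison` (a `crc_comparison`), `traces`, `costs`,
#'   `config`, and `life_table`.  Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`, `simulate`.
#' @examples
#' \donttest{
#' fit <- crc_model()
#' fit
#' }
#' @export
crc_model <- function(config = crc_basecase(), strategies = crc_strategies(),
                      life_table = NULL) {
  strategies <- match.arg(strategies, crc_strategies(), several.ok = TRUE)
  strategies <- union("none", strategies)
  strategies <- crc_strategies()[crc_strategies() %in% strategies]
  lt <- if (is.null(life_table)) default_life_table() else life_table
  traces <- lapply(strategies, function(s) run_cohort(config, s, lt))
  names(traces) <- strategies
  costs <- lapply(traces, accumulate_costs)
  outcomes <- Map(strategy_outcome, traces, costs)
  comparison <- comparison_table(outcomes)
  structure(list(config = config, life_table = lt, strategies = strategies,
                 traces = traces, costs = costs, outcomes = outcomes,
                 comparison = comparison),
            class = "crc_model")
}

#' @export
print.crc_model <- function(x, ...) {
  cat(sprintf("CRC screening cost-effectiveness model (%s strategies, cohort %s)\n\n",
              length(x$strategies),
              format(x$config$economics$cohort_size, big.mark = ",")))
  print(x$comparison)
  invisible(x)
}

#' @export
summary.crc_model <- function(object, ...) {
  tab <- object$comparison$table
  scr <- tab[tab$strategy != "none", ]
  best <- scr$strategy[which.min(scr$icer_vs_none)]
  fl <- object$comparison$icer_flags
  doms <- which(fl == "dominant", arr.ind = TRUE)
  structure(list(table = tab,
                 lowest_icer = best,
                 dominances = data.frame(
                   dominant = rownames(fl)[doms[, 1]],
                   dominated = colnames(fl)[doms[, 2]],
                   stringsAsFactors = FALSE)),
            class = "summary.crc_model")
}

#' @export
print.summary.crc_model <- function(x, ...) {
  cat("Strategy comparison summary\n")
  cat(sprintf("  lowest ICER vs no screening: %s\n", x$lowest_icer))
  if (nrow(x$dominances)) {
    for (i in seq_len(nrow(x$dominances))) {
      cat(sprintf("  %s dominates %s (cheaper and more effective)\n",
                  x$dominances$dominant[i], x$dominances$dominated[i]))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.crc_model <- function(x, ...) {
  x$comparison$table
}

#' Cost-effectiveness plane
#'
#' Plots each strategy's life years saved against its additional discounted
#' cost, both relative to no screening.
#'
#' @param x A `crc_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.crc_model <- function(x, ...) {
  tab <- x$comparison$table
  graphics::plot(tab$life_years_saved, tab$additional_cost / 1e6,
                 xlab = "Life years saved vs no screening",
                 ylab = "Additional cost (US $ million)",
                 pch = 19, ...)
  graphics::text(tab$life_years_saved, tab$additional_cost / 1e6,
                 labels = tab$strategy, pos = 3, cex = 0.8)
  invisible(x)
}

#' Microsimulation draws from a fitted model
#'
#' Runs the seeded per-individual [microsim_oracle()] under the model's
#' configuration for each strategy, as a stochastic counterpart of the
#' deterministic cohort results.
#'
#' @param object A `crc_model`.
#' @param nsim Number of simulated individuals per strategy.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Data frame of scaled microsimulation summaries, one row per
#'   strategy.
#' @export
simulate.crc_model <- function(object, nsim = 10000, seed = 1, ...) {
  rows <- lapply(object$strategies, function(s) {
    ms <- microsim_oracle(object$config, s, object$life_table, n = nsim,
                          seed = seed)
    data.frame(strategy = s, cases = ms$cases, crc_deaths = ms$crc_deaths,
               lyl = ms$lyl, lyl_disc = ms$lyl_disc, fits = ms$fits,
               colonoscopies = ms$colo_total, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
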