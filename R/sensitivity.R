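#' One-way deterministic sensitivity sweep
#'
#' Re-runs the full strategy comparison at each grid value of one parameter,
#' all other parameters held at their configured values.  The grouped path
#' `"compliance.all"` moves the initial FIT, primary colonoscopy and
#' follow-up compliance together, matching the convention that compliance
#' for initial, repeated and follow-up screening is the same;
#' `"costs.care_multiplier"` scales all four stage-care costs.
#'
#' @param config A `crc_config`.
#' @param parameter Dotted parameter path (see [config_set()]).
#' @param grid Strictly monotone, non-empty vector of parameter values.
#' @param strategies Strategies to evaluate (baseline always included).
#' @param life_table Optional `life_table` shared by every run.
#' @return Object of class `crc_sweep`: a long data frame with one row per
#'   grid value and strategy, carrying cases, life years saved, total and
#'   additional cost, and the ICER versus no screening, with the parameter
#'   path and grid attached as attributes.
#' @export
one_way_sweep <- function(config, parameter, grid,
                          strategies = crc_strategies(), life_table = NULL) {
  if (!length(grid)) stop("sweep grid must be non-empty", call. = FALSE)
  if (length(grid) > 1 && !(all(diff(grid) > 0) || all(diff(grid) < 0))) {
    stop("sweep grid must be strictly monotone", call. = FALSE)
  }
  lt <- if (is.null(life_table)) default_life_table() else life_table
  rows <- lapply(grid, function(v) {
    cfg <- config_set(config, parameter, v)
    fit <- crc_model(cfg, strategies, lt)
    tab <- fit$comparison$table
    tab$parameter <- parameter
    tab$value <- v
    tab
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("crc_sweep", "data.frame"),
            parameter = parameter, grid = grid)
}

#' Two-way deterministic sensitivity sweep
#'
#' Evaluates the strategy comparison on the Cartesian grid of two parameters
#' and returns it as a long-format table.
#'
#' @param config A `crc_config`.
#' @param parameter_a,parameter_b Dotted parameter paths.
#' @param grid_a,grid_b Monotone grids for each parameter.
#' @param strategies Strategies to evaluate.
#' @param life_table Optional shared `life_table`.
#' @return A `crc_sweep` data frame with columns `value_a`, `value_b`.
#' @export
two_way_sweep <- function(config, parameter_a, grid_a, parameter_b, grid_b,
                          strategies = crc_strategies(), life_table = NULL) {
  if (!length(grid_a) || !length(grid_b)) {
    stop("sweep grids must be non-empty", call. = FALSE)
  }
  lt <- if (is.null(life_table)) default_life_table() else life_table
  rows <- list()
  for (va in grid_a) {
    cfg_a <- config_set(config, parameter_a, va)
    for (vb in grid_b) {
      cfg <- config_set(cfg_a, parameter_b, vb)
      fit <- crc_model(cfg, strategies, lt)
      tab <- fit$comparison$table
      tab$parameter_a <- parameter_a
      tab$value_a <- va
      tab$parameter_b <- parameter_b
      tab$value_b <- vb
      rows[[length(rows) + 1]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("crc_sweep", "data.frame"),
            parameter = c(parameter_a, parameter_b))
}

#' Default sweep grids
#'
#' The shipped grids: compliance 0.10 to 1.00 in steps of 0.10 (the stated
#' plausible range), FIT specificity from 0.20 up to the 0.919 base value in
#' eight steps, colonoscopy cost from half to twice the base in seven steps,
#' and stage-care cost multipliers from 0.5 to 2.
#'
#' @param config Configuration supplying base values.
#' @return Named list of `list(parameter, grid)` sweep specs.
#' @export
default_sweeps <- function(config = crc_basecase()) {
  list(
    compliance = list(parameter = "compliance.all",
                      grid = seq(0.1, 1.0, by = 0.1)),
    fit_specificity = list(parameter = "tests.fit_specificity",
                           grid = seq(0.20, config$tests$fit_specificity,
                                      length.out = 8)),
    fit_sensitivity = list(parameter = "tests.fit_sensitivity",
                           grid = seq(0.40, config$tests$fit_sensitivity,
                                      length.out = 8)),
    colonoscopy_cost = list(parameter = "costs.colonoscopy",
                            grid = config$costs$colonoscopy *
                              seq(0.5, 2, length.out = 7)),
    treatment_cost = list(parameter = "costs.care_multiplier",
                          grid = seq(0.5, 2, length.out = 7))
  )
}

#' Threshold detection on a sweep curve
#'
#' Finds the parameter values where a criterion curve changes sign, by
#' linear interpolation between adjacent grid points.  Exact zeros at grid
#' points are reported as crossings.  A non-monotone criterion may cross
#' several times; all crossings are returned in grid order and the first is
#' conventionally reported.
#'
#' @param x Grid values (ordered).
#' @param y Criterion values at `x` (e.g. the ICER difference between two
#'   strategies); `NA`s are dropped pairwise.
#' @return Numeric vector of crossing locations; length zero when the curve
#'   is one-signed.
#' @examples
#' find_threshold(seq(0, 1, 0.2), seq(0, 1, 0.2) - 0.4)  # 0.4
#' @export
find_threshold <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) return(numeric(0))
  out <- numeric(0)
  for (i in seq_len(length(x) - 1)) {
    y1 <- y[i]; y2 <- y[i + 1]
    if (y1 == 0 && (i == 1 || y[i - 1] != 0)) out <- c(out, x[i])
    if (y1 * y2 < 0) {
      out <- c(out, x[i] + (x[i + 1] - x[i]) * (-y1) / (y2 - y1))
    }
  }
  if (length(x) >= 2 && y[length(y)] == 0 && y[length(y) - 1] != 0) {
    out <- c(out, x[length(x)])
  }
  sort(unique(out))
}

#' Extract an ICER curve from a sweep
#'
#' @param sweep A `crc_sweep` from [one_way_sweep()].
#' @param strategy Strategy whose ICER-vs-none curve to extract.
#' @return Data frame with columns `value`, `icer`.
#' @export
icer_curve <- function(sweep, strategy) {
  s <- sweep[sweep$strategy == strategy, ]
  data.frame(value = s$value, icer = s$icer_vs_none)
}

#' Plot ICER-versus-parameter curves from a one-way sweep
#'
#' @param x A `crc_sweep`.
#' @param strategies Strategies to draw (default: all screening arms present).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.crc_sweep <- function(x, strategies = NULL, ...) {
  if (is.null(strategies)) {
    strategies <- setdiff(unique(x$strategy), "none")
  }
  grid <- sort(unique(x$value))
  m <- sapply(strategies, function(s) {
    s_rows <- x[x$strategy == s, ]
    s_rows$icer_vs_none[match(grid, s_rows$value)]
  })
  graphics::matplot(grid, m, type = "b", pch = 19, lty = 1,
                    xlab = attr(x, "parameter")[1],
                    ylab = "ICER vs no screening (US $ / life year)", ...)
  graphics::legend("topright", legend = strategies, col = seq_along(strategies),
                   lty = 1, pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}
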