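#' Screening strategy identifiers
#'
#' The five strategies the model compares: no screening; annual FIT with
#' conventional colonoscopy follow-up of positives (`fit_colo`); annual FIT
#' with AI-assisted colonoscopy follow-up (`fit_ai`); direct conventional
#' colonoscopy every ten years (`colo`); and direct AI-assisted colonoscopy
#' (`ai_colo`).
#'
#' @return Character vector of strategy ids, in canonical order.
#' @export
crc_strategies <- function() {
  c("none", "fit_colo", "fit_ai", "colo", "ai_colo")
}

#' Base-case model configuration
#'
#' Returns the complete base-case parameter set: FIT performance at the
#' 20 ug/g cutoff (sensitivity 0.73, specificity 0.919), compliance rates
#' (FIT 60\%, primary colonoscopy 98.9\%, colonoscopy after a positive FIT
#' 100\%), complication rates per colonoscopy, incidence-reduction fractions
#' (FIT 21\%, conventional colonoscopy 44.2\%, AI-assisted colonoscopy
#' 48.9\%), Hong Kong age-specific CRC incidence in quinquennial bands
#' (55.9 to 330.5 per 100,000), the stage distribution at diagnosis
#' (renormalized to sum to one), stage-specific annual CRC mortality, unit
#' costs in US dollars, and economic settings (3\% annual discounting,
#' 100,000-person cohort entering at age 50, screened to 75, followed to the
#' life-table horizon).
#'
#' @param scenario `"base"` for the tabulated baseline estimates, or
#'   `"programme_efficacy"` for the alternative scenario in which annual
#'   colonoscopy screening is credited with a 51.5\% incidence reduction
#'   (a figure reported for a territory-wide screening programme rather than
#'   the trial-derived 44.2\%).
#' @return A validated object of class `crc_config`.
#' @examples
#' cfg <- crc_basecase()
#' cfg$costs$colonoscopy       # 1259
#' cfg$economics$discount_rate # 0.03
#' @export
crc_basecase <- function(scenario = c("base", "programme_efficacy")) {
  scenario <- match.arg(scenario)
  dist_raw <- c(0.113, 0.254, 0.324, 0.310)
  cfg <- list(
    tests = list(
      fit_sensitivity = 0.73,
      fit_specificity = 0.919
    ),
    compliance = list(
      fit = 0.60,
      colonoscopy_primary = 0.989,
      colonoscopy_after_positive = 1.00
    ),
    complications = list(
      polypectomy_rate = 0.73,
      bleeding_rate = 0.0098,
      perforation_rate = 0.0008,
      perforation_mortality = 0.000029
    ),
    efficacy = list(
      fit = 0.21,
      colonoscopy = 0.442,
      ai_colonoscopy = 0.489
    ),
    incidence = data.frame(
      age_start = c(50, 55, 60, 65, 70, 75),
      age_end   = c(55, 60, 65, 70, 75, 120),
      rate      = c(55.9, 89.8, 137, 200, 253.2, 330.5)
    ),
    stages = list(
      distribution_raw = dist_raw,
      distribution = dist_raw / sum(dist_raw),
      annual_mortality = c(0.01, 0.045, 0.087, 0.43)
    ),
    costs = list(
      fit_kit = 19,
      colonoscopy = 1259,
      consultation = 96,
      bleeding_episode = 3320,
      histopathology = 142,
      perforation_episode = 10790,
      care_stage1 = 17071,
      care_stage2 = 19755,
      care_stage3 = 26883,
      care_stage4 = 45115
    ),
    economics = list(
      discount_rate = 0.03,
      cohort_size = 1e5,
      start_age = 50,
      screening_stop_age = 75,
      horizon_age = 100
    ),
    schedule = list(
      fit_interval = 1,
      post_normal_hiatus = 10,
      surveillance_interval = 3
    ),
    options = list(
      # how the 0.0029% mortality figure attaches: per perforation event,
      # per colonoscopy, or per polypectomy
      perforation_mortality_basis = "per_perforation",
      consultation_per_colonoscopy = TRUE,
      histopathology_per_therapeutic = TRUE,
      # years a diagnosed patient must survive stage-specific mortality
      # before exiting to the cured state
      cure_years = 5,
      # adenoma removal at colonoscopy confers durable protection: direct
      # colonoscopy arms keep their incidence reduction after screening stops
      colonoscopy_protection_persists = TRUE,
      # discount lost life years from model start (alternative: from the
      # year of death only, i.e. no calendar offset)
      discount_lyl_from = "model_start",
      # FIT re-offer policy: "per_hiatus" puts a person who has tested
      # negative on the same ten-year hiatus as a clean colonoscopy
      # (non-attenders are re-invited annually), which reproduces published
      # programme volumes of roughly 2.4 FITs per person over 25 years;
      # "annual" re-offers every negative annually
      fit_reoffer = "per_hiatus"
    ),
    life_table_source = "synthetic"
  )
  if (scenario == "programme_efficacy") {
    cfg$efficacy$colonoscopy <- 0.515
  }
  structure(cfg, class = "crc_config")
}

#' @export
print.crc_config <- function(x, ...) {
  cat("CRC screening model configuration\n")
  cat(sprintf("  cohort: %s persons, ages %d-%d (screening to %d)\n",
              format(x$economics$cohort_size, big.mark = ","),
              x$economics$start_age, x$economics$horizon_age,
              x$economics$screening_stop_age))
  cat(sprintf("  FIT sens/spec: %.3f/%.3f, compliance FIT %.3f, colonoscopy %.3f\n",
              x$tests$fit_sensitivity, x$tests$fit_specificity,
              x$compliance$fit, x$compliance$colonoscopy_primary))
  cat(sprintf("  incidence reduction: FIT %.3f, colonoscopy %.3f, AI %.3f\n",
              x$efficacy$fit, x$efficacy$colonoscopy, x$efficacy$ai_colonoscopy))
  cat(sprintf("  discount rate: %.2f%%\n", 100 * x$economics$discount_rate))
  viol <- validate_config(x)
  if (nrow(viol)) cat(sprintf("  ** %d validation violation(s) **\n", nrow(viol)))
  invisible(x)
}

# flatten a nested config into dotted paths -> atomic values
flatten_config <- function(x, prefix = character()) {
  if (is.data.frame(x)) {
    out <- list()
    for (nm in names(x)) {
      for (i in seq_len(nrow(x))) {
        out[[paste(c(prefix, nm, i), collapse = ".")]] <- x[[nm]][i]
      }
    }
    return(out)
  }
  if (is.list(x)) {
    out <- list()
    for (nm in names(x)) {
      out <- c(out, flatten_config(x[[nm]], c(prefix, nm)))
    }
    return(out)
  }
  if (length(x) > 1) {
    out <- as.list(x)
    names(out) <- paste(paste(prefix, collapse = "."), seq_along(x), sep = ".")
    return(out)
  }
  stats::setNames(list(x), paste(prefix, collapse = "."))
}

viol_row <- function(field, value, rule) {
  data.frame(field = field, value = as.numeric(value)[1], rule = rule,
             stringsAsFactors = FALSE)
}

#' Validate a model configuration
#'
#' Checks every structural invariant of a [crc_config] object and returns the
#' violations as data, not exceptions: each row names the offending field, the
#' observed value and the rule broken.  Soft inconsistencies that do not stop
#' a run (e.g. AI efficacy below conventional) are attached as a `warnings`
#' attribute.
#'
#' @param config A `crc_config` object (possibly with overridden fields).
#' @return A data frame with columns `field`, `value`, `rule`; zero rows iff
#'   the configuration is valid.
#' @examples
#' nrow(validate_config(crc_basecase()))  # 0
#' @export
validate_config <- function(config) {
  v <- list()
  w <- list()
  prob_fields <- c(
    "tests.fit_sensitivity", "tests.fit_specificity",
    "compliance.fit", "compliance.colonoscopy_primary",
    "compliance.colonoscopy_after_positive",
    "complications.polypectomy_rate", "complications.bleeding_rate",
    "complications.perforation_rate", "complications.perforation_mortality",
    "efficacy.fit", "efficacy.colonoscopy", "efficacy.ai_colonoscopy"
  )
  for (f in prob_fields) {
    parts <- strsplit(f, ".", fixed = TRUE)[[1]]
    val <- config[[parts[1]]][[parts[2]]]
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val < 0 || val > 1) {
      v[[length(v) + 1]] <- viol_row(f, val, "must be a probability in [0, 1]")
    }
  }
  # incidence bands: contiguous, non-overlapping, covering the model ages
  inc <- config$incidence
  if (any(inc$rate < 0)) {
    v[[length(v) + 1]] <- viol_row("incidence.rate", min(inc$rate), "rates must be >= 0")
  }
  if (nrow(inc) && any(diff(inc$age_start) <= 0)) {
    v[[length(v) + 1]] <- viol_row("incidence.age_start", NA, "bands must be ordered")
  }
  if (nrow(inc) > 1 && any(inc$age_end[-nrow(inc)] != inc$age_start[-1])) {
    v[[length(v) + 1]] <- viol_row("incidence.age_end", NA,
                                   "bands must be contiguous and non-overlapping")
  }
  eco <- config$economics
  if (nrow(inc) && (inc$age_start[1] > eco$start_age ||
                    inc$age_end[nrow(inc)] < eco$horizon_age)) {
    v[[length(v) + 1]] <- viol_row("incidence", NA,
                                   "bands must cover [start_age, horizon_age]")
  }
  # stage model
  sd <- config$stages$distribution
  if (length(sd) != 4 || abs(sum(sd) - 1) > 1e-9) {
    v[[length(v) + 1]] <- viol_row("stages.distribution", sum(sd),
                                   sprintf("sums to %.6g, must sum to 1", sum(sd)))
  }
  sm <- config$stages$annual_mortality
  if (any(sm < 0 | sm > 1)) {
    v[[length(v) + 1]] <- viol_row("stages.annual_mortality", NA,
                                   "mortalities must be in [0, 1]")
  } else if (any(diff(sm) < 0)) {
    v[[length(v) + 1]] <- viol_row("stages.annual_mortality", NA,
                                   "mortalities must be non-decreasing in stage")
  }
  # costs
  for (f in names(config$costs)) {
    val <- config$costs[[f]]
    if (!is.numeric(val) || is.na(val) || val < 0) {
      v[[length(v) + 1]] <- viol_row(paste0("costs.", f), val, "costs must be >= 0")
    }
  }
  care <- unlist(config$costs[paste0("care_stage", 1:4)])
  if (!any(is.na(care)) && any(diff(care) < 0)) {
    v[[length(v) + 1]] <- viol_row("costs.care_stage", NA,
                                   "care costs must be non-decreasing in stage")
  }
  # economics
  if (eco$discount_rate < 0) {
    v[[length(v) + 1]] <- viol_row("economics.discount_rate", eco$discount_rate,
                                   "discount rate must be >= 0")
  }
  if (eco$cohort_size <= 0) {
    v[[length(v) + 1]] <- viol_row("economics.cohort_size", eco$cohort_size,
                                   "cohort size must be > 0")
  }
  if (!(eco$start_age < eco$screening_stop_age &&
        eco$screening_stop_age <= eco$horizon_age)) {
    v[[length(v) + 1]] <- viol_row("economics.start_age", eco$start_age,
                                   "requires start_age < screening_stop_age <= horizon_age")
  }
  # schedule
  for (f in names(config$schedule)) {
    val <- config$schedule[[f]]
    if (!is.numeric(val) || val < 1 || val != round(val)) {
      v[[length(v) + 1]] <- viol_row(paste0("schedule.", f), val,
                                     "intervals must be whole years >= 1")
    }
  }
  # soft warnings
  if (config$efficacy$ai_colonoscopy < config$efficacy$colonoscopy) {
    w[[length(w) + 1]] <- viol_row("efficacy.ai_colonoscopy",
                                   config$efficacy$ai_colonoscopy,
                                   "AI efficacy below conventional colonoscopy")
  }
  if (config$complications$perforation_mortality > config$complications$perforation_rate) {
    w[[length(w) + 1]] <- viol_row("complications.perforation_mortality",
                                   config$complications$perforation_mortality,
                                   "perforation mortality exceeds perforation rate")
  }
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(field = character(), value = numeric(), rule = character(),
               stringsAsFactors = FALSE)
  attr(out, "warnings") <- if (length(w)) do.call(rbind, w) else NULL
  out
}

merge_config <- function(base, override, path = character()) {
  for (nm in names(override)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ", here, call. = FALSE)
    }
    if (is.list(base[[nm]]) && !is.data.frame(base[[nm]])) {
      if (!is.list(override[[nm]])) {
        stop("configuration key ", here, " must be a mapping", call. = FALSE)
      }
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], c(path, nm))
    } else if (is.data.frame(base[[nm]])) {
      df <- as.data.frame(override[[nm]], stringsAsFactors = FALSE)
      if (!setequal(names(df), names(base[[nm]]))) {
        stop("configuration key ", here, " must have columns ",
             paste(names(base[[nm]]), collapse = ", "), call. = FALSE)
      }
      base[[nm]] <- df[names(base[[nm]])]
    } else {
      val <- override[[nm]]
      if (is.list(val)) val <- unlist(val)
      base[[nm]] <- val
    }
  }
  base
}

#' Load a model configuration from YAML
#'
#' Reads a (possibly partial) YAML override file and merges it onto the base
#' case: any field not mentioned keeps its base-case value, unknown keys are
#' an error, and the merged configuration is validated before being returned.
#' All rates are fractions (e.g. `fit: 0.3`), never percentages.  The dotted
#' paths of overridden fields are recorded in the `overrides` attribute.
#'
#' @param path Path to a YAML file.  An empty file reproduces [crc_basecase()].
#' @param base Configuration to merge onto (default the base case).
#' @return A validated `crc_config`.
#' @seealso [write_config()] for the round trip, [validate_config()].
#' @export
load_config <- function(path, base = crc_basecase()) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  override <- yaml::read_yaml(path)
  if (is.null(override)) override <- list()
  # stage distribution overrides arrive raw and are renormalized like the base case
  if (!is.null(override$stages$distribution)) {
    if (is.null(override$stages$distribution_raw)) {
      override$stages$distribution_raw <- override$stages$distribution
    }
    override$stages$distribution <-
      unlist(override$stages$distribution) / sum(unlist(override$stages$distribution))
  }
  cfg <- merge_config(unclass(base), override)
  class(cfg) <- "crc_config"
  viol <- validate_config(cfg)
  if (nrow(viol)) {
    stop("invalid configuration: ",
         paste(sprintf("%s (%s)", viol$field, viol$rule), collapse = "; "),
         call. = FALSE)
  }
  attr(cfg, "overrides") <- names(flatten_config(override))
  cfg
}

#' Write a configuration to YAML
#'
#' @param config A `crc_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$incidence <- as.list(x$incidence)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Export a configuration as JSON
#'
#' @param config A `crc_config`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
config_json <- function(config, path = NULL) {
  js <- jsonlite::toJSON(unclass(config), dataframe = "columns",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Tabulate the base-case parameter manifest
#'
#' One row per scalar parameter of a configuration, with its dotted field
#' path, value and parameter category — useful for auditing which numbers a
#' run actually used.
#'
#' @param config A `crc_config` (default the base case).
#' @return Data frame with columns `parameter`, `value`, `category`.
#' @export
config_manifest <- function(config = crc_basecase()) {
  fl <- flatten_config(unclass(config))
  fl <- fl[vapply(fl, is.numeric, logical(1))]
  cat_of <- function(p) strsplit(p, ".", fixed = TRUE)[[1]][1]
  data.frame(parameter = names(fl),
             value = unlist(fl, use.names = FALSE),
             category = vapply(names(fl), cat_of, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Set a configuration field by dotted path
#'
#' Used by the sensitivity sweeps.  Two grouped paths are recognized:
#' `"compliance.all"` moves the initial FIT, primary colonoscopy and
#' follow-up compliance together (the convention used in the compliance
#' sensitivity analysis), and `"costs.care_multiplier"` scales all four
#' stage-care costs by `value`.
#'
#' @param config A `crc_config`.
#' @param path Dotted field path, e.g. `"tests.fit_specificity"`.
#' @param value Replacement value (or multiplier for grouped cost paths).
#' @return The modified `crc_config`.
#' @export
config_set <- function(config, path, value) {
  if (path == "compliance.all") {
    config$compliance$fit <- value
    config$compliance$colonoscopy_primary <- value
    config$compliance$colonoscopy_after_positive <- value
    return(config)
  }
  if (path == "costs.care_multiplier") {
    for (s in paste0("care_stage", 1:4)) {
      config$costs[[s]] <- config$costs[[s]] * value
    }
    return(config)
  }
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (p in parts[-length(parts)]) {
    if (is.null(node[[p]])) stop("cannot resolve parameter path: ", path, call. = FALSE)
    node <- node[[p]]
  }
  last <- parts[length(parts)]
  if (is.null(node[[last]])) stop("cannot resolve parameter path: ", path, call. = FALSE)
  config[[parts]] <- value
  config
}

#' Build a strategy schedule
#'
#' @param strategy_id One of [crc_strategies()].
#' @param config Configuration providing the interval defaults (annual FIT,
#'   ten-year post-normal hiatus, three-year surveillance).
#' @return A list of class `crc_schedule`.
#' @export
strategy_schedule <- function(strategy_id, config = crc_basecase()) {
  strategy_id <- match.arg(strategy_id, crc_strategies())
  structure(list(
    strategy_id = strategy_id,
    fit_interval = config$schedule$fit_interval,
    post_normal_hiatus = config$schedule$post_normal_hiatus,
    surveillance_interval = config$schedule$surveillance_interval
  ), class = "crc_schedule")
}
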