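#' Model parameters for the PAH cost-utility model
#'
#' `pah_parameters()` loads a model configuration — by default the bundled
#' transcription of the published parameter table (`table1.yaml`) — and
#' returns a validated `pah_params` object. The configuration holds, for
#' each uncertain quantity, a mean, a standard error and a sampling
#' distribution family (`beta`, `gamma`, `lognormal` or `fixed`), plus
#' economic settings (discount rate, cycle length, horizon, willingness to
#' pay, perspective, drug prices) and epidemiology inputs for the budget
#' projection.
#'
#' The object keeps all uncertain parameters in a single long tibble with
#' one row per quantity and a `value` column initialised at the mean;
#' probabilistic analyses replace `value` with random draws (see
#' [sample_parameters()]).
#'
#' @param path Path to a YAML configuration. `NULL` loads the bundled
#'   default.
#' @return A `pah_params` object: a list with elements `table` (tibble of
#'   uncertain parameters), `settings` and `epidemiology`.
#' @examples
#' p <- pah_parameters()
#' dplyr::filter(tidy(p), group == "utilities")
#' @export
pah_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1.yaml", package = "pahcea")
  }
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  params_from_config(cfg)
}

# Build a pah_params from a nested configuration list.
params_from_config <- function(cfg) {
  for (sec in c("settings", "epidemiology", "transitions", "deaths",
                "effects", "costs", "utilities")) {
    if (is.null(cfg[[sec]])) {
      stop(sprintf("validation error at /%s: section missing", sec), call. = FALSE)
    }
  }
  tab <- flatten_moments(cfg[c("transitions", "deaths", "effects",
                               "costs", "utilities")])
  obj <- structure(
    list(table = tab, settings = cfg$settings, epidemiology = cfg$epidemiology),
    class = "pah_params"
  )
  validate_parameters(obj)
  obj
}

# Flatten nested {mean, se, family} leaves into a long tibble keyed by the
# dotted path, e.g. "costs.admissions_per_cycle.fc2".
flatten_moments <- function(x, prefix = character()) {
  if (is.list(x) && all(c("mean", "se", "family") %in% names(x))) {
    return(tibble::tibble(
      id = paste(prefix, collapse = "."),
      group = prefix[[1]],
      mean = as.numeric(x$mean), se = as.numeric(x$se),
      family = as.character(x$family), value = as.numeric(x$mean)
    ))
  }
  if (!is.list(x) || is.null(names(x))) {
    stop(sprintf("validation error at /%s: expected {mean, se, family} or a section",
                 paste(prefix, collapse = "/")), call. = FALSE)
  }
  purrr::list_rbind(purrr::imap(x, function(v, nm) {
    flatten_moments(v, c(prefix, nm))
  }))
}

#' Validate a parameter set
#'
#' Checks structural completeness and domain constraints: known
#' distribution families, nonnegative SEs, probabilities and utilities in
#' \[0, 1\], positive relative risks, nonnegative costs and counts, and the
#' presence of required settings. Errors name the offending field with a
#' JSON-pointer-style path.
#'
#' @param params A `pah_params` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "pah_params"))
  tab <- params$table
  fail <- function(id, msg) {
    stop(sprintf("validation error at /%s: %s", gsub("\\.", "/", id), msg),
         call. = FALSE)
  }
  required <- c(
    paste0("transitions.", c("fc1_to_fc2", "fc2_to_fc1", "fc2_to_fc3",
                             "fc3_to_fc2", "fc3_to_fc4", "fc4_to_fc3")),
    paste0("deaths.fc", 1:4),
    paste0("effects.", rep(c("sildenafil", "beraprost"), each = 2),
           ".", c("rr_worsening", "rr_improvement")),
    paste0("costs.admissions_per_cycle.fc", 1:4),
    paste0("costs.visits_per_cycle.fc", 1:4),
    "costs.cost_per_admission", "costs.cost_per_visit",
    paste0("costs.nonmedical_per_cycle.fc", 1:4),
    "costs.drug_per_cycle.sildenafil", "costs.drug_per_cycle.beraprost",
    paste0("utilities.fc", 1:4)
  )
  missing <- setdiff(required, tab$id)
  if (length(missing)) fail(missing[[1]], "required parameter missing")

  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (!row$family %in% c("beta", "gamma", "lognormal", "fixed")) {
      fail(row$id, sprintf("unknown distribution family '%s'", row$family))
    }
    if (!is.finite(row$mean)) fail(row$id, "mean must be finite")
    if (!is.finite(row$se) || row$se < 0) fail(row$id, "se must be >= 0")
    bounded01 <- row$group %in% c("transitions", "deaths", "utilities")
    if (bounded01 && (row$mean < 0 || row$mean > 1)) {
      fail(row$id, sprintf("value %g outside [0, 1]", row$mean))
    }
    if (row$group == "effects" && row$mean <= 0) {
      fail(row$id, "relative risk must be > 0")
    }
    if (row$group == "costs" && row$mean < 0) fail(row$id, "must be >= 0")
  }
  s <- params$settings
  for (key in c("annual_discount_rate", "cycle_length_years", "horizon_cycles",
                "wtp_per_qaly", "perspective")) {
    if (is.null(s[[key]])) fail(paste0("settings.", key), "setting missing")
  }
  if (s$annual_discount_rate < 0) fail("settings.annual_discount_rate", "must be >= 0")
  if (s$horizon_cycles < 1) fail("settings.horizon_cycles", "must be >= 1")
  if (!s$perspective %in% c("societal", "government")) {
    fail("settings.perspective", "must be 'societal' or 'government'")
  }
  invisible(params)
}

#' Write a parameter set back to YAML
#'
#' Inverse of [pah_parameters()]: serialises the parameter table (at its
#' current `value` = mean for an unsampled set), settings and epidemiology
#' to a YAML document that reloads to an identical object.
#'
#' @param params A `pah_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "pah_params"))
  assign_path <- function(lst, keys, value) {
    if (length(keys) == 1) {
      lst[[keys]] <- value
    } else {
      if (is.null(lst[[keys[[1]]]])) lst[[keys[[1]]]] <- list()
      lst[[keys[[1]]]] <- assign_path(lst[[keys[[1]]]], keys[-1], value)
    }
    lst
  }
  nested <- list()
  for (i in seq_len(nrow(params$table))) {
    row <- params$table[i, ]
    nested <- assign_path(nested, strsplit(row$id, ".", fixed = TRUE)[[1]],
                          list(mean = row$mean, se = row$se, family = row$family))
  }
  doc <- c(list(settings = params$settings, epidemiology = params$epidemiology),
           nested)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

# Look up current values (mean or sampled) by id; errors on unknown ids.
param_value <- function(params, id) {
  idx <- match(id, params$table$id)
  if (anyNA(idx)) stop("unknown parameter id: ", id[is.na(idx)][1], call. = FALSE)
  params$table$value[idx]
}

# Per-FC vector (fc1..fc4) of current values under a dotted prefix.
fc_values <- function(params, prefix) {
  param_value(params, paste0(prefix, ".fc", 1:4))
}

#' Direct medical cost per cycle by functional class
#'
#' Aggregates admission and outpatient-visit components into the per-cycle
#' direct medical cost of each living state:
#' `admissions x cost_per_admission + visits x cost_per_visit`. Drug cost
#' is excluded (it is arm-specific and added separately); the death state
#' carries zero cost by contract.
#'
#' @param params A `pah_params` object.
#' @return A tibble with columns `fc` (1:4) and `direct_medical` (USD per
#'   3-month cycle). At the bundled defaults this reproduces the published
#'   per-class totals (317, 368, 224, 404 USD) within rounding.
#' @export
direct_medical_cost <- function(params) {
  adm <- fc_values(params, "costs.admissions_per_cycle")
  vis <- fc_values(params, "costs.visits_per_cycle")
  tibble::tibble(
    fc = 1:4,
    direct_medical = adm * param_value(params, "costs.cost_per_admission") +
      vis * param_value(params, "costs.cost_per_visit")
  )
}

# Total per-cycle cost vector over living states for one arm and
# perspective. Societal adds household (non-medical) cost; the drug cost
# accrues in every living state.
state_costs <- function(params, drug, perspective = params$settings$perspective) {
  cost <- direct_medical_cost(params)$direct_medical +
    param_value(params, paste0("costs.drug_per_cycle.", drug))
  if (identical(perspective, "societal")) {
    cost <- cost + fc_values(params, "costs.nonmedical_per_cycle")
  }
  cost
}

#' Set the sildenafil price scenario
#'
#' Rebuilds the sildenafil per-cycle drug cost from a unit tablet price:
#' `tablets_per_cycle x price x multiplier`. The `"generic"` scenario at
#' multiplier 1 reproduces the default per-cycle cost (270 x 0.34 ~ 92
#' USD); `"originator"` uses the originator tablet price.
#'
#' @param params A `pah_params` object.
#' @param scenario `"generic"` or `"originator"`.
#' @param multiplier Price multiplier in (0, 1\]; used by the threshold
#'   price search.
#' @return The modified `pah_params`.
#' @export
set_price_scenario <- function(params, scenario = c("generic", "originator"),
                               multiplier = 1) {
  scenario <- match.arg(scenario)
  stopifnot(multiplier > 0)
  price <- switch(scenario,
    generic = params$settings$prices$sildenafil_generic_per_tablet,
    originator = params$settings$prices$sildenafil_originator_per_tablet
  )
  per_cycle <- params$settings$tablets_per_cycle * price * multiplier
  idx <- match("costs.drug_per_cycle.sildenafil", params$table$id)
  params$table$mean[idx] <- per_cycle
  params$table$value[idx] <- per_cycle
  params
}

#' @export
print.pah_params <- function(x, ...) {
  cat("<pah_params>", nrow(x$table), "uncertain parameters\n")
  cat("  perspective:", x$settings$perspective,
      "| discount:", x$settings$annual_discount_rate,
      "| horizon:", x$settings$horizon_cycles, "cycles",
      sprintf("(%.1f years)\n",
              x$settings$horizon_cycles * x$settings$cycle_length_years))
  cat("  WTP per QALY:", x$settings$wtp_per_qaly, x$settings$currency, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname pah_parameters
#' @param x A `pah_params` object.
#' @param ... Unused.
#' @method tidy pah_params
#' @export
tidy.pah_params <- function(x, ...) x$table
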