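#' Simulate a patient-level interview/billing cohort
#'
#' Generates the kind of microdata from which the model's cost and utility
#' parameters were estimated: one record per patient with functional
#' class, 3-month hospital admission and outpatient visit counts, unit
#' admission and visit costs, 3-month household (non-medical) cost and an
#' EQ-5D-style utility. The default class sizes (18, 19, 10, 1) mirror
#' the study's 48-patient sample, including the single FC IV patient.
#'
#' Counts are drawn from a Poisson law at the configured per-class mean
#' (nonnegative, integer-valued); monetary amounts from the fitted gamma
#' distributions; utilities from the fitted betas. Utilities are drawn
#' directly at the class level — dimension-level EQ-5D simulation is not
#' attempted, since no tariff is part of the model.
#'
#' @param params A [pah_parameters()] object providing the generating
#'   ("truth") parameter values.
#' @param n_per_fc Integer vector of patients per functional class I-IV.
#' @param seed Optional integer seed.
#' @return A tibble with one row per patient: `patient_id`, `fc`,
#'   `admissions`, `visits`, `admission_cost`, `visit_cost`,
#'   `nonmedical_cost`, `utility`.
#' @examples
#' cohort <- simulate_patients(pah_parameters(), seed = 1)
#' dplyr::count(cohort, fc)
#' @export
simulate_patients <- function(params, n_per_fc = c(18, 19, 10, 1), seed = NULL) {
  stopifnot(length(n_per_fc) == 4, all(n_per_fc >= 0))
  if (!is.null(seed)) set.seed(seed)
  n <- sum(n_per_fc)
  fc <- rep(1:4, times = n_per_fc)
  if (n == 0) {
    return(tibble::tibble(
      patient_id = integer(), fc = integer(), admissions = integer(),
      visits = integer(), admission_cost = numeric(), visit_cost = numeric(),
      nonmedical_cost = numeric(), utility = numeric()
    ))
  }
  adm_mean <- fc_values(params, "costs.admissions_per_cycle")[fc]
  vis_mean <- fc_values(params, "costs.visits_per_cycle")[fc]
  gdraw <- function(n, mean, se) {
    fit <- fit_gamma_moments(mean, se)
    stats::rgamma(n, shape = fit$shape, scale = fit$scale)
  }
  bdraw <- function(n, mean, se) {
    fit <- fit_beta_moments(mean, se)
    stats::rbeta(n, fit$shape1, fit$shape2)
  }
  tab <- params$table
  mom <- function(id) tab[match(id, tab$id), ]
  nm <- mom(paste0("costs.nonmedical_per_cycle.fc", 1:4))
  ut <- mom(paste0("utilities.fc", 1:4))
  ca <- mom("costs.cost_per_admission")
  cv <- mom("costs.cost_per_visit")
  tibble::tibble(
    patient_id = seq_len(n),
    fc = fc,
    admissions = stats::rpois(n, adm_mean),
    visits = stats::rpois(n, vis_mean),
    admission_cost = gdraw(n, ca$mean, ca$se),
    visit_cost = gdraw(n, cv$mean, cv$se),
    nonmedical_cost = purrr::map_dbl(fc, function(k) {
      gdraw(1, nm$mean[k], nm$se[k])
    }),
    utility = purrr::map_dbl(fc, function(k) bdraw(1, ut$mean[k], ut$se[k]))
  )
}

#' Estimate cost and utility moments from patient records
#'
#' Recomputes the model's interview-derived parameters from microdata:
#' per-class sample means and standard errors (SD / sqrt(n)) for admission
#' counts, visit counts, non-medical cost and utility, plus pooled means
#' for the per-admission and per-visit unit costs. A class observed in a
#' single patient has a defined mean but a missing SE, mirroring the
#' degenerate FC IV situation of the source sample; estimation must not
#' fail on it.
#'
#' @param records A tibble as produced by [simulate_patients()].
#' @return A tibble in the parameter-table schema (`id`, `group`, `mean`,
#'   `se`, `family`) plus `n`, directly usable to update a parameter set
#'   via [update_parameters()].
#' @export
estimate_moments <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("no patient records to estimate from", call. = FALSE)
  }
  se_of <- function(x) {
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  per_fc <- function(var, prefix, family) {
    d <- dplyr::summarise(
      dplyr::group_by(records, .data$fc),
      mean = mean(.data[[var]]), se = se_of(.data[[var]]),
      n = dplyr::n(), .groups = "drop"
    )
    tibble::tibble(
      id = paste0(prefix, ".fc", d$fc),
      group = strsplit(prefix, ".", fixed = TRUE)[[1]][1],
      mean = d$mean, se = d$se, family = family, n = d$n
    )
  }
  pooled <- function(var, id) {
    tibble::tibble(id = id, group = "costs", mean = mean(records[[var]]),
                   se = se_of(records[[var]]), family = "gamma",
                   n = nrow(records))
  }
  dplyr::bind_rows(
    per_fc("admissions", "costs.admissions_per_cycle", "gamma"),
    per_fc("visits", "costs.visits_per_cycle", "gamma"),
    pooled("admission_cost", "costs.cost_per_admission"),
    pooled("visit_cost", "costs.cost_per_visit"),
    per_fc("nonmedical_cost", "costs.nonmedical_per_cycle", "gamma"),
    per_fc("utility", "utilities", "beta")
  )
}

#' Update a parameter set with estimated moments
#'
#' Replaces the mean/SE of matching parameters with estimates from
#' [estimate_moments()], closing the loop from microdata back to model
#' input. Estimates with missing SE keep the original SE; zero-mean
#' estimates for gamma-family rows are marked `fixed` (a gamma law cannot
#' have mean 0).
#'
#' @param params A [pah_parameters()] object.
#' @param estimates Output of [estimate_moments()].
#' @return The updated `pah_params`.
#' @export
update_parameters <- function(params, estimates) {
  for (i in seq_len(nrow(estimates))) {
    j <- match(estimates$id[i], params$table$id)
    if (is.na(j)) next
    params$table$mean[j] <- estimates$mean[i]
    params$table$value[j] <- estimates$mean[i]
    if (!is.na(estimates$se[i])) params$table$se[j] <- estimates$se[i]
    if (estimates$mean[i] <= 0 && params$table$family[j] == "gamma") {
      params$table$family[j] <- "fixed"
    }
  }
  params
}
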