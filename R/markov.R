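STATES <- c("fc1", "fc2", "fc3", "fc4", "death")

#' Build a per-cycle transition matrix for one treatment arm
#'
#' Constructs the 5x5 row-stochastic matrix over states (FC I, FC II,
#' FC III, FC IV, death) for a 3-month cycle. Transitions are restricted
#' to adjacent functional classes plus death. A treatment arm's matrix is
#' obtained by multiplying the baseline switching probabilities by the
#' arm's relative risks: worsening probabilities by `rr_worsening`,
#' improvement probabilities by `rr_improvement`; per-class death
#' probabilities are common to both arms. The probability of remaining in
#' a class is the residual.
#'
#' If a (typically sampled) parameter combination makes a row's moves plus
#' death exceed 1, the improvement and worsening probabilities are scaled
#' down proportionally so that the row sums to 1 with death untouched
#' (death probabilities are the anchored survival data); a warning is
#' emitted unless `cap = FALSE`, in which case such a row is an error.
#'
#' @param params A [pah_parameters()] object (current `value`s are used, so
#'   sampled realizations work transparently).
#' @param drug `"sildenafil"`, `"beraprost"`, or `"none"` for standard
#'   treatment (relative risks of 1).
#' @param cap Apply the proportional capping rule to over-full rows.
#' @return A 5x5 matrix with `dimnames` the state labels and attributes
#'   `drug` and `capped` (number of rows capped).
#' @examples
#' M <- transition_matrix(pah_parameters(), "sildenafil")
#' rowSums(M)
#' @export
transition_matrix <- function(params, drug = c("sildenafil", "beraprost", "none"),
                              cap = TRUE) {
  drug <- match.arg(drug)
  rr_w <- if (drug == "none") 1 else
    param_value(params, paste0("effects.", drug, ".rr_worsening"))
  rr_i <- if (drug == "none") 1 else
    param_value(params, paste0("effects.", drug, ".rr_improvement"))

  worsen <- c(param_value(params, "transitions.fc1_to_fc2"),
              param_value(params, "transitions.fc2_to_fc3"),
              param_value(params, "transitions.fc3_to_fc4"), 0) * rr_w
  improve <- c(0, param_value(params, "transitions.fc2_to_fc1"),
               param_value(params, "transitions.fc3_to_fc2"),
               param_value(params, "transitions.fc4_to_fc3")) * rr_i
  death <- fc_values(params, "deaths")

  M <- matrix(0, 5, 5, dimnames = list(STATES, STATES))
  capped <- 0L
  for (i in 1:4) {
    w <- if (i < 4) worsen[i] else 0
    im <- if (i > 1) improve[i] else 0
    moves <- w + im
    if (moves + death[i] > 1) {
      if (!cap) {
        stop(sprintf("invalid transition row for %s in fc%d: probabilities sum to %g",
                     drug, i, moves + death[i]), call. = FALSE)
      }
      scale <- (1 - death[i]) / moves
      w <- w * scale
      im <- im * scale
      capped <- capped + 1L
    }
    if (i < 4) M[i, i + 1] <- w
    if (i > 1) M[i, i - 1] <- im
    M[i, 5] <- death[i]
    stay <- 1 - w - im - death[i]
    if (stay < 0 && stay > -1e-9) stay <- 0  # floating-point residue of capping
    M[i, i] <- stay
  }
  M[5, 5] <- 1
  if (capped > 0) {
    warning(sprintf("%d transition row(s) capped for %s", capped, drug),
            call. = FALSE)
  }
  structure(M, drug = drug, capped = capped)
}

#' Run the cohort simulation
#'
#' Propagates a cohort that starts entirely in one functional class through
#' the per-cycle transition matrix: `occupancy[k + 1] = occupancy[k] %*% M`.
#'
#' @param matrix A transition matrix from [transition_matrix()].
#' @param start_fc Starting functional class, 1-4 (the model is used from
#'   FC II or FC III).
#' @param horizon_cycles Number of 3-month cycles to simulate (>= 1).
#' @return A `pah_trace` tibble with columns `cycle` (0..horizon) and the
#'   occupancy fraction of each state; attributes `drug` and `start_fc`.
#' @export
run_cohort <- function(matrix, start_fc, horizon_cycles) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(5, 5)))
  if (!start_fc %in% 1:4) stop("start_fc must be 1, 2, 3 or 4", call. = FALSE)
  if (horizon_cycles < 1) stop("horizon_cycles must be >= 1", call. = FALSE)
  occ <- matrix(0, horizon_cycles + 1, 5, dimnames = list(NULL, STATES))
  occ[1, start_fc] <- 1
  for (k in seq_len(horizon_cycles)) {
    occ[k + 1, ] <- occ[k, ] %*% matrix
  }
  out <- tibble::as_tibble(as.data.frame(occ))
  out <- dplyr::bind_cols(tibble::tibble(cycle = 0:horizon_cycles), out)
  structure(out, drug = attr(matrix, "drug"), start_fc = start_fc,
            class = c("pah_trace", class(out)))
}

#' Accumulate life years, QALYs and costs over a cohort trace
#'
#' State membership during cycle `k` (the occupancy at the cycle's start)
#' accrues `cycle_length_years` of life, utility-weighted QALYs and the
#' state's per-cycle cost, discounted by `(1 + r)^(-k * cycle_length_years)`.
#' Optionally a half-cycle correction averages the occupancies at the start
#' and end of each cycle. Under the societal perspective cost includes
#' direct medical, household non-medical and drug cost; the government
#' perspective drops the non-medical component. Drug cost accrues in every
#' living state.
#'
#' @param trace A `pah_trace` from [run_cohort()].
#' @param params A `pah_params` object.
#' @param drug Arm whose drug cost applies (defaults to the trace's).
#' @param perspective Override the configured perspective.
#' @return A one-row tibble: `drug`, `start_fc`, life years, QALYs and
#'   total cost, discounted and undiscounted.
#' @export
accumulate_outcomes <- function(trace, params, drug = attr(trace, "drug"),
                                perspective = params$settings$perspective) {
  stopifnot(inherits(trace, "pah_trace"))
  if (is.null(drug) || drug == "none") {
    stop("a drug arm is required to cost the trace", call. = FALSE)
  }
  s <- params$settings
  occ <- as.matrix(trace[, STATES])
  H <- nrow(occ) - 1L
  live <- occ[1:H, 1:4, drop = FALSE]
  if (isTRUE(s$half_cycle_correction)) {
    live <- (live + occ[2:(H + 1), 1:4, drop = FALSE]) / 2
  }
  cl <- s$cycle_length_years
  df <- (1 + s$annual_discount_rate)^(-(0:(H - 1)) * cl)
  util <- fc_values(params, "utilities")
  cost <- state_costs(params, drug, perspective)

  alive <- rowSums(live)
  qaly_cycle <- as.vector(live %*% util) * cl
  cost_cycle <- as.vector(live %*% cost)
  tibble::tibble(
    drug = drug,
    start_fc = attr(trace, "start_fc"),
    perspective = perspective,
    life_years = sum(alive) * cl,
    life_years_disc = sum(alive * cl * df),
    qalys = sum(qaly_cycle),
    qalys_disc = sum(qaly_cycle * df),
    cost = sum(cost_cycle),
    cost_disc = sum(cost_cycle * df)
  )
}

# Run one arm end-to-end at the current parameter values.
run_arm <- function(params, drug, start_fc,
                    horizon_cycles = params$settings$horizon_cycles,
                    perspective = params$settings$perspective) {
  M <- transition_matrix(params, drug)
  trace <- run_cohort(M, start_fc, horizon_cycles)
  accumulate_outcomes(trace, params, drug, perspective)
}

#' Choose the simulation horizon
#'
#' The model is a lifetime model without an age-specific mortality table,
#' so "lifetime" must be a fixed cycle count. Three modes: `fixed` returns
#' `n`; `extinction` returns the first cycle at which the living occupancy
#' falls below `epsilon`; `calibrated` returns the horizon stored in the
#' configuration, chosen once by [calibrate_horizon()].
#'
#' @param params A `pah_params` object.
#' @param mode `"calibrated"`, `"fixed"` or `"extinction"`.
#' @param n Cycle count for `fixed` mode.
#' @param epsilon Living-occupancy threshold for `extinction` mode (> 0).
#' @param drug,start_fc Arm and start state used by `extinction` mode.
#' @return Integer number of cycles.
#' @export
choose_horizon <- function(params, mode = c("calibrated", "fixed", "extinction"),
                           n = NULL, epsilon = 1e-3,
                           drug = "sildenafil", start_fc = 2) {
  mode <- match.arg(mode)
  if (mode == "calibrated") return(as.integer(params$settings$horizon_cycles))
  if (mode == "fixed") {
    stopifnot(!is.null(n), n >= 1)
    return(as.integer(n))
  }
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  M <- transition_matrix(params, drug)
  occ <- numeric(5)
  occ[start_fc] <- 1
  k <- 0L
  while (sum(occ[1:4]) >= epsilon) {
    occ <- as.vector(occ %*% M)
    k <- k + 1L
    if (k > 100000L) stop("cohort did not go extinct within 100000 cycles",
                          call. = FALSE)
  }
  k
}

#' Calibrate the lifetime horizon against reference life-year values
#'
#' Grid search over whole-year horizons, picking the one that minimises the
#' total absolute deviation of the model's discounted and undiscounted life
#' years (both arms, FC II and FC III starts) from reference values. The
#' bundled configuration stores the grid, the reference values and the
#' chosen horizon under `settings$horizon_calibration`.
#'
#' @param params A `pah_params` object.
#' @param grid_years Candidate horizons in years; defaults to the
#'   configured grid.
#' @param reference Data frame with columns `drug`, `start_fc`,
#'   `undiscounted`, `discounted`; defaults to the configured reference.
#' @return A tibble of candidates with their deviations, the minimiser
#'   first flagged by `chosen`.
#' @export
calibrate_horizon <- function(params, grid_years = NULL, reference = NULL) {
  cal <- params$settings$horizon_calibration
  if (is.null(grid_years)) grid_years <- unlist(cal$grid_years)
  if (is.null(reference)) {
    reference <- purrr::list_rbind(purrr::map(cal$reference_life_years,
                                              tibble::as_tibble))
  }
  cl <- params$settings$cycle_length_years
  res <- purrr::map(grid_years, function(yrs) {
    H <- as.integer(round(yrs / cl))
    got <- purrr::pmap(reference, function(drug, start_fc, ...) {
      run_arm(params, drug, start_fc, horizon_cycles = H)
    })
    got <- purrr::list_rbind(got)
    dev <- sum(abs(got$life_years - reference$undiscounted)) +
      sum(abs(got$life_years_disc - reference$discounted))
    tibble::tibble(years = yrs, horizon_cycles = H, deviation = dev)
  })
  res <- dplyr::arrange(purrr::list_rbind(res), .data$deviation)
  res$chosen <- seq_len(nrow(res)) == 1L
  dplyr::arrange(res, .data$years)
}
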