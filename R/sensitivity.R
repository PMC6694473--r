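#' Draw one realization of the parameter set
#'
#' Samples every non-fixed parameter independently from its
#' method-of-moments fitted distribution (beta for probabilities and
#' utilities, gamma for counts and costs, lognormal for relative risks)
#' and returns the parameter set with the `value` column replaced by the
#' draw. Fixed parameters pass through their means. Uses the current RNG
#' state; seed at the caller for reproducibility.
#'
#' @param params A [pah_parameters()] object.
#' @param fitted Optional pre-fitted table from [fit_moments()] (an
#'   optimisation for repeated draws).
#' @return A `pah_params` realization.
#' @export
sample_parameters <- function(params, fitted = NULL) {
  if (is.null(fitted)) fitted <- fit_moments(params$table)
  params$table$value <- draw_moments(fitted)
  params
}

# Evaluate both arms under the current parameter values; returns a two-row
# tibble plus the number of capped matrix rows.
evaluate_arms <- function(params, start_fc, horizon_cycles, perspective) {
  capped <- 0L
  rows <- purrr::map(c("beraprost", "sildenafil"), function(drug) {
    M <- suppressWarnings(transition_matrix(params, drug))
    capped <<- capped + attr(M, "capped")
    trace <- run_cohort(M, start_fc, horizon_cycles)
    accumulate_outcomes(trace, params, drug, perspective)
  })
  list(outcomes = purrr::list_rbind(rows), capped = capped)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of all parameter uncertainty through the model:
#' each draw samples one shared realization of the baseline transition,
#' death, cost and utility parameters (common random numbers across arms)
#' plus arm-specific relative risks, then evaluates both arms from the
#' same starting class. Sampled transition rows whose moves plus death
#' exceed 1 are capped proportionally (death untouched); the number of
#' capped rows is aggregated in the result's `capped_rows` attribute.
#'
#' @param params A [pah_parameters()] object.
#' @param start_fc Starting functional class, 2 or 3.
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param seed Optional integer seed; fixing it makes the whole PSA
#'   reproducible draw-for-draw.
#' @param horizon_cycles Simulation horizon.
#' @return A `pah_psa` tibble with columns `draw`, `drug`, `cost_disc`,
#'   `qalys_disc` and attributes `start_fc`, `wtp`, `seed`, `capped_rows`.
#' @examples
#' \donttest{
#' psa <- run_psa(pah_parameters(), start_fc = 3, n_draws = 200, seed = 1)
#' summary(psa)
#' }
#' @export
run_psa <- function(params, start_fc, n_draws = 1000, seed = NULL,
                    horizon_cycles = params$settings$horizon_cycles) {
  stopifnot(n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  fitted <- fit_moments(params$table)
  capped_total <- 0L
  draws <- purrr::map(seq_len(n_draws), function(i) {
    realization <- sample_parameters(params, fitted)
    ev <- evaluate_arms(realization, start_fc, horizon_cycles,
                        params$settings$perspective)
    capped_total <<- capped_total + ev$capped
    dplyr::mutate(
      dplyr::select(ev$outcomes, "drug", "cost_disc", "qalys_disc"),
      draw = i, .before = 1
    )
  })
  out <- purrr::list_rbind(draws)
  structure(out,
            start_fc = start_fc, wtp = params$settings$wtp_per_qaly,
            seed = seed, n_draws = n_draws, capped_rows = capped_total,
            class = c("pah_psa", class(out)))
}

#' Summarise a PSA: probability each arm is cost-effective
#'
#' @param object A `pah_psa` object.
#' @param wtp Willingness to pay; defaults to the configured threshold.
#' @param ... Unused.
#' @return A tibble with one row per arm: the fraction of draws in which
#'   the arm has the higher net monetary benefit (ties split equally).
#' @export
summary.pah_psa <- function(object, wtp = attr(object, "wtp"), ...) {
  ceac_at(object, wtp)
}

ceac_at <- function(psa, wtp) {
  wide <- tidyr::pivot_wider(psa, id_cols = "draw", names_from = "drug",
                             values_from = c("cost_disc", "qalys_disc"))
  purrr::list_rbind(purrr::map(wtp, function(w) {
    nmb_s <- w * wide$qalys_disc_sildenafil - wide$cost_disc_sildenafil
    nmb_b <- w * wide$qalys_disc_beraprost - wide$cost_disc_beraprost
    p_s <- mean((nmb_s > nmb_b) + 0.5 * (nmb_s == nmb_b))
    tibble::tibble(
      wtp = w, drug = c("sildenafil", "beraprost"),
      probability = c(p_s, 1 - p_s), n_draws = nrow(wide)
    )
  }))
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability that each arm has
#' the higher net monetary benefit across the PSA draws (ties split
#' equally). The two arms' probabilities sum to 1 at every grid point.
#'
#' @param psa A `pah_psa` from [run_psa()].
#' @param wtp_grid Willingness-to-pay grid, USD/QALY (default 0 to 10,000
#'   in steps of 100).
#' @return A `pah_ceac` tibble: `wtp`, `drug`, `probability`, `n_draws`.
#' @export
compute_ceac <- function(psa, wtp_grid = seq(0, 10000, by = 100)) {
  stopifnot(inherits(psa, "pah_psa"))
  if (nrow(psa) == 0) stop("empty PSA draws", call. = FALSE)
  if (any(wtp_grid < 0)) stop("wtp_grid must be nonnegative", call. = FALSE)
  out <- ceac_at(psa, wtp_grid)
  structure(out, start_fc = attr(psa, "start_fc"),
            class = c("pah_ceac", class(out)))
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-computes the base-case ICER with each uncertain parameter set in
#' turn to the low and high end of its range (default mean +/- 1.96 SE,
#' clipped to the parameter's domain: \[0, 1\] for probabilities and
#' utilities, nonnegative for counts, costs and relative risks), all other
#' parameters at their means. Parameters with zero SE have zero swing and
#' are omitted.
#'
#' @param params A [pah_parameters()] object.
#' @param start_fc Starting functional class, 2 or 3.
#' @param ids Parameter ids to vary; default all with positive SE.
#' @param z Half-width of the range in standard errors (default 1.96).
#' @return A `pah_owsa` tibble sorted by decreasing ICER swing, with the
#'   bounds used and the ICER at each bound.
#' @export
one_way_analysis <- function(params, start_fc, ids = NULL, z = 1.96) {
  tab <- params$table
  if (is.null(ids)) ids <- tab$id[tab$se > 0 & tab$family != "fixed"]
  base_icer <- glance(run_base_case(params, start_fc))$icer
  rows <- purrr::map(ids, function(id) {
    i <- match(id, tab$id)
    lo <- tab$mean[i] - z * tab$se[i]
    hi <- tab$mean[i] + z * tab$se[i]
    bounded01 <- tab$group[i] %in% c("transitions", "deaths", "utilities")
    lo_c <- max(lo, 0)
    hi_c <- if (bounded01) min(hi, 1) else hi
    if (lo_c != lo || hi_c != hi) {
      warning(sprintf("range for %s clipped to its domain", id), call. = FALSE)
    }
    icer_at <- function(v) {
      p <- params
      p$table$value[i] <- v
      glance(suppressWarnings(run_base_case(p, start_fc)))$icer
    }
    tibble::tibble(
      id = id, low = lo_c, high = hi_c,
      icer_low = icer_at(lo_c), icer_high = icer_at(hi_c)
    )
  })
  out <- purrr::list_rbind(rows)
  out$swing <- abs(out$icer_high - out$icer_low)
  out <- dplyr::arrange(out, dplyr::desc(.data$swing))
  structure(out, start_fc = start_fc, base_icer = base_icer,
            class = c("pah_owsa", class(out)))
}

#' ICER under the generic and originator sildenafil price
#'
#' The explicit drug-price scenario comparison: the base-case ICER with
#' the sildenafil per-cycle cost rebuilt from the generic and from the
#' originator per-tablet price.
#'
#' @param params A [pah_parameters()] object.
#' @param start_fc Starting functional class, 2 or 3.
#' @return A tibble with one row per scenario and the ratio of the
#'   originator to the generic ICER.
#' @export
price_scenario_analysis <- function(params, start_fc) {
  icers <- purrr::map_dbl(c(generic = "generic", originator = "originator"),
    function(sc) {
      glance(run_base_case(set_price_scenario(params, sc), start_fc))$icer
    })
  tibble::tibble(
    scenario = names(icers), icer = unname(icers),
    ratio_to_generic = unname(icers / icers[["generic"]])
  )
}

#' Threshold price search for originator sildenafil
#'
#' Finds the multiplier on the current sildenafil price (set the originator
#' scenario first via [set_price_scenario()] to ask how far the originator
#' tablet price must fall) at which the base-case ICER equals the
#' willingness-to-pay threshold, by bisection
#' (the ICER is monotone increasing in the drug price, which the search
#' verifies via its bracketing step). The binding constraint is the larger
#' of the FC II and FC III start ICERs, so the reported reduction makes
#' sildenafil cost-effective from either starting class.
#'
#' @param params A [pah_parameters()] object.
#' @param wtp Willingness to pay; defaults to the configured threshold.
#' @param start_fc Starting classes over which the ICER must fall to the
#'   threshold (default both 2 and 3; the maximum binds).
#' @param tol Bisection stops when |ICER - wtp| < `tol` USD/QALY.
#' @return A one-row tibble: `multiplier`, `percent_reduction`, the ICER
#'   at the solution, and `wtp`. If already cost-effective at full price,
#'   multiplier 1 and reduction 0.
#' @export
threshold_price <- function(params, wtp = params$settings$wtp_per_qaly,
                            start_fc = c(2, 3), tol = 1) {
  i_drug <- match("costs.drug_per_cycle.sildenafil", params$table$id)
  full_price <- params$table$value[i_drug]
  icer_at <- function(m) {
    p <- params
    p$table$value[i_drug] <- full_price * m
    max(purrr::map_dbl(start_fc, function(fc) {
      glance(run_base_case(p, fc))$icer
    }))
  }
  hi <- 1
  icer_hi <- icer_at(hi)
  if (icer_hi <= wtp) {
    return(tibble::tibble(multiplier = 1, percent_reduction = 0,
                          icer = icer_hi, wtp = wtp))
  }
  lo <- 0.01
  if (icer_at(lo) >= wtp) {
    stop("no price multiplier in [0.01, 1] reaches the threshold", call. = FALSE)
  }
  repeat {
    mid <- (lo + hi) / 2
    icer_mid <- icer_at(mid)
    if (abs(icer_mid - wtp) < tol) break
    if (icer_mid > wtp) hi <- mid else lo <- mid
    if (hi - lo < 1e-10) break
  }
  tibble::tibble(multiplier = mid, percent_reduction = 100 * (1 - mid),
                 icer = icer_mid, wtp = wtp)
}
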