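#' Base-case cost-effectiveness analysis
#'
#' Runs both treatment arms at the current parameter values from a common
#' starting functional class and computes the incremental cost, incremental
#' discounted QALYs, the incremental cost-effectiveness ratio (ICER) and
#' the net-monetary-benefit difference at the configured willingness-to-pay
#' threshold. Sildenafil is the intervention, beraprost the comparator.
#'
#' Discounted outcomes drive the ICER. When the incremental QALY is zero
#' the ICER is undefined and the result is flagged `"indifferent"`; if the
#' intervention is cheaper and more effective it `"dominates"`.
#'
#' @param params A [pah_parameters()] object.
#' @param start_fc Starting functional class, 2 or 3.
#' @param horizon_cycles Simulation horizon; defaults to the configured
#'   (calibrated) lifetime horizon.
#' @param perspective Override the configured perspective.
#' @return A `pah_cea` object; see [tidy.pah_cea()] and
#'   [glance.pah_cea()].
#' @examples
#' cea <- run_base_case(pah_parameters(), start_fc = 2)
#' glance(cea)
#' @export
run_base_case <- function(params, start_fc,
                          horizon_cycles = params$settings$horizon_cycles,
                          perspective = params$settings$perspective) {
  if (!start_fc %in% 2:3) {
    stop("the model is evaluated from FC II or FC III (start_fc 2 or 3)",
         call. = FALSE)
  }
  arms <- dplyr::bind_rows(
    run_arm(params, "beraprost", start_fc, horizon_cycles, perspective),
    run_arm(params, "sildenafil", start_fc, horizon_cycles, perspective)
  )
  inc_cost <- arms$cost_disc[2] - arms$cost_disc[1]
  inc_qaly <- arms$qalys_disc[2] - arms$qalys_disc[1]
  wtp <- params$settings$wtp_per_qaly
  nmb_diff <- wtp * inc_qaly - inc_cost

  status <- if (inc_qaly == 0 && inc_cost == 0) {
    "indifferent"
  } else if (inc_qaly > 0 && inc_cost <= 0) {
    "dominates"
  } else if (inc_qaly <= 0 && inc_cost >= 0) {
    "dominated"
  } else {
    "trade-off"
  }
  icer <- if (inc_qaly != 0) inc_cost / inc_qaly else NA_real_
  cost_effective <- status == "dominates" ||
    (status == "trade-off" && inc_qaly > 0 && icer <= wtp)

  structure(
    list(
      start_fc = start_fc,
      outcomes = arms,
      incremental_cost = inc_cost,
      incremental_qaly = inc_qaly,
      icer = icer,
      wtp = wtp,
      nmb_difference = nmb_diff,
      status = status,
      cost_effective = cost_effective
    ),
    class = "pah_cea"
  )
}

#' Net monetary benefit
#'
#' `wtp x discounted QALYs - discounted cost` for a per-arm outcome row
#' (vectorised over rows). The NMB difference between two arms is positive
#' exactly when the first arm is preferred at that willingness to pay.
#'
#' @param outcome A tibble as produced by [accumulate_outcomes()].
#' @param wtp Willingness to pay per QALY (>= 0).
#' @return Numeric vector of NMB values, USD.
#' @export
net_monetary_benefit <- function(outcome, wtp) {
  stopifnot(wtp >= 0)
  wtp * outcome$qalys_disc - outcome$cost_disc
}

#' @export
print.pah_cea <- function(x, ...) {
  cat(sprintf("<pah_cea> sildenafil vs beraprost, FC %s start\n",
              c("I", "II", "III", "IV")[x$start_fc]))
  print(x$outcomes)
  cat(sprintf("incremental cost  %10.2f USD\n", x$incremental_cost))
  cat(sprintf("incremental QALYs %10.4f\n", x$incremental_qaly))
  if (is.na(x$icer)) {
    cat("ICER undefined:", x$status, "\n")
  } else {
    cat(sprintf("ICER              %10.2f USD/QALY (%s)\n", x$icer, x$status))
  }
  cat(sprintf("NMB difference at WTP %s: %.2f USD -> %scost-effective\n",
              format(x$wtp), x$nmb_difference,
              if (x$cost_effective) "" else "not "))
  invisible(x)
}

#' Tidy per-arm outcomes of a base-case analysis
#'
#' @param x A `pah_cea` object.
#' @param ... Unused.
#' @return The two-row per-arm outcome tibble.
#' @method tidy pah_cea
#' @export
tidy.pah_cea <- function(x, ...) x$outcomes

#' One-row summary of a base-case analysis
#'
#' @param x A `pah_cea` object.
#' @param ... Unused.
#' @return A one-row tibble with the incremental quantities, ICER, NMB
#'   difference and cost-effectiveness flag.
#' @method glance pah_cea
#' @export
glance.pah_cea <- function(x, ...) {
  tibble::tibble(
    start_fc = x$start_fc,
    incremental_cost = x$incremental_cost,
    incremental_qaly = x$incremental_qaly,
    icer = x$icer,
    wtp = x$wtp,
    nmb_difference = x$nmb_difference,
    status = x$status,
    cost_effective = x$cost_effective
  )
}
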