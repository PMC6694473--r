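#' Fit a beta distribution by the method of moments
#'
#' Recovers the `(shape1, shape2)` parameters of a beta distribution with
#' the given mean and standard error. Used to turn the mean/SE pairs of
#' probability and utility parameters into sampling distributions for
#' probabilistic sensitivity analysis.
#'
#' The moment equations give `k = mean (1 - mean) / se^2 - 1`,
#' `shape1 = mean k`, `shape2 = (1 - mean) k`. The moments are only
#' feasible when `se^2 < mean (1 - mean)`.
#'
#' @param mean Mean of the distribution, in (0, 1).
#' @param se Standard error (standard deviation of the parameter), > 0.
#' @param name Parameter name used in error messages.
#' @return A named list with elements `shape1` and `shape2`.
#' @examples
#' fit_beta_moments(0.74, 0.04)   # utility of functional class I
#' @export
fit_beta_moments <- function(mean, se, name = "parameter") {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop(sprintf("infeasible moments for '%s': beta requires 0 < mean < 1 (got %g)",
                 name, mean), call. = FALSE)
  }
  if (!is.finite(se) || se <= 0 || se^2 >= mean * (1 - mean)) {
    stop(sprintf(
      "infeasible moments for '%s': beta requires 0 < se^2 < mean(1-mean) (mean=%g, se=%g)",
      name, mean, se), call. = FALSE)
  }
  k <- mean * (1 - mean) / se^2 - 1
  list(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Fit a gamma distribution by the method of moments
#'
#' Recovers `(shape, scale)` for a gamma distribution with the given mean
#' and standard error; used for nonnegative quantities (counts per cycle,
#' unit costs, non-medical costs).
#'
#' @inheritParams fit_beta_moments
#' @return A named list with elements `shape` and `scale`.
#' @examples
#' fit_gamma_moments(808, 143)    # cost per hospital admission
#' @export
fit_gamma_moments <- function(mean, se, name = "parameter") {
  if (!is.finite(mean) || mean <= 0 || !is.finite(se) || se <= 0) {
    stop(sprintf("infeasible moments for '%s': gamma requires mean > 0 and se > 0",
                 name), call. = FALSE)
  }
  list(shape = mean^2 / se^2, scale = se^2 / mean)
}

#' Fit a lognormal distribution by the method of moments
#'
#' Recovers `(meanlog, sdlog)` for a lognormal distribution with the given
#' arithmetic mean and standard error. Used for ratio parameters (relative
#' risks), for which a beta law cannot hold means above 1:
#' `sdlog^2 = log(1 + se^2/mean^2)`, `meanlog = log(mean) - sdlog^2/2`.
#'
#' @inheritParams fit_beta_moments
#' @return A named list with elements `meanlog` and `sdlog`.
#' @examples
#' fit_lnorm_moments(4.23, 2.043) # RR of functional-class improvement
#' @export
fit_lnorm_moments <- function(mean, se, name = "parameter") {
  if (!is.finite(mean) || mean <= 0 || !is.finite(se) || se <= 0) {
    stop(sprintf("infeasible moments for '%s': lognormal requires mean > 0 and se > 0",
                 name), call. = FALSE)
  }
  s2 <- log(1 + se^2 / mean^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Fit sampling distributions for a table of parameters
#'
#' Vectorised wrapper applying the per-family moment fit to each row of a
#' parameter table (as held in a [pah_params] object or produced by
#' [estimate_moments()]). Rows with family `"fixed"` get `NA` shape
#' parameters and are never sampled.
#'
#' @param data A data frame with columns `mean`, `se`, `family` and
#'   (optionally) `id` for error messages.
#' @return The input as a tibble with list-column `fit` holding the fitted
#'   parameter list per row.
#' @export
fit_moments <- function(data) {
  stopifnot(all(c("mean", "se", "family") %in% names(data)))
  nm <- if ("id" %in% names(data)) data$id else paste0("row", seq_len(nrow(data)))
  data <- tibble::as_tibble(data)
  data$fit <- purrr::pmap(
    list(data$mean, data$se, data$family, nm),
    function(m, s, fam, id) {
      if (fam != "fixed" && s == 0) return(NULL)  # degenerate: point mass at the mean
      switch(fam,
        fixed     = NULL,
        beta      = fit_beta_moments(m, s, id),
        gamma     = fit_gamma_moments(m, s, id),
        lognormal = fit_lnorm_moments(m, s, id),
        stop(sprintf("unknown distribution family '%s' for '%s'", fam, id),
             call. = FALSE)
      )
    }
  )
  data
}

# One random draw per row of a fitted parameter table. Fixed rows pass
# through their mean unchanged.
draw_moments <- function(fitted) {
  purrr::pmap_dbl(
    list(fitted$mean, fitted$family, fitted$fit),
    function(m, fam, fit) {
      if (is.null(fit)) return(m)
      switch(fam,
        fixed     = m,
        beta      = stats::rbeta(1, fit$shape1, fit$shape2),
        gamma     = stats::rgamma(1, shape = fit$shape, scale = fit$scale),
        lognormal = stats::rlnorm(1, fit$meanlog, fit$sdlog)
      )
    }
  )
}
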