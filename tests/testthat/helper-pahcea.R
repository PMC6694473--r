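# Shared fixtures and independent oracles for the test suite.

default_params <- pah_parameters()

# A parameter set in which the cohort never moves and never dies: patients
# stay in their starting class forever. Useful for hand-computable sums.
frozen_params <- function(params = default_params) {
  ids <- c(paste0("transitions.",
                  c("fc1_to_fc2", "fc2_to_fc1", "fc2_to_fc3",
                    "fc3_to_fc2", "fc3_to_fc4", "fc4_to_fc3")),
           paste0("deaths.fc", 1:4))
  idx <- match(ids, params$table$id)
  params$table$mean[idx] <- 0
  params$table$value[idx] <- 0
  params$table$se[idx] <- 0
  params
}

# Make the two arms literally identical (shared relative risks and drug
# cost), so every incremental quantity must vanish.
identical_arms_params <- function(params = default_params, rr_w = 0.5,
                                  rr_i = 1.2) {
  for (drug in c("sildenafil", "beraprost")) {
    iw <- match(paste0("effects.", drug, ".rr_worsening"), params$table$id)
    ii <- match(paste0("effects.", drug, ".rr_improvement"), params$table$id)
    params$table$value[c(iw, ii)] <- c(rr_w, rr_i)
    params$table$mean[c(iw, ii)] <- c(rr_w, rr_i)
    ic <- match(paste0("costs.drug_per_cycle.", drug), params$table$id)
    params$table$value[ic] <- 90
    params$table$mean[ic] <- 90
  }
  params
}

# Set every parameter's SE to zero (all sampling distributions degenerate).
zero_se_params <- function(params = default_params) {
  params$table$se[] <- 0
  params
}

# Independent brute-force oracle: enumerate every state path of length
# `horizon` under transition matrix M, weight by its path probability, and
# accumulate life years, QALYs and cost with cycle-start accrual and
# annual discounting. Deliberately shares no code with the cohort engine.
enumerate_outcomes <- function(M, start_fc, horizon, util, state_cost,
                               discount_rate, cycle_len) {
  acc <- c(ly = 0, ly_disc = 0, qaly = 0, qaly_disc = 0,
           cost = 0, cost_disc = 0)
  recurse <- function(state, k, prob, a) {
    if (prob == 0) return()
    if (state <= 4) {  # reward for occupying a living state during cycle k
      df <- (1 + discount_rate)^(-k * cycle_len)
      a["ly"] <- a["ly"] + cycle_len
      a["ly_disc"] <- a["ly_disc"] + cycle_len * df
      a["qaly"] <- a["qaly"] + cycle_len * util[state]
      a["qaly_disc"] <- a["qaly_disc"] + cycle_len * util[state] * df
      a["cost"] <- a["cost"] + state_cost[state]
      a["cost_disc"] <- a["cost_disc"] + state_cost[state] * df
    }
    if (k == horizon - 1) {
      acc <<- acc + prob * a
      return()
    }
    for (nxt in 1:5) recurse(nxt, k + 1, prob * M[state, nxt], a)
  }
  recurse(start_fc, 0, 1, acc)
  acc
}
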