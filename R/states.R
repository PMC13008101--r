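#' Health-state space of the MASLD Markov model
#'
#' Thirteen states: no MASLD, fibrosis stages F0-F3, compensated cirrhosis
#' (F4_CC), decompensated cirrhosis (DC), hepatocellular carcinoma (HCC),
#' liver transplantation (LT), post-transplant (POST_LT), and three absorbing
#' death states split by attributed cause (cardiovascular, liver-related,
#' other). The three death states are absorbing; LT is a one-year tunnel state
#' whose survivors all move to POST_LT.
#'
#' @return Character vector of the 13 state labels, in model order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("NO_MASLD", "F0", "F1", "F2", "F3", "F4_CC", "DC", "HCC",
    "LT", "POST_LT", "D_CVD", "D_LIVER", "D_OTHER")
}

# index helpers used throughout the engine
.states <- function() health_states()
.n_states <- function() 13L
.death_states <- function() c("D_CVD", "D_LIVER", "D_OTHER")
.alive_states <- function() setdiff(health_states(), .death_states())
# states in which a lifestyle-programme participant accrues the annual
# programme cost (pre-decompensation disease course)
.lifestyle_states <- function() c("NO_MASLD", "F0", "F1", "F2", "F3", "F4_CC")
.sigfib_states <- function() c("F2", "F3", "F4_CC")

# map the 7 cost/utility groups onto the 13 states
.state_group <- function() {
  c(NO_MASLD = "no_masld", F0 = "f0_f3", F1 = "f0_f3", F2 = "f0_f3",
    F3 = "f0_f3", F4_CC = "f4", DC = "dc", HCC = "hcc", LT = "lt",
    POST_LT = "post_lt", D_CVD = "death", D_LIVER = "death",
    D_OTHER = "death")
}

# expand a named per-group vector (no_masld, f0_f3, f4, dc, hcc, lt, post_lt)
# to a full 13-state vector with 0 in the death states
.expand_group_vector <- function(by_group) {
  grp <- .state_group()
  out <- numeric(.n_states())
  names(out) <- .states()
  alive <- grp != "death"
  out[alive] <- unname(by_group[grp[alive]])
  out
}
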