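# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Full decision-tree enumeration: walk every path
# (screen? x true condition x step-1 result x attend-TE? x TE result),
# multiply branch probabilities, and pool leaf masses by outcome label.
tree_enumeration <- function(pi, se1 = NULL, sp1 = NULL, se_te, sp_te,
                             u1 = NULL, u2 = NULL, u_te = NULL) {
  fr <- c(unscreened = 0, step1_negative = 0, referred_not_attending = 0,
          te_negative = 0, treated_true = 0, treated_false = 0)
  add <- function(label, p) fr[label] <<- fr[label] + p
  for (sick in c(TRUE, FALSE)) {
    p_cond <- if (sick) pi else 1 - pi
    if (!is.null(se1)) { # stepwise strategy
      add("unscreened", p_cond * (1 - u1))
      for (pos1 in c(TRUE, FALSE)) {
        p1 <- if (sick) (if (pos1) se1 else 1 - se1)
              else (if (pos1) 1 - sp1 else sp1)
        base <- p_cond * u1 * p1
        if (!pos1) { add("step1_negative", base); next }
        add("referred_not_attending", base * (1 - u2))
        for (pos2 in c(TRUE, FALSE)) {
          p2 <- if (sick) (if (pos2) se_te else 1 - se_te)
                else (if (pos2) 1 - sp_te else sp_te)
          leaf <- if (!pos2) "te_negative"
                  else if (sick) "treated_true" else "treated_false"
          add(leaf, base * u2 * p2)
        }
      }
    } else { # TE alone
      add("unscreened", p_cond * (1 - u_te))
      for (pos in c(TRUE, FALSE)) {
        p2 <- if (sick) (if (pos) se_te else 1 - se_te)
              else (if (pos) 1 - sp_te else sp_te)
        leaf <- if (!pos) "te_negative"
                else if (sick) "treated_true" else "treated_false"
        add(leaf, p_cond * u_te * p2)
      }
    }
  }
  fr
}

# run the enumeration for a configured strategy id
tree_oracle <- function(strategy_id, params, age = params$start_age) {
  pi <- fibscreen:::.sigfib_prev_at(params, age)
  s <- params$strategies[[strategy_id]]
  te <- params$tests$te
  if (!isTRUE(s$screen))
    return(c(unscreened = 1, step1_negative = 0, referred_not_attending = 0,
             te_negative = 0, treated_true = 0, treated_false = 0))
  if (!is.null(s$stage1)) {
    t1 <- params$tests[[s$stage1]]
    tree_enumeration(pi, t1$sens, t1$spec, te$sens, te$spec,
                     u1 = s$uptake_stage1, u2 = s$uptake_te)
  } else {
    tree_enumeration(pi, se_te = te$sens, sp_te = te$spec, u_te = s$uptake_te)
  }
}

# Brute-force cost-effectiveness frontier: greedy lower-hull construction on
# (qaly, cost). Start at the cheapest strategy, then repeatedly move to the
# more-effective strategy reachable at the smallest incremental slope.
brute_frontier <- function(df) {
  ids <- character(0); slopes <- numeric(0)
  cur <- which(df$cost == min(df$cost))
  if (length(cur) > 1) cur <- cur[which.max(df$qaly[cur])]
  ids <- df$strategy[cur]
  repeat {
    better <- which(df$qaly > df$qaly[cur])
    if (!length(better)) break
    sl <- (df$cost[better] - df$cost[cur]) / (df$qaly[better] - df$qaly[cur])
    k <- better[which.min(sl)]
    slopes <- c(slopes, min(sl))
    ids <- c(ids, df$strategy[k])
    cur <- k
  }
  list(ids = ids, slopes = slopes)
}

# strategy picked by the "most effective frontier strategy whose incremental
# ICER does not exceed wtp" rule
icer_rule_choice <- function(front, wtp) {
  ok <- c(TRUE, front$slopes <= wtp)
  front$ids[max(which(ok))]
}

# small deterministic parameter tweak helper
with_param <- function(params, path, value) fibscreen:::.set_path(params, path, value)
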