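#' Utility weight of a terminal health state
#'
#' `resolved_no_vats` maps to the resolved-pneumothorax utility (base
#' 0.92); `resolved_post_vats` to the invasive-lung-procedure utility
#' (base 0.83, a long-term dyspnoea surrogate).
#'
#' @param state A terminal-state label, see [terminal_states()].
#' @param utilities The `utilities` element of a [parameter_set()] (or a
#'   full `psp_params` object).
#' @return The utility weight in `[0, 1]`.
#' @export
terminal_state_utility <- function(state, utilities) {
  if (inherits(utilities, "psp_params")) utilities <- utilities$utilities
  key <- switch(state,
                resolved_no_vats = "resolved_psp",
                resolved_post_vats = "invasive_lung_procedure",
                stop("unknown terminal state: ", state, call. = FALSE))
  utilities[[key]]$base
}

#' Discounted quality-adjusted life-years for a constant utility
#'
#' Present value, discounted annually in advance, of living
#' `horizon_years` years at utility weight `u`:
#' `u * sum_{t=0}^{horizon-1} (1+r)^-t`.
#'
#' @param u Utility weight in `[0, 1]`.
#' @param horizon_years Whole years lived (>= 0).
#' @param r Annual discount rate (>= 0).
#' @return Discounted QALYs.
#' @examples
#' discounted_qalys(1, 53, 0)     # 53
#' discounted_qalys(1, 53, 0.03)  # ~27.2
#' @export
discounted_qalys <- function(u, horizon_years, r) {
  stopifnot(length(u) == 1, length(horizon_years) == 1, length(r) == 1)
  if (u < 0 || u > 1) stop("utility must lie in [0, 1]", call. = FALSE)
  if (horizon_years < 0) stop("domain error: negative horizon", call. = FALSE)
  if (r < 0) stop("domain error: negative discount rate", call. = FALSE)
  if (horizon_years == 0) return(0)
  u * sum((1 + r)^-(0:(horizon_years - 1)))
}

#' Lifetime discounted effectiveness of a terminal-state distribution
#'
#' The horizon is the base-case patient's remaining lifetime
#' (`life_expectancy - age`, 53 years in the base case). Under the
#' default `"lifetime"` utility mode each terminal state's utility weight
#' applies for the whole remaining lifetime; under `"first_year"` it
#' applies in the first year only, with the baseline utility thereafter.
#'
#' @param dist Named probability vector over [terminal_states()]
#'   (sums to 1).
#' @param params A [parameter_set()].
#' @param utility_mode `"lifetime"` (default) or `"first_year"`.
#' @return Expected discounted QALYs.
#' @export
lifetime_effectiveness <- function(dist, params,
                                   utility_mode = c("lifetime", "first_year")) {
  stopifnot(inherits(params, "psp_params"))
  utility_mode <- match.arg(utility_mode)
  if (abs(sum(dist) - 1) > 1e-9)
    stop("terminal-state distribution must sum to 1", call. = FALSE)
  horizon <- params$life_expectancy$base - params$age$base
  if (horizon <= 0) stop("domain error: non-positive horizon", call. = FALSE)
  r <- params$discount_rate$base
  per_state <- vapply(names(dist), function(s) {
    u <- terminal_state_utility(s, params)
    if (utility_mode == "lifetime") {
      discounted_qalys(u, horizon, r)
    } else {
      u0 <- params$utilities$baseline$base
      discounted_qalys(u, 1, r) +
        (discounted_qalys(u0, horizon, r) - discounted_qalys(u0, 1, r))
    }
  }, numeric(1))
  sum(dist * per_state)
}

#' Net monetary benefit
#'
#' `nmb = wtp * effectiveness - cost`: the dollar value of the health
#' gained at the willingness-to-pay threshold, minus what it cost.
#' Higher is better.
#'
#' @param effectiveness QALYs.
#' @param cost USD.
#' @param wtp Willingness-to-pay threshold, USD per QALY (>= 0).
#' @return USD.
#' @export
nmb <- function(effectiveness, cost, wtp) {
  if (any(wtp < 0)) stop("domain error: negative WTP", call. = FALSE)
  wtp * effectiveness - cost
}

#' Per-strategy cost, effectiveness and net monetary benefit
#'
#' Rolls the tree back and converts each strategy's expected cost and
#' terminal-state distribution into lifetime discounted QALYs and NMB at
#' the parameter set's willingness-to-pay threshold. All modelled costs
#' fall at the index episode (t = 0) and are therefore undiscounted.
#'
#' @param tree A `psp_tree` from [build_psp_tree()] (or `NULL` to build
#'   one from `params`).
#' @param params A [parameter_set()].
#' @param utility_mode See [lifetime_effectiveness()].
#' @param wtp Optional override of the configured threshold.
#' @return A data.frame of class `psp_outcomes`: `strategy`,
#'   `expected_cost`, `effectiveness`, `nmb`, with the WTP as attribute
#'   `"wtp"`.
#' @examples
#' outcomes <- strategy_outcomes(params = base_case_parameters())
#' rank_by_nmb(outcomes)
#' @export
strategy_outcomes <- function(tree = NULL, params,
                              utility_mode = c("lifetime", "first_year"),
                              wtp = NULL) {
  stopifnot(inherits(params, "psp_params"))
  utility_mode <- match.arg(utility_mode)
  if (is.null(tree)) tree <- build_psp_tree(params)
  if (is.null(wtp)) wtp <- params$wtp
  rb <- rollback(tree)
  states <- terminal_states()
  eff <- vapply(seq_len(nrow(rb)), function(i) {
    dist <- stats::setNames(as.numeric(rb[i, paste0("p_", states)]), states)
    lifetime_effectiveness(dist, params, utility_mode)
  }, numeric(1))
  out <- data.frame(strategy = rb$strategy,
                    expected_cost = rb$expected_cost,
                    effectiveness = eff,
                    nmb = nmb(eff, rb$expected_cost, wtp),
                    stringsAsFactors = FALSE)
  attr(out, "wtp") <- wtp
  class(out) <- c("psp_outcomes", "data.frame")
  out
}

#' Rank strategies by net monetary benefit
#'
#' Descending NMB; exact ties go to the less invasive strategy
#' (observation, aspiration, valve, suction).
#'
#' @param outcomes A `psp_outcomes` data.frame (needs `strategy` and
#'   `nmb` columns).
#' @return Character vector of strategy labels, best first.
#' @export
rank_by_nmb <- function(outcomes) {
  if (NROW(outcomes) == 0) stop("domain error: no outcomes", call. = FALSE)
  invasiveness <- match(outcomes$strategy, psp_strategies())
  outcomes$strategy[order(-outcomes$nmb, invasiveness)]
}

#' Incremental cost-effectiveness analysis against a reference strategy
#'
#' For each strategy, the cost, effectiveness and NMB differences versus
#' the reference, plus the ICER (incremental cost per QALY gained). A
#' strategy that costs more and is no more effective than the reference
#' is flagged dominated. When the effectiveness difference is zero the
#' ICER is undefined (`NA`) and never computed by division.
#'
#' @param outcomes A `psp_outcomes` data.frame.
#' @param reference Strategy label to compare against (default: first
#'   of [rank_by_nmb()]).
#' @return A data.frame: `strategy`, `delta_cost`, `delta_effectiveness`,
#'   `icer`, `dominated`, `delta_nmb`.
#' @export
incremental_analysis <- function(outcomes, reference = NULL) {
  if (NROW(outcomes) == 0) stop("domain error: no outcomes", call. = FALSE)
  if (is.null(reference)) reference <- rank_by_nmb(outcomes)[1]
  i <- match(reference, outcomes$strategy)
  if (is.na(i))
    stop("reference strategy not among outcomes: ", reference,
         call. = FALSE)
  dc <- outcomes$expected_cost - outcomes$expected_cost[i]
  de <- outcomes$effectiveness - outcomes$effectiveness[i]
  icer <- ifelse(de != 0, dc / de, NA_real_)
  data.frame(strategy = outcomes$strategy,
             reference = reference,
             delta_cost = dc,
             delta_effectiveness = de,
             icer = icer,
             dominated = dc > 0 & de <= 0,
             delta_nmb = outcomes$nmb - outcomes$nmb[i],
             stringsAsFactors = FALSE)
}

#' @export
print.psp_outcomes <- function(x, ...) {
  cat("<psp_outcomes> WTP $", format(attr(x, "wtp"), big.mark = ","),
      "/QALY\n", sep = "")
  y <- data.frame(strategy = x$strategy,
                  cost = round(x$expected_cost),
                  effectiveness = round(x$effectiveness, 2),
                  nmb = round(x$nmb))
  print.data.frame(y[order(-x$nmb), ], row.names = FALSE)
  invisible(x)
}
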