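#' Distribution specifications for the probabilistic sensitivity analysis
#'
#' Each ranged parameter gets a sampling distribution moment-matched to
#' its base value and sensitivity range: the mean is the base value and
#' the `(low, high)` range is treated as a central 95% interval, i.e.
#' `sd = (high - low) / (2 * 1.96)`. Probabilities and utilities use a
#' beta distribution (support `[0, 1]`), costs a gamma distribution
#' (support `>= 0`). Where moment matching is infeasible (e.g. a mean on
#' the boundary, as for the baseline utility of 1) the parameter falls
#' back to uniform on `(low, high)`. Degenerate ranges (`low == high`) are
#' fixed. Settings (discount rate, age, life expectancy) are held fixed
#' by default: they are scenario choices, not sampled epistemic
#' uncertainty.
#'
#' @param params A [parameter_set()].
#' @param settings Family for the settings block: `"fixed"` (default) or
#'   `"uniform"`.
#' @return A data.frame of class `psp_dist_specs`: `parameter`, `group`,
#'   `family`, `base`, `low`, `high`, `par1`, `par2` (shape1/shape2 for
#'   beta, shape/rate for gamma, min/max for uniform).
#' @export
psa_distributions <- function(params, settings = c("fixed", "uniform")) {
  stopifnot(inherits(params, "psp_params"))
  settings <- match.arg(settings)
  tab <- parameter_table(params)
  fam <- character(nrow(tab)); p1 <- p2 <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    fit <- fit_distribution(row$base, row$low, row$high, row$group, settings)
    fam[i] <- fit$family; p1[i] <- fit$par1; p2[i] <- fit$par2
  }
  out <- cbind(tab, data.frame(family = fam, par1 = p1, par2 = p2,
                               stringsAsFactors = FALSE))
  class(out) <- c("psp_dist_specs", "data.frame")
  out
}

fit_distribution <- function(base, low, high, group, settings_family) {
  if (low == high)
    return(list(family = "fixed", par1 = base, par2 = base))
  if (group == "setting") {
    if (settings_family == "fixed")
      return(list(family = "fixed", par1 = base, par2 = base))
    return(list(family = "uniform", par1 = low, par2 = high))
  }
  s <- (high - low) / (2 * stats::qnorm(0.975))
  v <- s^2
  if (group %in% c("probability", "utility")) {
    # beta by mean/variance; infeasible when the variance exceeds the
    # Bernoulli bound or the mean sits on the boundary
    if (base > 0 && base < 1 && v < base * (1 - base)) {
      k <- base * (1 - base) / v - 1
      return(list(family = "beta", par1 = base * k, par2 = (1 - base) * k))
    }
    return(list(family = "uniform", par1 = low, par2 = high))
  }
  if (group == "cost") {
    if (base > 0)
      return(list(family = "gamma", par1 = base^2 / v, par2 = base / v))
    return(list(family = "uniform", par1 = low, par2 = high))
  }
  stop("specification error: unknown parameter group '", group, "'",
       call. = FALSE)
}

#' Draw joint parameter realizations for the PSA
#'
#' Parameters are sampled independently, each from its
#' [psa_distributions()] specification. Draws are reproducible: the same
#' seed gives bit-identical output.
#'
#' @param params A [parameter_set()].
#' @param specs Distribution specs (default [psa_distributions()]).
#' @param n Number of draws (>= 1).
#' @param seed Integer seed for the draw stream.
#' @return A data.frame with `n` rows and one column per parameter.
#' @export
sample_parameters <- function(params, specs = psa_distributions(params),
                              n, seed = 1L) {
  stopifnot(inherits(params, "psp_params"))
  if (!is.numeric(n) || n < 1) stop("domain error: n must be >= 1",
                                    call. = FALSE)
  n <- as.integer(n)
  with_local_seed(seed, {
    draws <- lapply(seq_len(nrow(specs)), function(i) {
      sp <- specs[i, ]
      switch(sp$family,
             fixed = rep(sp$base, n),
             beta = stats::rbeta(n, sp$par1, sp$par2),
             gamma = stats::rgamma(n, shape = sp$par1, rate = sp$par2),
             uniform = stats::runif(n, sp$par1, sp$par2),
             stop("specification error: unknown family '", sp$family, "'",
                  call. = FALSE))
    })
    names(draws) <- specs$parameter
    as.data.frame(draws, optional = TRUE)
  })
}

# apply one row of sampled parameter values onto a parameter set
realize_parameters <- function(params, draw) {
  for (nm in names(draw))
    params <- set_parameter(params, nm, as.numeric(draw[[nm]]))
  params
}

#' One-way deterministic sensitivity analysis for a single parameter
#'
#' Rebuilds and re-evaluates the full model with the parameter at its
#' low and at its high value, all other parameters at base, and reports
#' the outcome metric at each end. The default metric is the *frontier*
#' net monetary benefit — the NMB of the base-case optimal strategy minus
#' the best NMB among the other strategies — i.e. how strongly the
#' parameter moves the decision itself. `metric = "strategy"` instead
#' reports a single strategy's NMB (default: the base-case optimal one).
#'
#' @param param Parameter name (must have a non-degenerate range).
#' @param params A [parameter_set()].
#' @param structure Structural options, see [psp_structure()].
#' @param utility_mode See [lifetime_effectiveness()].
#' @param metric `"frontier"` (default) or `"strategy"`.
#' @param strategy Strategy whose NMB to track when
#'   `metric = "strategy"`; default is the base-case optimal strategy.
#' @return A one-row data.frame: `parameter`, `low`, `high`,
#'   `nmb_at_low`, `nmb_at_high`, `bar_width`.
#' @export
one_way_dsa <- function(param, params, structure = psp_structure(),
                        utility_mode = "lifetime",
                        metric = c("frontier", "strategy"),
                        strategy = NULL) {
  stopifnot(inherits(params, "psp_params"))
  metric <- match.arg(metric)
  tab <- parameter_table(params)
  row <- tab[tab$parameter == param, ]
  if (nrow(row) == 0) stop("unknown parameter: ", param, call. = FALSE)
  if (row$low > row$high)
    stop("domain error: parameter '", param, "' has no valid range",
         call. = FALSE)
  base_out <- strategy_outcomes(build_psp_tree(params, structure), params,
                                utility_mode)
  optimal <- rank_by_nmb(base_out)[1]
  if (is.null(strategy)) strategy <- optimal
  eval_at <- function(value) {
    p <- set_parameter(params, param, value)
    out <- strategy_outcomes(build_psp_tree(p, structure), p, utility_mode)
    if (metric == "frontier") {
      others <- out$nmb[out$strategy != optimal]
      out$nmb[out$strategy == optimal] - max(others)
    } else {
      out$nmb[out$strategy == strategy]
    }
  }
  lo <- eval_at(row$low); hi <- eval_at(row$high)
  data.frame(parameter = param, low = row$low, high = row$high,
             nmb_at_low = lo, nmb_at_high = hi,
             bar_width = abs(hi - lo), stringsAsFactors = FALSE)
}

#' Tornado analysis over every ranged parameter
#'
#' Runs [one_way_dsa()] for each parameter whose sensitivity range is
#' non-degenerate and sorts the results by decreasing bar width — the
#' classic tornado ordering, widest (most influential) bar first.
#'
#' @inheritParams one_way_dsa
#' @return A data.frame of class `psp_tornado`, one row per ranged
#'   parameter, sorted by `bar_width` descending.
#' @export
tornado_analysis <- function(params, structure = psp_structure(),
                             utility_mode = "lifetime",
                             metric = c("frontier", "strategy"),
                             strategy = NULL) {
  metric <- match.arg(metric)
  ranged <- parameter_table(params, ranged_only = TRUE)$parameter
  rows <- lapply(ranged, one_way_dsa, params = params,
                 structure = structure, utility_mode = utility_mode,
                 metric = metric, strategy = strategy)
  out <- do.call(rbind, rows)
  out <- out[order(-out$bar_width, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("psp_tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Draws `n` joint parameter realizations, rebuilds and rolls back the
#' decision tree for each, and records per-draw cost, effectiveness and
#' NMB for every strategy. The summary reports, per strategy, the
#' fraction of draws in which it attains the maximal NMB (ties to the
#' less invasive strategy) and in which it attains the minimal NMB.
#'
#' @param params A [parameter_set()].
#' @param specs Distribution specs (default [psa_distributions()]).
#' @param n Number of Monte Carlo draws (default 5000).
#' @param seed Integer seed.
#' @param structure Structural options.
#' @param utility_mode See [lifetime_effectiveness()].
#' @return An object of class `psp_psa` with elements `draws` (parameter
#'   realizations), `samples` (long data.frame: `draw`, `strategy`,
#'   `cost`, `effectiveness`, `nmb`), `summary`, `wtp`, `n`, `seed`.
#' @export
run_psa <- function(params, specs = psa_distributions(params), n = 5000,
                    seed = 1L, structure = psp_structure(),
                    utility_mode = "lifetime") {
  stopifnot(inherits(params, "psp_params"))
  draws <- sample_parameters(params, specs, n, seed)
  strategies <- psp_strategies()
  k <- length(strategies)
  cost <- eff <- matrix(NA_real_, n, k, dimnames = list(NULL, strategies))
  for (i in seq_len(n)) {
    p_i <- realize_parameters(params, draws[i, , drop = FALSE])
    out <- strategy_outcomes(build_psp_tree(p_i, structure), p_i,
                             utility_mode)
    cost[i, out$strategy] <- out$expected_cost
    eff[i, out$strategy] <- out$effectiveness
  }
  nmb_mat <- params$wtp * eff - cost
  samples <- data.frame(
    draw = rep(seq_len(n), times = k),
    strategy = rep(strategies, each = n),
    cost = as.vector(cost),
    effectiveness = as.vector(eff),
    nmb = as.vector(nmb_mat),
    stringsAsFactors = FALSE)
  res <- structure(list(draws = draws, samples = samples,
                        wtp = params$wtp, n = n, seed = seed,
                        strategies = strategies),
                   class = "psp_psa")
  res$summary <- psa_summary(res)
  res
}

# per-strategy win/loss fractions and outcome moments
psa_summary <- function(psa) {
  wide <- psa_wide(psa)
  best <- apply(wide$nmb, 1, which_best, decreasing = TRUE)
  worst <- apply(wide$nmb, 1, which_best, decreasing = FALSE)
  strategies <- psa$strategies
  data.frame(
    strategy = strategies,
    p_optimal = tabulate(best, length(strategies)) / psa$n,
    p_least_effective = tabulate(worst, length(strategies)) / psa$n,
    mean_cost = colMeans(wide$cost),
    mean_effectiveness = colMeans(wide$effectiveness),
    mean_nmb = colMeans(wide$nmb),
    row.names = NULL, stringsAsFactors = FALSE)
}

# ties resolved toward the first (least invasive) column
which_best <- function(x, decreasing = TRUE) {
  if (decreasing) which(x == max(x))[1] else which(x == min(x))[1]
}

psa_wide <- function(psa) {
  n <- psa$n; strategies <- psa$strategies
  grab <- function(col) {
    m <- matrix(psa$samples[[col]], nrow = n,
                dimnames = list(NULL, strategies))
    m
  }
  list(cost = grab("cost"), effectiveness = grab("effectiveness"),
       nmb = grab("nmb"))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on the grid, recomputes every
#' draw's NMB from its stored cost and effectiveness and reports the
#' fraction of draws in which each strategy attains the maximal NMB.
#' At each grid point the fractions partition the draws (sum to 1).
#'
#' @param psa A `psp_psa` object from [run_psa()].
#' @param wtp_grid Willingness-to-pay grid in USD/QALY (default 0 to
#'   200,000 in steps of 5,000).
#' @return A data.frame of class `psp_ceac`: `wtp`, `strategy`,
#'   `p_optimal`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 200000, by = 5000)) {
  stopifnot(inherits(psa, "psp_psa"))
  if (length(wtp_grid) == 0) stop("domain error: empty WTP grid",
                                  call. = FALSE)
  if (psa$n == 0) stop("domain error: empty PSA", call. = FALSE)
  wide <- psa_wide(psa)
  rows <- lapply(wtp_grid, function(w) {
    nmb_w <- w * wide$effectiveness - wide$cost
    best <- apply(nmb_w, 1, which_best)
    data.frame(wtp = w, strategy = psa$strategies,
               p_optimal = tabulate(best, length(psa$strategies)) / psa$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("psp_ceac", "data.frame")
  out
}

#' @export
print.psp_psa <- function(x, ...) {
  cat("<psp_psa>", x$n, "Monte Carlo draws, WTP $",
      format(x$wtp, big.mark = ","), "/QALY, seed", x$seed, "\n")
  s <- x$summary
  s$mean_cost <- round(s$mean_cost)
  s$mean_effectiveness <- round(s$mean_effectiveness, 2)
  s$mean_nmb <- round(s$mean_nmb)
  print.data.frame(s, row.names = FALSE, digits = 4)
  invisible(x)
}
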