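# Run `expr` under a private, explicitly seeded RNG stream, restoring
# the caller's RNG state afterwards: each seeded operation is an
# independent stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Patient-level microsimulation through the decision tree
#'
#' Routes `n` simulated patients through one strategy's subtree, drawing
#' each chance-node branch independently. This is the brute-force
#' counterpart of [rollback()]: by the law of large numbers the cohort's
#' mean cost and terminal-state frequencies converge (at rate ~1/sqrt(n))
#' to the rollback expectations, which makes the microsimulation a
#' validation oracle for the analytic engine (and vice versa).
#'
#' @param tree A `psp_tree`.
#' @param strategy Strategy label, see [psp_strategies()].
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; the same seed reproduces the cohort
#'   bit-for-bit.
#' @return A data.frame with one row per patient: `patient_id`,
#'   `strategy`, `path` (node labels joined by `">"`), `total_cost`,
#'   `terminal_state`.
#' @export
simulate_patients <- function(tree, strategy, n, seed = 1L) {
  stopifnot(inherits(tree, "psp_tree"))
  if (!strategy %in% names(tree$root$children))
    stop("domain error: unknown strategy '", strategy, "'", call. = FALSE)
  if (!is.numeric(n) || n < 1)
    stop("domain error: n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  path <- character(n); cost <- numeric(n); state <- character(n)
  with_local_seed(seed, {
    # recursive partition: all patients at a node draw their branch at
    # once, then descend with their subgroup
    descend <- function(node, ids, labels) {
      labels <- c(labels, node$label)
      if (node$kind == "terminal") {
        path[ids] <<- paste(labels, collapse = ">")
        cost[ids] <<- node$cost
        state[ids] <<- node$state
        return(invisible())
      }
      probs <- vapply(node$branches, function(b) b$prob, numeric(1))
      pick <- sample.int(length(probs), length(ids), replace = TRUE,
                         prob = probs)
      for (j in seq_along(probs)) {
        sub <- ids[pick == j]
        if (length(sub)) descend(node$branches[[j]]$node, sub, labels)
      }
    }
    descend(tree$root$children[[strategy]], seq_len(n), character())
  })
  data.frame(patient_id = seq_len(n), strategy = strategy, path = path,
             total_cost = cost, terminal_state = state,
             stringsAsFactors = FALSE)
}

#' Synthetic randomized-trial success counts
#'
#' Emulates a trial arm's success/failure count: successes are drawn
#' binomially at the true success proportion, and a 95% Wilson score
#' interval is attached. At the pooled observation-trial conditions
#' (p = 0.846, n = 162) the expected count is 137.05, emulating the
#' published 137/162.
#'
#' @param p_true True success probability in `[0, 1]`.
#' @param n Patients in the arm (>= 1).
#' @param seed Integer seed.
#' @return A one-row data.frame: `n`, `successes`, `proportion`,
#'   `ci_low`, `ci_high`.
#' @export
synth_trial_counts <- function(p_true, n, seed = 1L) {
  if (!is.numeric(p_true) || p_true < 0 || p_true > 1)
    stop("domain error: p_true must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(n) || n < 1)
    stop("domain error: n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  x <- with_local_seed(seed, stats::rbinom(1, n, p_true))
  ci <- wilson_interval(x, n)
  data.frame(n = n, successes = x, proportion = x / n,
             ci_low = ci[1], ci_high = ci[2])
}

# 95% Wilson score interval (prop.test without continuity correction)
wilson_interval <- function(x, n) {
  if (x == 0) return(c(0, unname(stats::prop.test(x, n, correct = FALSE)$conf.int[2])))
  if (x == n) return(c(unname(stats::prop.test(x, n, correct = FALSE)$conf.int[1]), 1))
  unname(stats::prop.test(x, n, correct = FALSE)$conf.int)
}

#' Success percentage from trial counts
#'
#' @param successes Successes (0 <= successes <= n).
#' @param n Trial size (>= 1).
#' @return `100 * successes / n`, rounded to one decimal (the reporting
#'   precision of the source trials: 137/162 -> 84.6).
#' @export
proportion_from_counts <- function(successes, n) {
  if (!is.numeric(n) || n < 1)
    stop("domain error: n must be >= 1", call. = FALSE)
  if (successes < 0 || successes > n)
    stop("domain error: successes must lie in [0, n]", call. = FALSE)
  round(100 * successes / n, 1)
}
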