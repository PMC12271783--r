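#' Model parameters for the pneumothorax decision tree
#'
#' A `psp_params` object bundles everything the model needs: initial-success
#' probabilities for the four strategies, service costs (2022 USD, CPT/DRG
#' billing codes), health-state utility weights, and the analysis settings
#' (annual discount rate, willingness-to-pay threshold, patient age and life
#' expectancy). Every probability, cost and utility carries a base value plus
#' a `[low, high]` range used by the deterministic and probabilistic
#' sensitivity analyses.
#'
#' @param probabilities,costs,utilities Named lists; each element is a list
#'   with `base`, `low`, `high` (costs also take a `code` billing string).
#' @param settings Named list with `discount_rate`, `age`, `life_expectancy`
#'   (each with `base`, `low`, `high`) and a scalar `wtp`.
#' @return An object of class `psp_params`.
#' @seealso [load_parameters()] to read a configuration file,
#'   [base_case_parameters()] for the packaged base case.
#' @export
parameter_set <- function(probabilities, costs, utilities, settings) {
  ps <- structure(
    list(
      probabilities = lapply_named(probabilities, as_prob_param),
      costs         = lapply_named(costs, as_cost_param),
      utilities     = lapply_named(utilities, as_utility_param),
      discount_rate = as_ranged(settings$discount_rate, "discount_rate"),
      wtp           = as_scalar(settings$wtp, "wtp"),
      age           = as_ranged(settings$age, "age"),
      life_expectancy = as_ranged(settings$life_expectancy, "life_expectancy")
    ),
    class = "psp_params"
  )
  validate_parameter_set(ps)
}

required_probabilities <- c("p_obs", "p_na", "p_valve", "p_suction")
required_costs <- c("ed_visit", "chest_xray", "needle_aspiration",
                    "pleural_catheter", "pneumothorax_admission",
                    "vats_admission")
required_utilities <- c("baseline", "resolved_psp", "invasive_lung_procedure")

lapply_named <- function(x, f) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("parameter entries must be named", call. = FALSE)
  out <- lapply(seq_along(x), function(i) f(x[[i]], names(x)[i]))
  names(out) <- names(x)
  out
}

as_scalar <- function(x, what) {
  if (is.null(x)) stop("missing parameter: ", what, call. = FALSE)
  x <- as.numeric(x)
  if (length(x) != 1 || !is.finite(x))
    stop(what, " must be a single finite number", call. = FALSE)
  x
}

# base plus sensitivity range; invariant low <= base <= high
as_ranged <- function(x, what) {
  if (is.null(x)) stop("missing parameter: ", what, call. = FALSE)
  if (is.numeric(x) && length(x) == 1)
    x <- list(base = x, low = x, high = x)
  for (f in c("base", "low", "high"))
    if (is.null(x[[f]]))
      stop("parameter '", what, "' is missing its '", f, "' value",
           call. = FALSE)
  out <- list(name = what, base = as_scalar(x$base, paste0(what, "$base")),
              low = as_scalar(x$low, paste0(what, "$low")),
              high = as_scalar(x$high, paste0(what, "$high")))
  if (out$low > out$high || out$base < out$low || out$base > out$high)
    stop("range error in '", what, "': need low <= base <= high (got ",
         out$low, ", ", out$base, ", ", out$high, ")", call. = FALSE)
  out
}

as_prob_param <- function(x, name) {
  p <- as_ranged(x, name)
  if (p$low < 0 || p$high > 1)
    stop("range error in '", name, "': probabilities must lie in [0, 1]",
         call. = FALSE)
  class(p) <- "psp_prob_param"
  p
}

as_utility_param <- function(x, name) {
  u <- as_ranged(x, name)
  if (u$low < 0 || u$high > 1)
    stop("range error in '", name, "': utilities must lie in [0, 1]",
         call. = FALSE)
  class(u) <- "psp_utility_param"
  u
}

as_cost_param <- function(x, name) {
  code <- if (!is.null(x$code)) as.character(x$code) else NA_character_
  cst <- as_ranged(x, name)
  if (cst$low < 0)
    stop("range error in '", name, "': costs must be non-negative",
         call. = FALSE)
  cst$code <- code
  class(cst) <- "psp_cost_param"
  cst
}

validate_parameter_set <- function(ps) {
  for (nm in required_probabilities)
    if (is.null(ps$probabilities[[nm]]))
      stop("configuration error: missing probability '", nm, "'",
           call. = FALSE)
  for (nm in required_costs)
    if (is.null(ps$costs[[nm]]))
      stop("configuration error: missing cost '", nm, "'", call. = FALSE)
  for (nm in required_utilities)
    if (is.null(ps$utilities[[nm]]))
      stop("configuration error: missing utility '", nm, "'", call. = FALSE)
  if (ps$discount_rate$low < 0)
    stop("range error in 'discount_rate': must be non-negative",
         call. = FALSE)
  if (ps$wtp < 0)
    stop("range error in 'wtp': must be non-negative", call. = FALSE)
  if (ps$age$base >= ps$life_expectancy$base)
    stop("range error: age must be below life expectancy", call. = FALSE)
  ps
}

#' Load model parameters from a YAML configuration file
#'
#' The configuration has four sections: `probabilities`, `costs`,
#' `utilities` and `settings`; see the packaged base case
#' (`system.file("extdata", "psp_base_case.yaml", package = "psptree")`)
#' for the layout. Every parameter must supply `base`, `low` and `high`;
#' a missing parameter or an inverted range is an error naming the field.
#'
#' @param path Path to the configuration file.
#' @return A validated [parameter_set()].
#' @examples
#' params <- base_case_parameters()
#' params$probabilities$p_obs$base  # 0.846
#' @export
load_parameters <- function(path) {
  if (!file.exists(path))
    stop("configuration error: file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (section in c("probabilities", "costs", "utilities", "settings"))
    if (is.null(cfg[[section]]))
      stop("configuration error: missing section '", section, "'",
           call. = FALSE)
  parameter_set(cfg$probabilities, cfg$costs, cfg$utilities, cfg$settings)
}

#' @rdname load_parameters
#' @export
base_case_parameters <- function() {
  load_parameters(system.file("extdata", "psp_base_case.yaml",
                              package = "psptree", mustWork = TRUE))
}

#' All parameters of a set, one row each, with their sensitivity ranges
#'
#' @param params A [parameter_set()].
#' @param ranged_only Keep only parameters whose range is non-degenerate
#'   (`low < high`); these are the ones a tornado analysis varies.
#' @return A data.frame with columns `parameter`, `group`, `base`, `low`,
#'   `high`.
#' @export
parameter_table <- function(params, ranged_only = FALSE) {
  stopifnot(inherits(params, "psp_params"))
  one <- function(p, group)
    data.frame(parameter = p$name, group = group, base = p$base,
               low = p$low, high = p$high, stringsAsFactors = FALSE)
  rows <- c(
    lapply(params$probabilities, one, group = "probability"),
    lapply(params$costs, one, group = "cost"),
    lapply(params$utilities, one, group = "utility"),
    list(one(params$discount_rate, "setting"),
         one(params$age, "setting"),
         one(params$life_expectancy, "setting"))
  )
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (ranged_only) out <- out[out$low < out$high, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Return a copy of `params` with one named parameter's base value replaced.
# Settings are matched by name alongside probabilities/costs/utilities.
set_parameter <- function(params, name, value) {
  stopifnot(inherits(params, "psp_params"))
  for (group in c("probabilities", "costs", "utilities")) {
    if (!is.null(params[[group]][[name]])) {
      params[[group]][[name]]$base <- value
      return(params)
    }
  }
  if (name %in% c("discount_rate", "age", "life_expectancy")) {
    params[[name]]$base <- value
    return(params)
  }
  if (name == "wtp") {
    params$wtp <- value
    return(params)
  }
  stop("unknown parameter: ", name, call. = FALSE)
}

base_value <- function(params, name) {
  for (group in c("probabilities", "costs", "utilities"))
    if (!is.null(params[[group]][[name]]))
      return(params[[group]][[name]]$base)
  if (name %in% c("discount_rate", "age", "life_expectancy"))
    return(params[[name]]$base)
  if (name == "wtp") return(params$wtp)
  stop("unknown parameter: ", name, call. = FALSE)
}

#' @export
print.psp_params <- function(x, ...) {
  cat("<psp_params> pneumothorax decision-model inputs\n")
  cat(sprintf("  %d probabilities, %d costs (2022 USD), %d utilities\n",
              length(x$probabilities), length(x$costs), length(x$utilities)))
  cat(sprintf("  discount rate %.0f%%/y, WTP $%s/QALY, age %g y, life expectancy %g y\n",
              100 * x$discount_rate$base, format(x$wtp, big.mark = ","),
              x$age$base, x$life_expectancy$base))
  invisible(x)
}
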