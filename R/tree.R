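#' Decision-tree node constructors
#'
#' The model tree is built from three node kinds. A *decision* node (the
#' root, one per tree) holds one child subtree per strategy. A *chance* node
#' splits into branches whose probabilities must sum to 1. A *terminal* node
#' ends a pathway and carries the accumulated pathway cost and a terminal
#' health state. Any node may carry `services`, the names of billed service
#' costs incurred on entering it; [path_cost()] sums these along a pathway.
#'
#' @param label Node label (identifier, unique within its subtree).
#' @param children Named list of child nodes (decision node), one per
#'   strategy.
#' @param branches List of `list(prob =, node =)` pairs (chance node).
#' @param services Character vector of service-cost names billed at this
#'   node.
#' @param state Terminal health state, one of `"resolved_no_vats"`,
#'   `"resolved_post_vats"`.
#' @param cost Accumulated pathway cost at a terminal node (filled in by
#'   [build_psp_tree()]).
#' @return A list with class `psp_node`.
#' @name tree_nodes
NULL

#' @rdname tree_nodes
#' @export
decision_node <- function(label, children) {
  stopifnot(length(children) >= 1, !is.null(names(children)))
  structure(list(kind = "decision", label = label, children = children),
            class = "psp_node")
}

#' @rdname tree_nodes
#' @export
chance_node <- function(label, branches, services = character()) {
  probs <- vapply(branches, function(b) b$prob, numeric(1))
  if (any(probs < 0 | probs > 1))
    stop("validation error at '", label,
         "': branch probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-12)
    stop("validation error at '", label,
         "': branch probabilities sum to ", sum(probs), ", not 1",
         call. = FALSE)
  structure(list(kind = "chance", label = label, services = services,
                 branches = branches),
            class = "psp_node")
}

#' @rdname tree_nodes
#' @export
terminal_node <- function(label, state, services = character(), cost = NA_real_) {
  stopifnot(is.character(state), length(state) == 1)
  structure(list(kind = "terminal", label = label, services = services,
                 state = state, cost = cost),
            class = "psp_node")
}

#' Terminal health states of the model
#'
#' Pathways end either with a pneumothorax resolved without surgery
#' (`resolved_no_vats`) or resolved after video-assisted thoracoscopic
#' surgery (`resolved_post_vats`). Death from PSP is rare enough that the
#' model excludes it.
#' @export
terminal_states <- function() c("resolved_no_vats", "resolved_post_vats")

#' Strategy labels, ordered by increasing invasiveness
#'
#' The order doubles as the tie-break rule wherever strategies compare
#' equal: less invasive wins.
#' @export
psp_strategies <- function()
  c("observation_only", "needle_aspiration", "valve", "suction")

#' Structural options for the pneumothorax tree
#'
#' The published pathway descriptions leave three points open; each is a
#' configurable option with a documented default.
#'
#' @param observation_failure What follows failed observation. Only
#'   `"suction_admission"` (small-bore chest tube to suction with
#'   admission, mirroring the needle-aspiration failure rule) is defined.
#' @param valve_failure `"convert_in_place"` (default): a failed one-way
#'   valve is converted to suction on admission without billing a second
#'   catheter; `"rebill_catheter"`: a new catheter is billed.
#' @param vats_billing `"additive"` (default): the VATS admission DRG is
#'   billed on top of the pneumothorax admission already incurred during
#'   the failed-suction stay; `"replace"`: it replaces it.
#' @return A list of class `psp_structure`.
#' @export
psp_structure <- function(observation_failure = "suction_admission",
                          valve_failure = c("convert_in_place", "rebill_catheter"),
                          vats_billing = c("additive", "replace")) {
  if (!identical(observation_failure, "suction_admission"))
    stop("configuration error: unknown observation_failure option '",
         observation_failure, "'", call. = FALSE)
  valve_failure <- match_option(valve_failure, c("convert_in_place", "rebill_catheter"),
                                "valve_failure")
  vats_billing <- match_option(vats_billing, c("additive", "replace"),
                               "vats_billing")
  structure(list(observation_failure = observation_failure,
                 valve_failure = valve_failure,
                 vats_billing = vats_billing),
            class = "psp_structure")
}

match_option <- function(value, choices, what) {
  value <- value[1]
  if (!value %in% choices)
    stop("configuration error: unknown ", what, " option '", value, "'",
         call. = FALSE)
  value
}

#' Build the four-strategy pneumothorax decision tree
#'
#' Every patient incurs a high-complexity ED visit and a chest radiograph.
#' Strategy pathways then follow the published protocol: a failed needle
#' aspiration (and, by the default structural choice, failed observation)
#' leads to a small-bore chest tube to suction with admission; a failed
#' one-way valve is converted to suction on admission; every suction
#' failure, in any pathway, proceeds to VATS. Success under observation
#' means discharge without intervention; under the other strategies it
#' means resolution of the pneumothorax. Terminal nodes accumulate the
#' summed service costs along their pathway.
#'
#' @param params A [parameter_set()].
#' @param structure Structural options from [psp_structure()].
#' @return An object of class `psp_tree` with the decision root and the
#'   strategy labels.
#' @examples
#' tree <- build_psp_tree(base_case_parameters())
#' nrow(enumerate_paths(tree))  # 11 pathways
#' @export
build_psp_tree <- function(params, structure = psp_structure()) {
  stopifnot(inherits(params, "psp_params"))
  if (!inherits(structure, "psp_structure"))
    stop("configuration error: 'structure' must come from psp_structure()",
         call. = FALSE)
  p <- function(nm) params$probabilities[[nm]]$base
  entry <- c("ed_visit", "chest_xray")

  # suction limb (initial strategy or rescue after a failed first line);
  # `services` are the costs billed on entering it (catheter/admission)
  rescue <- function(label, services) {
    chance_node(
      label, services = services,
      branches = list(
        list(prob = p("p_suction"),
             node = terminal_node(paste0(label, "_success"),
                                  "resolved_no_vats")),
        list(prob = 1 - p("p_suction"),
             node = terminal_node(paste0(label, "_vats"),
                                  "resolved_post_vats",
                                  services = "vats_admission"))
      ))
  }

  first_line <- function(label, services, p_success, on_failure) {
    chance_node(
      label, services = services,
      branches = list(
        list(prob = p_success,
             node = terminal_node(paste0(label, "_success"),
                                  "resolved_no_vats")),
        list(prob = 1 - p_success, node = on_failure)
      ))
  }

  observation <- first_line(
    "observation", entry, p("p_obs"),
    rescue("observation_failed_suction",
           c("pleural_catheter", "pneumothorax_admission")))

  aspiration <- first_line(
    "needle_aspiration", c(entry, "needle_aspiration"), p("p_na"),
    rescue("aspiration_failed_suction",
           c("pleural_catheter", "pneumothorax_admission")))

  valve_rescue_services <- switch(structure$valve_failure,
    convert_in_place = "pneumothorax_admission",
    rebill_catheter  = c("pleural_catheter", "pneumothorax_admission"))
  valve <- first_line(
    "valve", c(entry, "pleural_catheter"), p("p_valve"),
    rescue("valve_failed_suction", valve_rescue_services))

  suction <- rescue("suction", c(entry, "pleural_catheter",
                                 "pneumothorax_admission"))

  tree <- structure(
    list(root = decision_node("psp_management",
                              list(observation_only = observation,
                                   needle_aspiration = aspiration,
                                   valve = valve,
                                   suction = suction)),
         strategies = psp_strategies(),
         structure = structure),
    class = "psp_tree")
  annotate_costs(tree, params)
}

# fill in each terminal node's accumulated pathway cost; under the
# "replace" VATS billing the pneumothorax admission is dropped from
# VATS pathways
annotate_costs <- function(tree, params) {
  costs <- vapply(params$costs, function(cc) cc$base, numeric(1))
  replace_vats <- tree$structure$vats_billing == "replace"
  walk <- function(node, acc) {
    acc <- c(acc, node$services)
    if (node$kind == "terminal") {
      if (replace_vats && "vats_admission" %in% acc)
        acc <- acc[acc != "pneumothorax_admission"]
      node$cost <- sum(costs[acc])
      return(node)
    }
    if (node$kind == "chance") {
      node$branches <- lapply(node$branches, function(b) {
        b$node <- walk(b$node, acc)
        b
      })
      return(node)
    }
    node$children <- lapply(node$children, walk, acc = acc)
    node
  }
  tree$root <- walk(tree$root, character())
  tree
}

#' Enumerate every root-to-leaf pathway of a tree
#'
#' @param tree A `psp_tree`.
#' @param strategy Optional strategy label to restrict to one subtree.
#' @return A data.frame with one row per pathway: `strategy`, `path`
#'   (node labels joined by `">"`), `probability`, `cost`,
#'   `terminal_state`.
#' @export
enumerate_paths <- function(tree, strategy = NULL) {
  stopifnot(inherits(tree, "psp_tree"))
  strategies <- names(tree$root$children)
  if (!is.null(strategy)) {
    if (!strategy %in% strategies)
      stop("unknown strategy: ", strategy, call. = FALSE)
    strategies <- strategy
  }
  rows <- list()
  descend <- function(node, strat, prob, labels) {
    labels <- c(labels, node$label)
    if (node$kind == "terminal") {
      rows[[length(rows) + 1]] <<- data.frame(
        strategy = strat, path = paste(labels, collapse = ">"),
        probability = prob, cost = node$cost,
        terminal_state = node$state, stringsAsFactors = FALSE)
      return(invisible())
    }
    for (b in node$branches)
      descend(b$node, strat, prob * b$prob, labels)
  }
  for (s in strategies)
    descend(tree$root$children[[s]], s, 1, character())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Sum the service costs billed along a root-to-leaf pathway
#'
#' @param path A list of `psp_node` objects from root to leaf (the leaf
#'   must be a terminal node).
#' @param costs Either a `psp_params` object or a named list/vector of
#'   service costs.
#' @return The summed cost in USD (0 for a pathway billing no services).
#' @export
path_cost <- function(path, costs) {
  if (inherits(costs, "psp_params"))
    costs <- vapply(costs$costs, function(cc) cc$base, numeric(1))
  costs <- unlist(costs)
  last <- path[[length(path)]]
  if (!identical(last$kind, "terminal"))
    stop("structural error: pathway does not end at a terminal node",
         call. = FALSE)
  services <- unlist(lapply(path, function(n) n$services))
  if (length(services) == 0) return(0)
  missing <- setdiff(services, names(costs))
  if (length(missing))
    stop("unknown service cost: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sum(costs[services])
}

#' Roll back a decision tree to per-strategy expected values
#'
#' Standard expected-value rollback: a terminal node is worth its
#' accumulated cost and its terminal state with certainty; a chance node
#' is worth the probability-weighted sum of its branches. Equivalent to
#' summing probability times cost over every root-to-leaf pathway.
#'
#' @param tree A `psp_tree`.
#' @return An object of class `psp_rollback`: a data.frame with one row
#'   per strategy (`strategy`, `expected_cost`, and one probability
#'   column `p_<state>` per terminal state).
#' @export
rollback <- function(tree) {
  stopifnot(inherits(tree, "psp_tree"))
  states <- terminal_states()
  eval_node <- function(node) {
    if (node$kind == "terminal") {
      dist <- stats::setNames(as.numeric(states == node$state), states)
      return(list(cost = node$cost, dist = dist))
    }
    if (node$kind != "chance")
      stop("validation error: decision node below the root", call. = FALSE)
    probs <- vapply(node$branches, function(b) b$prob, numeric(1))
    if (abs(sum(probs) - 1) > 1e-12)
      stop("validation error at '", node$label,
           "': branch probabilities sum to ", sum(probs), call. = FALSE)
    vals <- lapply(node$branches, function(b) eval_node(b$node))
    cost <- sum(probs * vapply(vals, function(v) v$cost, numeric(1)))
    dist <- Reduce(`+`, Map(function(p, v) p * v$dist, probs, vals))
    list(cost = cost, dist = dist)
  }
  res <- lapply(tree$root$children, eval_node)
  out <- data.frame(strategy = names(res),
                    expected_cost = vapply(res, function(v) v$cost, numeric(1)),
                    stringsAsFactors = FALSE)
  for (s in states)
    out[[paste0("p_", s)]] <- vapply(res, function(v) v$dist[[s]], numeric(1))
  rownames(out) <- NULL
  class(out) <- c("psp_rollback", "data.frame")
  out
}

#' @export
print.psp_tree <- function(x, ...) {
  paths <- enumerate_paths(x)
  cat("<psp_tree> decision tree over", length(x$root$children),
      "strategies,", nrow(paths), "terminal pathways\n")
  cat("  structure: valve_failure =", x$structure$valve_failure,
      "| vats_billing =", x$structure$vats_billing, "\n")
  invisible(x)
}
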