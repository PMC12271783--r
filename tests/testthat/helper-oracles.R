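# Independent oracles and fixture builders, deliberately written without
# touching the package's rollback/enumeration code paths.

base_params <- function() base_case_parameters()

# Brute-force expected value by explicit path products: walk every
# root-to-leaf route of one strategy subtree, accumulating probability
# mass, and sum probability * terminal cost. Independent of rollback().
oracle_expectation <- function(node) {
  acc <- list(cost = 0,
              dist = stats::setNames(numeric(2), terminal_states()))
  walk <- function(nd, prob) {
    if (nd$kind == "terminal") {
      acc$cost <<- acc$cost + prob * nd$cost
      acc$dist[nd$state] <<- acc$dist[nd$state] + prob
      return(invisible())
    }
    for (b in nd$branches) walk(b$node, prob * b$prob)
  }
  walk(node, 1)
  acc
}

oracle_rollback <- function(tree) {
  lapply(tree$root$children, oracle_expectation)
}

# Random small chance tree (terminal costs drawn directly); wrapped as a
# psp_tree so both rollback() and the oracle accept it.
random_tree <- function(max_depth = 4) {
  counter <- 0
  grow <- function(depth) {
    counter <<- counter + 1
    if (depth >= max_depth || stats::runif(1) < 0.35)
      return(terminal_node(paste0("t", counter),
                           sample(terminal_states(), 1),
                           cost = stats::runif(1, 0, 1e5)))
    k <- sample(2:3, 1)
    w <- stats::runif(k)
    p <- w / sum(w)
    p[k] <- 1 - sum(p[-k])  # force the sum to be exactly 1
    chance_node(paste0("c", counter),
                lapply(seq_len(k), function(j)
                  list(prob = p[j], node = grow(depth + 1))))
  }
  root <- grow(1)
  if (root$kind == "terminal")  # guarantee at least one chance node
    root <- chance_node("c0", list(list(prob = 0.6, node = root),
                                   list(prob = 0.4, node = grow(max_depth))))
  structure(list(root = decision_node("root", list(only = root)),
                 strategies = "only",
                 structure = psp_structure()),
            class = "psp_tree")
}

# Resolve a ">"-joined label path of a strategy subtree back into the
# node sequence, for recomputing pathway costs from first principles.
nodes_along <- function(tree, strategy, path_string) {
  labels <- strsplit(path_string, ">", fixed = TRUE)[[1]]
  node <- tree$root$children[[strategy]]
  stopifnot(identical(node$label, labels[1]))
  out <- list(node)
  for (lab in labels[-1]) {
    hit <- NULL
    for (b in node$branches) if (identical(b$node$label, lab)) hit <- b$node
    stopifnot(!is.null(hit))
    node <- hit
    out <- c(out, list(node))
  }
  out
}

# The published base-case results table, used for arithmetic-identity
# checks (the printed values serve as inputs, not as expectations for
# this engine's own absolute outputs).
printed_base_case <- function() {
  out <- data.frame(
    strategy = c("observation_only", "needle_aspiration", "valve", "suction"),
    expected_cost = c(5332, 16766, 13086, 33728),
    effectiveness = c(49.82, 48.76, 49.29, 48.76),
    nmb = c(41910, 29465, 33520, 12831),
    stringsAsFactors = FALSE)
  class(out) <- c("psp_outcomes", "data.frame")
  attr(out, "wtp") <- 50000
  out
}
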