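#' Declare a discrete variable of a causal network
#'
#' @param name variable name (unique within the network).
#' @param cardinality number of states (>= 2); states are integers
#'   `0..cardinality-1`.
#' @return a one-row tibble, suitable for binding into a variable table.
#' @export
variable_spec <- function(name, cardinality = 2L) {
  cardinality <- as.integer(cardinality)
  if (is.na(cardinality) || cardinality < 2L) {
    abort_schema(sprintf("variable '%s' must have cardinality >= 2", name))
  }
  tibble::tibble(name = as.character(name), cardinality = cardinality)
}

as_variable_table <- function(x, tier) {
  if (is.character(x)) {
    x <- tibble::tibble(name = x, cardinality = 2L)
  }
  x <- tibble::as_tibble(x)
  if (!all(c("name", "cardinality") %in% names(x)) || nrow(x) == 0L) {
    abort_schema(sprintf(
      "%s variables must be a nonempty table with columns name, cardinality",
      tier
    ))
  }
  x$name <- as.character(x$name)
  x$cardinality <- as.integer(x$cardinality)
  if (any(x$cardinality < 2L)) abort_schema("cardinalities must be >= 2")
  if (anyDuplicated(x$name)) abort_schema("duplicate variable names")
  x[, c("name", "cardinality")]
}

#' Build a two-slice dynamical causal network
#'
#' A dynamical causal network here consists of two time slices: pre-tier
#' variables (time t-1) and post-tier variables (time t), with one mechanism
#' (conditional probability table over its pre-tier inputs) per post-tier node.
#' There are no within-slice edges by construction, so the network is acyclic
#' and the post-tier nodes are conditionally independent given the full
#' pre-tier state: the transition probability factorizes over mechanisms.
#'
#' @param pre,post variable declarations for each tier: a character vector of
#'   (binary) names, or a table as produced by [variable_spec()].
#' @param mechanisms list of [make_gate_mechanism()] objects, exactly one per
#'   post-tier variable.
#' @param background named integer vector of already-conditioned exogenous
#'   variables and their fixed states (informational record, see
#'   [condition_on_background()]).
#' @return an object of class `causal_network`.
#' @examples
#' net <- build_network(
#'   pre = c("OR", "AND"), post = c("OR", "AND"),
#'   mechanisms = list(
#'     make_gate_mechanism("OR", c("OR", "AND"), "OR"),
#'     make_gate_mechanism("AND", c("OR", "AND"), "AND")
#'   )
#' )
#' @export
build_network <- function(pre, post, mechanisms, background = integer()) {
  pre <- as_variable_table(pre, "pre")
  post <- as_variable_table(post, "post")

  if (!is.list(mechanisms) || !all(vapply(mechanisms, inherits, TRUE, "mechanism"))) {
    abort_schema("`mechanisms` must be a list of mechanism objects")
  }
  nodes <- vapply(mechanisms, function(m) m$node, "")
  if (anyDuplicated(nodes)) abort_schema("more than one mechanism for a node")
  missing <- setdiff(post$name, nodes)
  if (length(missing)) {
    abort_schema(sprintf(
      "post variable(s) without a mechanism: %s", paste(missing, collapse = ", ")
    ))
  }
  extra <- setdiff(nodes, post$name)
  if (length(extra)) {
    abort_schema(sprintf(
      "mechanism for unknown post variable(s): %s", paste(extra, collapse = ", ")
    ))
  }
  mechanisms <- mechanisms[match(post$name, nodes)]
  names(mechanisms) <- post$name

  for (m in mechanisms) {
    unknown <- setdiff(m$inputs, pre$name)
    if (length(unknown)) {
      abort_schema(sprintf(
        "mechanism for '%s' references unknown pre variable(s): %s",
        m$node, paste(unknown, collapse = ", ")
      ))
    }
    in_cards <- pre$cardinality[match(m$inputs, pre$name)]
    node_card <- post$cardinality[match(m$node, post$name)]
    if (nrow(m$table) != prod(in_cards) || ncol(m$table) != node_card) {
      abort_schema(sprintf(
        "mechanism table for '%s' has wrong shape for the declared cardinalities",
        m$node
      ))
    }
    validate_mechanism_table(m$table, m$node)
  }

  structure(
    list(
      pre = pre, post = post, mechanisms = mechanisms,
      background = background,
      cache = new.env(parent = emptyenv())
    ),
    class = "causal_network"
  )
}

pre_cards <- function(net) stats::setNames(net$pre$cardinality, net$pre$name)
post_cards <- function(net) stats::setNames(net$post$cardinality, net$post$name)

n_variables <- function(net) nrow(net$pre) + nrow(net$post)

check_state <- function(state, vars, cards, what) {
  state <- as.integer(state)
  if (is.null(names(state)) && length(state) == length(vars)) {
    names(state) <- vars
  }
  if (!setequal(names(state), vars) || length(state) != length(vars)) {
    abort_schema(sprintf("%s must assign every variable exactly once", what))
  }
  state <- state[vars]
  if (any(state < 0L) || any(state >= cards[vars])) {
    abort_schema(sprintf("%s has a state out of range", what))
  }
  state
}

#' Interventional transition probability of a full state pair
#'
#' Computes `p(post_state | do(pre_state))` as the product over post-tier
#' nodes of their mechanism probabilities — the factorized transition
#' probability of the network.
#'
#' @param net a [build_network()] object.
#' @param pre_state,post_state full named (or declaration-ordered) integer
#'   state assignments for each tier.
#' @return a probability in `[0, 1]`.
#' @export
transition_probability <- function(net, pre_state, post_state) {
  pre_state <- check_state(pre_state, net$pre$name, pre_cards(net), "pre_state")
  post_state <- check_state(post_state, net$post$name, post_cards(net), "post_state")
  p <- 1
  for (m in net$mechanisms) {
    row <- state_index(pre_state[m$inputs], pre_cards(net)[m$inputs])
    p <- p * m$table[row, post_state[m$node] + 1L]
  }
  min(max(p, 0), 1)
}

#' Fix background conditions by conditioning the network
#'
#' Pins the given pre-tier variables to fixed states and removes them from the
#' network: each mechanism's table is restricted to the rows consistent with
#' the assignment and the variables disappear from the pre-slice, so no
#' counterfactuals over them are considered in any later analysis. The
#' assignment is recorded in the returned network's `background` field.
#'
#' @param net a [build_network()] object.
#' @param assignments named integer vector, e.g. `c(D = 0)`.
#' @return a `causal_network` over the remaining pre-tier variables.
#' @export
condition_on_background <- function(net, assignments) {
  if (length(assignments) == 0L) {
    return(net)
  }
  x <- unlist(assignments)
  if (is.null(names(x)) || any(names(x) == "")) {
    abort_schema("background assignments must be named")
  }
  assignments <- stats::setNames(as.integer(round(x)), names(x))
  vars <- names(assignments)
  unknown <- setdiff(vars, net$pre$name)
  if (length(unknown)) {
    if (any(unknown %in% net$post$name)) {
      abort_schema("cannot condition on a post-tier variable")
    }
    abort_schema(sprintf(
      "unknown background variable(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  cards <- pre_cards(net)
  if (any(assignments < 0L) || any(assignments >= cards[vars])) {
    abort_schema("background state out of range")
  }

  keep <- setdiff(net$pre$name, vars)
  if (length(keep) == 0L) abort_schema("cannot condition away the entire pre-slice")

  mechanisms <- lapply(net$mechanisms, function(m) {
    in_cards <- cards[m$inputs]
    grid <- state_grid(in_cards)
    rows <- rep(TRUE, nrow(grid))
    for (v in intersect(m$inputs, vars)) {
      rows <- rows & grid[, match(v, m$inputs)] == assignments[[v]]
    }
    new_inputs <- setdiff(m$inputs, vars)
    tab <- m$table[rows, , drop = FALSE]
    # restricted rows arrive in canonical order of the remaining inputs
    new_mechanism(m$node, new_inputs, tab, m$gate, m$params)
  })

  build_network(
    pre = net$pre[net$pre$name %in% keep, ],
    post = net$post,
    mechanisms = mechanisms,
    background = c(net$background, assignments)
  )
}

#' Define and validate a realized transition
#'
#' A transition is a pair of full consecutive states (the realization
#' principle requires its interventional probability to be positive).
#' `make_transition()` constructs and checks it; [validate_transition()]
#' re-checks an existing one against a network.
#'
#' @param net a [build_network()] object.
#' @param before,after full pre- and post-tier state assignments.
#' @return an object of class `transition` with fields `before` and `after`.
#' @export
make_transition <- function(net, before, after) {
  before <- check_state(before, net$pre$name, pre_cards(net), "before")
  after <- check_state(after, net$post$name, post_cards(net), "after")
  tr <- structure(list(before = before, after = after), class = "transition")
  validate_transition(net, tr)
  tr
}

#' @rdname make_transition
#' @param transition a `transition` object.
#' @return `validate_transition()` returns the transition invisibly, or signals
#'   an error of class `actualcause_realization_error` if the transition has
#'   zero probability in the network.
#' @export
validate_transition <- function(net, transition) {
  p <- transition_probability(net, transition$before, transition$after)
  if (p <= 0) {
    abort_realization(
      "transition violates the realization principle: p(after | do(before)) = 0"
    )
  }
  invisible(transition)
}

#' Extract an occurrence (sub-state) of a transition
#'
#' An occurrence is a subset of one tier's variables fixed in the states they
#' actually took in the transition. The empty occurrence is allowed (it
#' represents "no constraint").
#'
#' @param transition a [make_transition()] object.
#' @param vars character vector of variable names (possibly empty).
#' @param tier `"pre"` or `"post"`.
#' @return a named integer vector with attribute `tier`.
#' @export
occurrence <- function(transition, vars, tier = c("pre", "post")) {
  tier <- match.arg(tier)
  full <- if (tier == "pre") transition$before else transition$after
  vars <- as.character(vars)
  unknown <- setdiff(vars, names(full))
  if (length(unknown)) {
    abort_schema(sprintf(
      "occurrence variable(s) not on the %s tier: %s",
      tier, paste(unknown, collapse = ", ")
    ))
  }
  structure(full[vars], tier = tier)
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf(
    "<causal_network> %d pre -> %d post variables\n",
    nrow(x$pre), nrow(x$post)
  ))
  cat("  pre: ", paste0(x$pre$name, "(", x$pre$cardinality, ")", collapse = " "), "\n")
  gates <- vapply(x$mechanisms, function(m) {
    sprintf("%s=%s(%s)", m$node, m$gate, paste(m$inputs, collapse = ","))
  }, "")
  cat("  post:", paste(gates, collapse = " "), "\n")
  if (length(x$background)) {
    cat(
      "  background:",
      paste0(names(x$background), "=", x$background, collapse = " "), "\n"
    )
  }
  invisible(x)
}

#' @export
print.transition <- function(x, ...) {
  cat(sprintf(
    "<transition> {%s} > {%s}\n",
    paste0(names(x$before), "=", x$before, collapse = ", "),
    paste0(names(x$after), "=", x$after, collapse = ", ")
  ))
  invisible(x)
}

fmt_occurrence <- function(occ) {
  if (length(occ) == 0L) {
    return("{}")
  }
  paste0("{", paste0(names(occ), "=", unname(occ), collapse = ","), "}")
}
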