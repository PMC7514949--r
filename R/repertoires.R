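# Core repertoire engine.
#
# All internal computations work on plain probability vectors in the canonical
# joint-state enumeration of the purview (first-listed variable fastest); the
# exported functions wrap them into tibbles. Probabilities stay in linear
# space throughout; logs are taken only at the information layer.

# --- internal vector engine ---------------------------------------------------

# effect repertoire of a single post node given a pre-tier occurrence:
# average of p(node | do(occ, W = w)) over all states w of W = pre \ occ,
# each state weighted uniformly. Only the node's parents matter: weights over
# mechanism rows are 1{matches occ} for parents in the occurrence and
# 1/cardinality for marginalized parents; non-parents average out exactly.
er_node <- function(net, occ, node) {
  m <- net$mechanisms[[node]]
  cards <- pre_cards(net)[m$inputs]
  nr <- nrow(m$table)
  w <- rep(1, nr)
  for (j in seq_along(m$inputs)) {
    v <- m$inputs[j]
    col <- state_column(j, cards)
    if (v %in% names(occ)) {
      w <- w * (col == occ[[v]])
    } else {
      w <- w / cards[[j]]
    }
  }
  as.vector(crossprod(w, m$table))
}

# effect repertoire over a purview: product over purview nodes (discounts
# correlations due to common inputs). Returns vector over purview joint states.
er_vec <- function(net, occ, purview) {
  if (length(purview) == 0L) {
    return(1)
  }
  cards <- post_cards(net)[purview]
  grid <- state_grid(cards)
  out <- rep(1, nrow(grid))
  for (j in seq_along(purview)) {
    pj <- er_node(net, occ, purview[j])
    out <- out * pj[grid[, j] + 1L]
  }
  out
}

# unnormalized single-occurrence-node cause weights over purview states:
# q(x) = sum over states of the node's marginalized parents of
# p(y | do(x, w)); constant factors (non-parent marginalized variables) cancel
# on normalization.
cr_node_q <- function(net, y_node, y_state, purview) {
  m <- net$mechanisms[[y_node]]
  cards_all <- pre_cards(net)
  in_cards <- cards_all[m$inputs]
  p_row <- m$table[, y_state + 1L]

  inside <- intersect(m$inputs, purview) # parents constrained by the purview
  nr <- length(p_row)
  w <- rep(1, nr)
  for (j in seq_along(m$inputs)) {
    if (!(m$inputs[j] %in% inside)) {
      w <- w / in_cards[[j]]
    }
  }
  if (length(inside) == 0L) {
    q0 <- sum(w * p_row) # constant in the purview
    return(rep(q0, prod(cards_all[purview])))
  }
  # aggregate rows by the joint state of the purview-parents
  idx_cols <- match(inside, m$inputs)
  grid_in <- state_grid(in_cards)
  sub_idx <- state_index(grid_in[, idx_cols, drop = FALSE], in_cards[idx_cols])
  q0 <- as.vector(rowsum(w * p_row, sub_idx)) # ordered by sub_idx value

  # expand over the full purview enumeration (constant in purview vars that
  # are not parents of the node)
  cards_pv <- cards_all[purview]
  grid_pv <- state_grid(cards_pv)
  pos <- match(inside, purview)
  full_idx <- state_index(grid_pv[, pos, drop = FALSE], cards_pv[pos])
  q0[full_idx]
}

# cause repertoire over a purview given a post-tier occurrence: pointwise
# product over occurrence nodes of the per-node Bayes-inverted distributions,
# renormalized. Empty occurrence -> uniform.
cr_vec <- function(net, occ, purview) {
  if (length(purview) == 0L) {
    return(1)
  }
  cards <- pre_cards(net)[purview]
  n <- prod(cards)
  if (length(occ) == 0L) {
    return(rep(1 / n, n))
  }
  out <- rep(1, n)
  for (v in names(occ)) {
    q <- cr_node_q(net, v, occ[[v]], purview)
    s <- sum(q)
    if (s <= 0) {
      abort_schema(sprintf(
        "occurrence state %s=%d is unreachable under every intervention",
        v, occ[[v]]
      ))
    }
    out <- out * (q / s)
  }
  s <- sum(out)
  if (s <= 0) {
    abort_schema("cause repertoire normalization constant is zero")
  }
  out / s
}

rep_vec <- function(net, occ, purview, direction) {
  # networks are immutable after construction, so repertoires memoize safely
  # in the per-network cache (keyed by direction, occurrence state, purview)
  cache <- net$cache
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(
      direction, paste0(names(occ), "=", occ, collapse = ";"),
      paste(purview, collapse = ","),
      sep = "|"
    )
    val <- cache[[key]]
    if (!is.null(val)) {
      return(val)
    }
  }
  val <- switch(direction,
    effect = er_vec(net, occ, purview),
    cause = cr_vec(net, occ, purview),
    abort_schema("direction must be 'cause' or 'effect'")
  )
  if (!is.null(cache)) cache[[key]] <- val
  val
}

# probability a repertoire vector assigns to one named purview state
prob_at <- function(vec, purview, cards, state) {
  if (length(purview) == 0L) {
    return(1)
  }
  vec[state_index(state[purview], cards[purview])]
}

# --- exported interface -------------------------------------------------------

new_repertoire <- function(net, occ, purview, direction, probs) {
  cards <- if (direction == "effect") post_cards(net) else pre_cards(net)
  grid <- state_grid(cards[purview])
  colnames(grid) <- purview
  out <- tibble::as_tibble(as.data.frame(grid))
  out$prob <- probs
  structure(out,
    class = c("repertoire", class(out)),
    direction = direction, purview = purview,
    conditioned_on = occ, cards = cards[purview]
  )
}

#' Cause and effect repertoires of an occurrence
#'
#' An effect repertoire is the interventional distribution over a set of
#' post-tier variables (the purview) induced by fixing a pre-tier occurrence
#' with `do()` and averaging uniformly over all states of the remaining
#' pre-tier variables (causal marginalization); the joint distribution is the
#' product of the per-node distributions, which discounts correlations due to
#' common inputs from marginalized variables. A cause repertoire is the
#' Bayes-inverted counterpart: the distribution over pre-tier purview states
#' given a post-tier occurrence, with a uniform prior over purview states;
#' multi-node occurrences multiply their per-node distributions pointwise and
#' renormalize. The empty occurrence gives the unconstrained repertoire
#' (uniform for causes; the product of per-node averages for effects).
#'
#' @param net a [build_network()] object.
#' @param occ a named integer vector (e.g. from [occurrence()]), possibly
#'   empty: a pre-tier sub-state for `effect_repertoire()`, post-tier for
#'   `cause_repertoire()`.
#' @param purview nonempty character vector of variable names on the opposite
#'   tier of the repertoire's direction (post-tier for effect, pre-tier for
#'   cause).
#' @return a `repertoire` tibble: one column per purview variable plus `prob`,
#'   rows in canonical state order (first purview variable varying fastest).
#' @examples
#' net <- paper_example("or_and_system")$network
#' effect_repertoire(net, c(OR = 1), "OR") # p(OR_t = 1) = 1
#' cause_repertoire(net, c(OR = 1), c("OR", "AND")) # 1/3 on 01, 10, 11
#' @export
effect_repertoire <- function(net, occ, purview) {
  check_repertoire_args(net, occ, purview, "effect")
  new_repertoire(net, occ, purview, "effect", er_vec(net, occ, purview))
}

#' @rdname effect_repertoire
#' @export
cause_repertoire <- function(net, occ, purview) {
  check_repertoire_args(net, occ, purview, "cause")
  new_repertoire(net, occ, purview, "cause", cr_vec(net, occ, purview))
}

check_repertoire_args <- function(net, occ, purview, direction) {
  occ_tier <- if (direction == "effect") net$pre$name else net$post$name
  pv_tier <- if (direction == "effect") net$post$name else net$pre$name
  if (length(purview) == 0L) {
    abort_schema("purview must be nonempty (the empty repertoire is the scalar 1)")
  }
  if (anyDuplicated(purview) || !all(purview %in% pv_tier)) {
    abort_schema("purview must be distinct variables of the opposite tier")
  }
  if (length(occ) && (is.null(names(occ)) || !all(names(occ) %in% occ_tier))) {
    abort_schema(sprintf(
      "occurrence variables must lie on the %s tier",
      if (direction == "effect") "pre" else "post"
    ))
  }
  invisible(TRUE)
}

#' @export
print.repertoire <- function(x, ...) {
  dir <- attr(x, "direction")
  cat(sprintf(
    "<%s repertoire> pi(%s | %s)\n",
    dir, paste(attr(x, "purview"), collapse = ","),
    fmt_occurrence(attr(x, "conditioned_on"))
  ))
  NextMethod()
}
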