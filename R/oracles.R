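# Independent reference implementations used to cross-check the engine:
# a literal brute-force repertoire (no factorization shortcuts) and the
# closed-form predictions for linear threshold units and
# disjunction-of-conjunction gates.

#' Brute-force repertoire by literal enumeration of interventions
#'
#' Reference implementation kept deliberately independent of the engine: it
#' enumerates every joint state of the marginalized pre-tier variables, reads
#' each node's interventional distribution off the network's full transition
#' distribution (product over all mechanisms, then marginalized), and then
#' averages (effect direction) or Bayes-inverts with a uniform prior (cause
#' direction). Intended for small networks and used as a test oracle.
#'
#' @inheritParams effect_repertoire
#' @param direction `"cause"` or `"effect"`.
#' @param max_states guard on `|pre states| * |post states|`.
#' @return a `repertoire` tibble, comparable to [effect_repertoire()] /
#'   [cause_repertoire()] output.
#' @export
brute_force_repertoire <- function(net, occ, purview,
                                   direction = c("cause", "effect"),
                                   max_states = 250000) {
  direction <- match.arg(direction)
  check_repertoire_args(net, occ, purview, direction)
  pre_c <- pre_cards(net)
  post_c <- post_cards(net)
  if (prod(pre_c) * prod(post_c) > max_states) {
    abort_guard("state space too large for brute-force enumeration")
  }
  pre_grid <- state_grid(pre_c)
  colnames(pre_grid) <- net$pre$name
  post_grid <- state_grid(post_c)
  colnames(post_grid) <- net$post$name

  # p(node = y | do(full pre state)) via the full joint transition distribution
  node_prob <- function(pre_state, node, y) {
    tot <- 0
    for (r in seq_len(nrow(post_grid))) {
      if (post_grid[r, node] != y) next
      tot <- tot + transition_probability(net, pre_state, post_grid[r, ])
    }
    tot
  }

  if (direction == "effect") {
    # rows of pre_grid consistent with the occurrence = do(occ, W = w), all w
    keep <- rep(TRUE, nrow(pre_grid))
    for (v in names(occ)) keep <- keep & pre_grid[, v] == occ[[v]]
    rows <- which(keep)
    per_node <- lapply(purview, function(nd) {
      card <- post_c[[nd]]
      p <- numeric(card)
      for (y in 0:(card - 1L)) {
        p[y + 1L] <- mean(vapply(
          rows, function(r) node_prob(pre_grid[r, ], nd, y), 0
        ))
      }
      p
    })
    grid_pv <- state_grid(post_c[purview])
    probs <- rep(1, nrow(grid_pv))
    for (j in seq_along(purview)) {
      probs <- probs * per_node[[j]][grid_pv[, j] + 1L]
    }
    return(new_repertoire(net, occ, purview, "effect", probs))
  }

  # cause direction
  grid_pv <- state_grid(pre_c[purview])
  n_pv <- nrow(grid_pv)
  if (length(occ) == 0L) {
    return(new_repertoire(net, occ, purview, "cause", rep(1 / n_pv, n_pv)))
  }
  probs <- rep(1, n_pv)
  for (v in names(occ)) {
    q <- numeric(n_pv)
    for (i in seq_len(n_pv)) {
      keep <- rep(TRUE, nrow(pre_grid))
      for (j in seq_along(purview)) {
        keep <- keep & pre_grid[, purview[j]] == grid_pv[i, j]
      }
      rows <- which(keep)
      q[i] <- sum(vapply(
        rows, function(r) node_prob(pre_grid[r, ], v, occ[[v]]), 0
      ))
    }
    probs <- probs * (q / sum(q))
  }
  new_repertoire(net, occ, purview, "cause", probs / sum(probs))
}

#' Closed-form actual cause / effect predictions for a linear threshold unit
#'
#' For a single binary linear threshold unit Y over n binary inputs that fires
#' iff at least k inputs are 1: when the unit fired, the actual cause of
#' `{Y=1}` is a k-subset of the inputs in state 1 (indeterminate between all
#' such subsets when more than k inputs are on), and an input occurrence has
#' actual effect `{Y=1}` iff it is all-1 with at most k variables. When the
#' unit did not fire, the same statements hold with the roles of 0 and 1
#' exchanged and threshold `n - k + 1` on the number of zeros (the complement
#' of "at least k ones" under the >= convention).
#'
#' @param n,k input count and firing threshold (`1 <= k <= n`).
#' @param pre_state integer vector of n input states (0/1); names optional
#'   (defaults `I1..In`).
#' @param y observed output state (0 or 1); must be consistent with
#'   `pre_state`.
#' @return list with `cause` (list of named candidate-state vectors — the
#'   predicted minimal actual causes of `{Y=y}`) and `effect_of`, a function
#'   taking a character vector of input names and returning `TRUE` if that
#'   occurrence has the actual effect `{Y=y}` and `FALSE` if it is reducible.
#' @export
ltu_predict <- function(n, k, pre_state, y = NULL) {
  if (k < 1L || k > n) abort_schema("ltu_predict requires 1 <= k <= n")
  if (is.null(names(pre_state))) {
    names(pre_state) <- paste0("I", seq_len(n))
  }
  fired <- sum(pre_state) >= k
  if (is.null(y)) y <- as.integer(fired)
  if (as.integer(y) != as.integer(fired)) {
    abort_schema("y is inconsistent with pre_state for this LTU")
  }
  if (y == 1L) {
    on_state <- 1L
    kk <- k
  } else {
    on_state <- 0L # roles of 0 and 1 reversed
    kk <- n - k + 1L
  }
  active <- names(pre_state)[pre_state == on_state]
  cause <- lapply(
    utils::combn(active, kk, simplify = FALSE),
    function(v) stats::setNames(rep(on_state, kk), v)
  )
  effect_of <- function(vars) {
    all(pre_state[vars] == on_state) && length(vars) <= kk && length(vars) >= 1L
  }
  list(cause = cause, effect_of = effect_of, y = as.integer(y))
}

#' Closed-form actual cause / effect predictions for a disjunction of
#' conjunctions
#'
#' For a single binary node Y that is an OR over AND-groups of its binary
#' inputs (groups partition the inputs): when `y = 1`, the predicted minimal
#' actual causes of `{Y=1}` are the fully satisfied conjunctions (indeterminate
#' between them when several are satisfied — asymmetric over-determination),
#' and an all-1 input occurrence has actual effect `{Y=1}` unless it strictly
#' contains a complete conjunction (over-determination makes it reducible).
#' When `y = 0`, the predicted causes pick exactly one 0-input from every
#' conjunction, and an all-0 occurrence has actual effect `{Y=0}` iff it takes
#' at most one variable from each conjunction.
#'
#' @param groups list of character vectors partitioning the input names into
#'   conjunctions.
#' @param pre_state named integer vector over all inputs (0/1).
#' @param y observed output (0/1); must be consistent with `pre_state`.
#' @return list with `cause` (list of named candidate-state vectors) and
#'   `effect_of(vars)` as in [ltu_predict()].
#' @export
doc_predict <- function(groups, pre_state, y = NULL) {
  inputs <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(inputs) || !setequal(inputs, names(pre_state))) {
    abort_schema("groups must partition the names of pre_state")
  }
  sat <- vapply(groups, function(g) all(pre_state[g] == 1L), TRUE)
  fired <- any(sat)
  if (is.null(y)) y <- as.integer(fired)
  if (as.integer(y) != as.integer(fired)) {
    abort_schema("y is inconsistent with pre_state for this DOC")
  }

  if (y == 1L) {
    cause <- lapply(groups[sat], function(g) {
      stats::setNames(rep(1L, length(g)), g)
    })
    effect_of <- function(vars) {
      if (length(vars) == 0L || any(pre_state[vars] != 1L)) {
        return(FALSE)
      }
      # reducible iff the occurrence strictly contains a complete conjunction
      !any(vapply(groups, function(g) {
        all(g %in% vars) && length(vars) > length(g)
      }, TRUE))
    }
    return(list(cause = cause, effect_of = effect_of, y = 1L))
  }

  # y = 0: every conjunction has at least one 0-input; a cause takes exactly
  # one 0-input from each conjunction
  zero_choices <- lapply(groups, function(g) g[pre_state[g] == 0L])
  combos <- expand.grid(zero_choices, stringsAsFactors = FALSE)
  cause <- lapply(seq_len(nrow(combos)), function(i) {
    v <- unlist(combos[i, ], use.names = FALSE)
    stats::setNames(rep(0L, length(v)), v)
  })
  effect_of <- function(vars) {
    if (length(vars) == 0L || any(pre_state[vars] != 0L)) {
      return(FALSE)
    }
    all(vapply(groups, function(g) sum(g %in% vars) <= 1L, TRUE))
  }
  list(cause = cause, effect_of = effect_of, y = 0L)
}
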