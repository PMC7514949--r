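# Canonical joint-state enumeration. States of a variable with cardinality c
# are the integers 0..c-1. A joint state over variables (v1, ..., vn) is
# enumerated with the FIRST variable varying fastest, so that state index
# idx (1-based) encodes state s via s_j = floor((idx - 1) / prod(c_{<j})) mod c_j.

#' Enumerate all joint states of a set of discrete variables
#'
#' The canonical enumeration used everywhere in the package: one row per joint
#' state, the first variable varying fastest. Variable states are the integers
#' `0..cardinality-1`.
#'
#' @param cards integer vector of cardinalities.
#' @return an integer matrix with `prod(cards)` rows and `length(cards)`
#'   columns.
#' @examples
#' state_grid(c(2, 3))
#' @export
state_grid <- function(cards) {
  cards <- as.integer(cards)
  n <- prod(cards)
  if (length(cards) == 0L) {
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  }
  out <- matrix(0L, nrow = n, ncol = length(cards))
  rep_each <- 1L
  for (j in seq_along(cards)) {
    out[, j] <- rep(rep(0L:(cards[j] - 1L), each = rep_each), length.out = n)
    rep_each <- rep_each * cards[j]
  }
  out
}

# 1-based index of joint state(s); `states` is a vector or matrix of columns
# matching `cards`
state_index <- function(states, cards) {
  cards <- as.integer(cards)
  if (length(cards) == 0L) {
    return(1L)
  }
  if (is.null(dim(states))) states <- matrix(as.integer(states), nrow = 1L)
  mult <- cumprod(c(1L, cards[-length(cards)]))
  as.integer(states %*% mult) + 1L
}

# column of states of variable j within the canonical enumeration over `cards`
state_column <- function(j, cards) {
  state_grid(cards)[, j]
}
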