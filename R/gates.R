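#' Construct a node mechanism from a named gate type
#'
#' A mechanism is the conditional probability table of one post-tier node given
#' the states of its (pre-tier) input variables. Named gates are constructors
#' only: the mechanism is always stored extensionally as a full table, one row
#' per joint input state (first-listed input varying fastest), one column per
#' output state. This keeps the analysis engine uniform and gives multi-valued
#' variables the same code path as binary ones.
#'
#' Available gates (binary inputs/output unless noted):
#' \describe{
#'   \item{OR, AND}{n-ary disjunction / conjunction.}
#'   \item{XOR, XNOR}{parity / its complement (for two inputs: inequality /
#'     equality, the "bi-conditional").}
#'   \item{COPY}{single input, output follows it (any cardinality).}
#'   \item{NOISY_COPY}{single binary input; output equals the input with
#'     probability `p` (`params$p`), otherwise flips.}
#'   \item{MAJORITY}{1 iff strictly more than half the inputs are 1.}
#'   \item{LTU}{linear threshold unit: 1 iff at least `params$k` inputs are 1.}
#'   \item{DOC}{disjunction of conjunctions: `params$groups` is a list of
#'     character vectors partitioning `inputs`; output is 1 iff at least one
#'     group has all its inputs 1.}
#'   \item{TABLE}{explicit table: `params$table`, a numeric matrix with
#'     `prod(input_cards)` rows and `node_card` columns, rows summing to 1.}
#' }
#'
#' @param kind gate name, see Details.
#' @param inputs character vector of input (pre-tier) variable names, in the
#'   order that indexes the table rows.
#' @param node name of the post-tier node this mechanism drives.
#' @param params list of gate parameters (`p`, `k`, `groups`, `table`).
#' @param input_cards integer cardinalities of the inputs (default all binary).
#' @param node_card cardinality of the output node (default binary).
#' @return an object of class `mechanism`: a list with fields `node`, `inputs`,
#'   `table` (matrix), `gate`, `params`.
#' @examples
#' make_gate_mechanism("LTU", c("A", "B", "C", "D"), "M", params = list(k = 3))
#' make_gate_mechanism("NOISY_COPY", "A", "N", params = list(p = 0.9))
#' @export
make_gate_mechanism <- function(kind, inputs, node, params = list(),
                                input_cards = rep(2L, length(inputs)),
                                node_card = 2L) {
  kind <- toupper(kind)
  inputs <- as.character(inputs)
  n <- length(inputs)
  input_cards <- as.integer(input_cards)
  node_card <- as.integer(node_card)
  if (length(input_cards) != n) {
    abort_schema("`input_cards` must have one entry per input")
  }

  grid <- state_grid(input_cards)
  nr <- nrow(grid)
  det_out <- NULL # deterministic output state per row, if applicable

  switch(kind,
    OR = {
      require_binary(input_cards, node_card, kind, n_min = 1L)
      det_out <- as.integer(rowSums(grid) >= 1L)
    },
    AND = {
      require_binary(input_cards, node_card, kind, n_min = 1L)
      det_out <- as.integer(rowSums(grid) == n)
    },
    XOR = {
      require_binary(input_cards, node_card, kind, n_min = 1L)
      det_out <- as.integer(rowSums(grid) %% 2L == 1L)
    },
    XNOR = {
      require_binary(input_cards, node_card, kind, n_min = 1L)
      det_out <- as.integer(rowSums(grid) %% 2L == 0L)
    },
    COPY = {
      if (n != 1L) abort_schema("COPY takes exactly one input")
      if (node_card != input_cards[1L]) {
        abort_schema("COPY requires matching input and output cardinality")
      }
      det_out <- grid[, 1L]
    },
    NOISY_COPY = {
      if (n != 1L) abort_schema("NOISY_COPY takes exactly one input")
      require_binary(input_cards, node_card, kind, n_min = 1L)
      p <- params$p
      if (is.null(p) || !is.numeric(p) || p < 0 || p > 1) {
        abort_schema("NOISY_COPY requires params$p in [0, 1]")
      }
      tab <- matrix(1 - p, nrow = nr, ncol = 2L)
      tab[cbind(seq_len(nr), grid[, 1L] + 1L)] <- p
      return(new_mechanism(node, inputs, tab, kind, params))
    },
    MAJORITY = {
      require_binary(input_cards, node_card, kind)
      det_out <- as.integer(rowSums(grid) > n / 2)
    },
    LTU = {
      require_binary(input_cards, node_card, kind)
      k <- params$k
      if (is.null(k) || k < 1L || k > n) {
        abort_schema("LTU requires params$k with 1 <= k <= number of inputs")
      }
      det_out <- as.integer(rowSums(grid) >= k)
    },
    DOC = {
      require_binary(input_cards, node_card, kind)
      groups <- params$groups
      if (is.null(groups) || !is.list(groups)) {
        abort_schema("DOC requires params$groups, a list of input-name vectors")
      }
      flat <- unlist(groups, use.names = FALSE)
      if (anyDuplicated(flat) || !setequal(flat, inputs)) {
        abort_schema("DOC groups must partition the inputs")
      }
      sat <- rep(FALSE, nr)
      for (g in groups) {
        idx <- match(g, inputs)
        sat <- sat | rowSums(grid[, idx, drop = FALSE]) == length(idx)
      }
      det_out <- as.integer(sat)
    },
    TABLE = {
      tab <- params$table
      if (is.null(tab)) abort_schema("TABLE requires params$table")
      tab <- as.matrix(tab)
      if (nrow(tab) != nr || ncol(tab) != node_card) {
        abort_schema(sprintf(
          "TABLE for node '%s' must be %d x %d (got %d x %d)",
          node, nr, node_card, nrow(tab), ncol(tab)
        ))
      }
      return(new_mechanism(node, inputs, tab, kind, params))
    },
    abort_schema(sprintf("unknown gate kind '%s'", kind))
  )

  tab <- matrix(0, nrow = nr, ncol = node_card)
  tab[cbind(seq_len(nr), det_out + 1L)] <- 1
  new_mechanism(node, inputs, tab, kind, params)
}

new_mechanism <- function(node, inputs, table, gate, params = list()) {
  validate_mechanism_table(table, node)
  structure(
    list(
      node = as.character(node), inputs = inputs,
      table = unname(as.matrix(table)), gate = gate, params = params
    ),
    class = "mechanism"
  )
}

validate_mechanism_table <- function(table, node) {
  if (any(table < -PROB_TOL)) {
    abort_schema(sprintf("mechanism for '%s' has negative probabilities", node))
  }
  bad <- which(abs(rowSums(table) - 1) > PROB_TOL)
  if (length(bad)) {
    abort_schema(sprintf(
      "mechanism table for '%s' has row(s) not summing to 1: row %d sums to %.6g",
      node, bad[1L], rowSums(table)[bad[1L]]
    ))
  }
  invisible(table)
}

require_binary <- function(input_cards, node_card, kind, n_min = 2L) {
  if (length(input_cards) < n_min) {
    abort_schema(sprintf("%s requires at least %d input(s)", kind, n_min))
  }
  if (any(input_cards != 2L) || node_card != 2L) {
    abort_schema(sprintf("%s is defined for binary variables only", kind))
  }
}

#' @export
print.mechanism <- function(x, ...) {
  cat(sprintf(
    "<mechanism> %s <- %s(%s): %d x %d table\n",
    x$node, x$gate, paste(x$inputs, collapse = ", "),
    nrow(x$table), ncol(x$table)
  ))
  invisible(x)
}
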