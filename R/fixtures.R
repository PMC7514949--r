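# Worked-example networks: small logic-gate systems that exercise every part
# of the analysis (overdetermination, prevention, thresholds, disjunctions of
# conjunctions, multi-valued voting, noise, a toy classifier). Each fixture is
# a network plus its transition of interest, rebuilt programmatically.

binary_table_gate <- function(node, inputs, fn) {
  grid <- state_grid(rep(2L, length(inputs)))
  out <- apply(grid, 1L, fn)
  tab <- matrix(0, nrow = nrow(grid), ncol = 2L)
  tab[cbind(seq_len(nrow(grid)), out + 1L)] <- 1
  make_gate_mechanism("TABLE", inputs, node, params = list(table = tab))
}

fixture_builders <- function() {
  list(
    or_and_system = function() {
      net <- build_network(
        pre = c("OR", "AND"), post = c("OR", "AND"),
        mechanisms = list(
          make_gate_mechanism("OR", c("OR", "AND"), "OR"),
          make_gate_mechanism("AND", c("OR", "AND"), "AND")
        )
      )
      list(
        network = net,
        transition = make_transition(net, c(OR = 1, AND = 0), c(OR = 1, AND = 0)),
        notes = "two-node OR/AND system, transition 10 > 10"
      )
    },
    disjunction = two_input_gate_fixture("OR", "C"),
    conjunction = two_input_gate_fixture("AND", "D"),
    biconditional = two_input_gate_fixture("XNOR", "E"),
    prevention = function() {
      # F is 0 only for AB = 10: B=1 'prevents' any effect of A
      mech <- binary_table_gate("F", c("A", "B"), function(s) {
        as.integer(!(s[1] == 1 && s[2] == 0))
      })
      net <- build_network(c("A", "B"), "F", list(mech))
      list(
        network = net,
        transition = make_transition(net, c(A = 1, B = 1), c(F = 1)),
        notes = "prevention: all input states but 10 yield F=1; transition 11 > 1"
      )
    },
    majority4 = function() {
      net <- build_network(
        pre = c("A", "B", "C", "D"), post = "M",
        mechanisms = list(
          make_gate_mechanism("LTU", c("A", "B", "C", "D"), "M", params = list(k = 3))
        )
      )
      list(
        network = net,
        transition = make_transition(net, c(A = 1, B = 1, C = 1, D = 0), c(M = 1)),
        notes = "4-input majority (threshold 3), transition 1110 > 1"
      )
    },
    majority4_bg = function() {
      base <- paper_example("majority4")
      net <- condition_on_background(base$network, c(D = 0))
      list(
        network = net,
        transition = make_transition(net, c(A = 1, B = 1, C = 1), c(M = 1)),
        notes = "majority4 with D=0 as fixed background: M = AND(A,B,C)"
      )
    },
    doc = function() {
      net <- build_network(
        pre = c("A", "B", "C"), post = "D",
        mechanisms = list(
          make_gate_mechanism("DOC", c("A", "B", "C"), "D",
            params = list(groups = list(c("A", "B"), "C"))
          )
        )
      )
      list(
        network = net,
        transition = make_transition(net, c(A = 1, B = 0, C = 1), c(D = 1)),
        notes = "disjunction of conjunctions (A AND B) OR C, transition 101 > 1"
      )
    },
    doc_bg = function() {
      base <- paper_example("doc")
      net <- condition_on_background(base$network, c(B = 0))
      list(
        network = net,
        transition = make_transition(net, c(A = 1, C = 1), c(D = 1)),
        notes = "(A AND B) OR C with B=0 as fixed background: D = COPY(C)"
      )
    },
    complicated_voting = function() {
      # F = A if A == B; F = A if B == C == D == E; otherwise majority of all 5
      mech <- binary_table_gate("F", c("A", "B", "C", "D", "E"), function(s) {
        if (s[1] == s[2]) {
          s[1]
        } else if (length(unique(s[2:5])) == 1L) {
          s[1]
        } else {
          as.integer(sum(s) > 2)
        }
      })
      net <- build_network(c("A", "B", "C", "D", "E"), "F", list(mech))
      list(
        network = net,
        transition = make_transition(
          net, c(A = 1, B = 1, C = 0, D = 0, E = 0), c(F = 1)
        ),
        notes = "non-linear voting rule, transition 11000 > 1"
      )
    },
    ternary_voting = function() {
      # seven ternary voters (state s = vote for candidate s+1); W in 0..3:
      # W = c when candidate c (1..3) uniquely has the most votes, else W = 0
      voters <- LETTERS[1:7]
      grid <- state_grid(rep(3L, 7L))
      winner <- apply(grid, 1L, function(s) {
        counts <- tabulate(s + 1L, nbins = 3L)
        top <- max(counts)
        if (sum(counts == top) > 1L) 0L else which.max(counts)
      })
      tab <- matrix(0, nrow = nrow(grid), ncol = 4L)
      tab[cbind(seq_len(nrow(grid)), winner + 1L)] <- 1
      net <- build_network(
        pre = tibble::tibble(name = voters, cardinality = 3L),
        post = variable_spec("W", 4L),
        mechanisms = list(
          make_gate_mechanism("TABLE", voters, "W",
            params = list(table = tab),
            input_cards = rep(3L, 7L), node_card = 4L
          )
        )
      )
      before <- stats::setNames(c(0L, 0L, 0L, 0L, 0L, 1L, 1L), voters)
      list(
        network = net,
        transition = make_transition(net, before, c(W = 1)),
        notes = "plurality vote, 3 candidates, votes 1111122 > candidate 1 wins"
      )
    },
    noisy_copy = function() {
      net <- build_network(
        "A", "N",
        list(make_gate_mechanism("NOISY_COPY", "A", "N", params = list(p = 0.9)))
      )
      list(
        network = net,
        transition = make_transition(net, c(A = 1), c(N = 1)),
        notes = "noisy copy, p(follow) = 0.9, transition 1 > 1"
      )
    },
    noisy_copy_off = function() {
      base <- paper_example("noisy_copy")
      list(
        network = base$network,
        transition = make_transition(base$network, c(A = 1), c(N = 0)),
        notes = "noisy copy, the noise-driven transition 1 > 0 (p = 0.1)"
      )
    },
    classifier_dsl = function() {
      inputs <- c("A", "B", "C")
      dot <- binary_table_gate("D", inputs, function(s) as.integer(sum(s) == 1L))
      seg <- binary_table_gate("S", inputs, function(s) {
        as.integer(all(s == c(1, 1, 0)) || all(s == c(0, 1, 1)))
      })
      lin <- make_gate_mechanism("AND", inputs, "L")
      net <- build_network(inputs, c("D", "S", "L"), list(dot, seg, lin))
      list(
        network = net,
        transition = make_transition(
          net, c(A = 0, B = 0, C = 1), c(D = 1, S = 0, L = 0)
        ),
        notes = "dot/segment/line detectors, transition 001 > 100"
      )
    },
    xor_pin = function() {
      net <- build_network(
        c("A", "B"), "XOR",
        list(make_gate_mechanism("XOR", c("A", "B"), "XOR"))
      )
      list(
        network = net,
        transition = make_transition(net, c(A = 1, B = 0), c(XOR = 1)),
        notes = "single XOR, used for repertoire demonstrations"
      )
    },
    double_biconditional = function() {
      net <- build_network(
        pre = c("A", "B", "C"), post = c("D", "E"),
        mechanisms = list(
          make_gate_mechanism("XNOR", c("A", "B"), "D"),
          make_gate_mechanism("XNOR", c("B", "C"), "E")
        )
      )
      list(
        network = net,
        transition = make_transition(
          net, c(A = 1, B = 1, C = 1), c(D = 1, E = 1)
        ),
        notes = "two XNORs sharing input B, transition 111 > 11"
      )
    },
    reducible_or_and = function() {
      net <- build_network(
        pre = c("A", "B", "C", "D"), post = c("OR", "AND"),
        mechanisms = list(
          make_gate_mechanism("OR", c("A", "B"), "OR"),
          make_gate_mechanism("AND", c("C", "D"), "AND")
        )
      )
      list(
        network = net,
        transition = make_transition(
          net, c(A = 1, B = 0, C = 1, D = 0), c(OR = 1, AND = 0)
        ),
        notes = "OR and AND with independent inputs: no second-order link"
      )
    },
    and_xor = function() {
      net <- build_network(
        pre = c("A", "B"), post = c("AND", "XOR"),
        mechanisms = list(
          make_gate_mechanism("AND", c("A", "B"), "AND"),
          make_gate_mechanism("XOR", c("A", "B"), "XOR")
        )
      )
      list(
        network = net,
        transition = make_transition(
          net, c(A = 1, B = 1), c(AND = 1, XOR = 0)
        ),
        notes = "AND and XOR reading the same inputs, transition 11 > 10"
      )
    }
  )
}

two_input_gate_fixture <- function(gate, node) {
  force(gate)
  force(node)
  function() {
    net <- build_network(
      c("A", "B"), node,
      list(make_gate_mechanism(gate, c("A", "B"), node))
    )
    list(
      network = net,
      transition = make_transition(
        net, c(A = 1, B = 1),
        stats::setNames(transition_det_output(net, c(A = 1, B = 1), node), node)
      ),
      notes = sprintf("two-input %s gate, transition 11 > %s gate output", gate, gate)
    )
  }
}

transition_det_output <- function(net, before, node) {
  m <- net$mechanisms[[node]]
  row <- state_index(before[m$inputs], pre_cards(net)[m$inputs])
  which.max(m$table[row, ]) - 1L
}

#' Retrieve a worked-example network and transition
#'
#' @param name fixture name; see [list_examples()].
#' @return a `fixture_case`: list with `name`, `network`, `transition`,
#'   `notes`.
#' @examples
#' fx <- paper_example("doc")
#' fx$network
#' @export
paper_example <- function(name) {
  builders <- fixture_builders()
  if (!name %in% names(builders)) {
    abort_schema(sprintf(
      "unknown example '%s'; see list_examples()", name
    ))
  }
  out <- builders[[name]]()
  out$name <- name
  class(out) <- "fixture_case"
  out
}

#' @rdname paper_example
#' @return `list_examples()` returns the fixture names.
#' @export
list_examples <- function() {
  names(fixture_builders())
}

#' @export
print.fixture_case <- function(x, ...) {
  cat(sprintf("<example '%s'> %s\n", x$name, x$notes))
  print(x$network)
  print(x$transition)
  invisible(x)
}

#' Generate a reproducible random network
#'
#' Draws a random gate (from `gate_pool`) over a random nonempty input subset
#' for each post-tier node. With cardinalities other than 2, random TABLE
#' mechanisms (Dirichlet-free: normalized uniform draws) are generated instead.
#' The RNG state is restored on exit.
#'
#' @param seed integer seed.
#' @param n_pre,n_post number of pre-/post-tier variables.
#' @param cardinality shared variable cardinality (2 for logic-gate pools).
#' @param gate_pool character vector of gate kinds to sample from (binary
#'   only), or `"TABLE"` for random tables.
#' @return a `causal_network`.
#' @export
random_network <- function(seed, n_pre = 3L, n_post = 2L, cardinality = 2L,
                           gate_pool = c("OR", "AND", "XOR")) {
  if (n_pre + n_post > DEFAULT_GUARD) {
    abort_guard("random_network limited to the enumeration guard size")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)

  pre <- tibble::tibble(
    name = paste0("X", seq_len(n_pre)),
    cardinality = as.integer(cardinality)
  )
  post <- tibble::tibble(
    name = paste0("Y", seq_len(n_post)),
    cardinality = as.integer(cardinality)
  )
  mechanisms <- lapply(post$name, function(nd) {
    k <- sample.int(n_pre, 1L)
    inputs <- sort(sample(pre$name, k))
    kind <- sample(gate_pool, 1L)
    if (cardinality != 2L || kind == "TABLE") {
      nr <- cardinality^length(inputs)
      tab <- matrix(stats::runif(nr * cardinality), nrow = nr)
      tab <- tab / rowSums(tab)
      make_gate_mechanism("TABLE", inputs, nd,
        params = list(table = tab),
        input_cards = rep(cardinality, length(inputs)),
        node_card = cardinality
      )
    } else {
      params <- if (kind == "LTU") list(k = sample.int(length(inputs), 1L)) else list()
      if (kind %in% c("COPY", "NOISY_COPY") && length(inputs) > 1L) {
        inputs <- inputs[1L]
      }
      if (kind == "NOISY_COPY") params <- list(p = stats::runif(1, 0.6, 0.95))
      make_gate_mechanism(kind, inputs, nd, params = params)
    }
  })
  build_network(pre, post, mechanisms)
}
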