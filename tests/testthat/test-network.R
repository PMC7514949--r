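state_index_for_test <- function(bits) {
  sum(bits * 2^(seq_along(bits) - 1)) + 1
}

test_that("gate constructors produce correct deterministic tables", {
  ltu <- make_gate_mechanism("LTU", paste0("I", 1:4), "Y", params = list(k = 3))
  # row for input 1110 (first input varies fastest in the enumeration)
  row <- ltu$table[1 + 1 + 2 + 4, ]
  expect_equal(row, c(0, 1)) # three active inputs reach the threshold
  expect_equal(ltu$table[1 + 1 + 2, ], c(1, 0)) # 1100 stays below it
  expect_true(all(ltu$table %in% c(0, 1)))

  nc <- make_gate_mechanism("NOISY_COPY", "A", "N", params = list(p = 0.9))
  expect_equal(nc$table[2, ], c(0.1, 0.9)) # input 1 follows with p = 0.9

  doc <- make_gate_mechanism("DOC", c("A", "B", "C"), "D",
    params = list(groups = list(c("A", "B"), "C"))
  )
  idx <- function(s) state_index_for_test(s)
  expect_equal(doc$table[idx(c(1, 0, 1)), 2], 1) # C alone satisfies (A&B)|C
  expect_equal(doc$table[idx(c(1, 0, 0)), 2], 0) # A without B or C does not
  expect_equal(doc$table[idx(c(1, 1, 0)), 2], 1)

  xnor <- make_gate_mechanism("XNOR", c("A", "B"), "E")
  expect_equal(xnor$table[, 2], c(1, 0, 0, 1))
})

test_that("gate constructors reject malformed parameters", {
  expect_error(
    make_gate_mechanism("FROB", c("A", "B"), "Y"),
    class = "actualcause_schema_error"
  )
  expect_error(
    make_gate_mechanism("LTU", c("A", "B"), "Y", params = list(k = 3)),
    class = "actualcause_schema_error"
  )
  expect_error(
    make_gate_mechanism("DOC", c("A", "B", "C"), "Y",
      params = list(groups = list("A", "B")) # C not covered
    ),
    class = "actualcause_schema_error"
  )
  expect_error(
    make_gate_mechanism("TABLE", "A", "Y",
      params = list(table = matrix(c(0.5, 0.4, 0.3, 0.7), nrow = 2))
    ),
    class = "actualcause_schema_error"
  )
})

test_that("build_network validates its parts", {
  expect_s3_class(paper_example("or_and_system")$network, "causal_network")
  mech <- make_gate_mechanism("OR", c("A", "B"), "C")
  expect_error(
    build_network(c("A", "B"), c("C", "D"), list(mech)),
    class = "actualcause_schema_error"
  ) # D lacks a mechanism
  expect_error(
    build_network(c("A", "A"), "C", list(mech)),
    class = "actualcause_schema_error"
  )
  expect_error(
    build_network("A", "C", list(mech)), # references unknown B
    class = "actualcause_schema_error"
  )
  # ternary seven-voter network with a 4-state output is valid
  expect_s3_class(paper_example("ternary_voting")$network, "causal_network")
})

test_that("transition probabilities multiply mechanism factors", {
  net <- paper_example("or_and_system")$network
  expect_equal(transition_probability(net, c(OR = 1, AND = 0), c(OR = 1, AND = 0)), 1)
  expect_equal(transition_probability(net, c(OR = 1, AND = 0), c(OR = 0, AND = 1)), 0)
  nc <- paper_example("noisy_copy")$network
  expect_equal(transition_probability(nc, c(A = 1), c(N = 1)), 0.9)
  expect_equal(transition_probability(nc, c(A = 1), c(N = 0)), 0.1)
  expect_error(
    transition_probability(net, c(OR = 2, AND = 0), c(OR = 1, AND = 0)),
    class = "actualcause_schema_error"
  )
})

test_that("transition probabilities over all post states sum to one", {
  nets <- list(
    paper_example("classifier_dsl")$network,
    paper_example("ternary_voting")$network,
    random_network(7, n_pre = 3, n_post = 3, gate_pool = c("OR", "AND", "XOR", "NOISY_COPY")),
    random_network(8, n_pre = 2, n_post = 2, cardinality = 3)
  )
  for (net in nets) {
    pre_grid <- state_grid(net$pre$cardinality)
    post_grid <- state_grid(net$post$cardinality)
    for (r in seq_len(nrow(pre_grid))) {
      pre <- stats::setNames(pre_grid[r, ], net$pre$name)
      tot <- sum(apply(post_grid, 1, function(ps) {
        transition_probability(net, pre, stats::setNames(ps, net$post$name))
      }))
      expect_equal(tot, 1, tolerance = 1e-9)
    }
  }
})

test_that("realization principle is enforced", {
  fx <- paper_example("or_and_system")
  expect_silent(validate_transition(fx$network, fx$transition))
  copy_net <- build_network("A", "B", list(make_gate_mechanism("COPY", "A", "B")))
  expect_error(
    make_transition(copy_net, c(A = 1), c(B = 0)),
    class = "actualcause_realization_error"
  )
  # the probabilistic counterpart is realizable
  nc <- paper_example("noisy_copy")$network
  expect_s3_class(make_transition(nc, c(A = 1), c(N = 0)), "transition")
})

test_that("background conditioning restricts mechanisms and records the pin", {
  fx <- paper_example("majority4")
  cond <- condition_on_background(fx$network, c(D = 0))
  expect_setequal(cond$pre$name, c("A", "B", "C"))
  expect_equal(cond$background, c(D = 0L))
  # with D pinned to 0 the gate fires only on A=B=C=1
  grid <- state_grid(rep(2L, 3))
  for (r in seq_len(nrow(grid))) {
    s <- stats::setNames(grid[r, ], c("A", "B", "C"))
    expect_equal(
      transition_probability(cond, s, c(M = 1)),
      transition_probability(fx$network, c(s, D = 0L), c(M = 1))
    )
  }
  # DOC with B pinned to 0 reduces to D = COPY(C)
  dfx <- paper_example("doc_bg")
  expect_equal(transition_probability(dfx$network, c(A = 1, C = 1), c(D = 1)), 1)
  expect_equal(transition_probability(dfx$network, c(A = 1, C = 0), c(D = 1)), 0)
  # conditioning errors
  expect_error(
    condition_on_background(fx$network, c(M = 0)),
    class = "actualcause_schema_error"
  )
  expect_error(
    condition_on_background(fx$network, c(D = 5)),
    class = "actualcause_schema_error"
  )
  expect_identical(condition_on_background(fx$network, integer()), fx$network)
})

test_that("conditioned and pinned transition probabilities agree on random nets", {
  for (seed in 1:4) {
    net <- random_network(seed, n_pre = 4, n_post = 2, gate_pool = c("OR", "AND", "XOR"))
    pin <- c(X1 = seed %% 2L)
    cond <- condition_on_background(net, pin)
    grid <- state_grid(rep(2L, 3))
    post_grid <- state_grid(rep(2L, 2))
    for (r in seq_len(nrow(grid))) {
      s <- stats::setNames(grid[r, ], c("X2", "X3", "X4"))
      for (q in seq_len(nrow(post_grid))) {
        ps <- stats::setNames(post_grid[q, ], c("Y1", "Y2"))
        expect_equal(
          transition_probability(cond, s, ps),
          transition_probability(net, c(pin, s), ps)
        )
      }
    }
  }
})
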