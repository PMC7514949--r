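or_and <- paper_example("or_and_system")

test_that("cause and effect information reproduce the OR/AND values", {
  net <- or_and$network
  tr <- or_and$transition
  expect_equal(information(net, tr, "OR", "OR", "effect"), log2(1 / 0.75),
    tolerance = 1e-12
  ) # 0.415 bits
  expect_equal(information(net, tr, "OR", "OR", "cause"), log2((1 / 3) / 0.25),
    tolerance = 1e-12
  ) # 0.415 bits, the mirrored link
  # {OR_{t-1}=1} lowers the probability of {AND_t=0}: negative information
  expect_equal(information(net, tr, "OR", "AND", "effect"), log2(0.5 / 0.75),
    tolerance = 1e-12
  )
  # conditioning on the empty set never carries information
  expect_equal(information(net, tr, character(0), "OR", "effect"), 0)
  expect_equal(information(net, tr, "OR", character(0), "cause"), 0)
})

test_that("MIP search reproduces the second-order OR/AND results", {
  net <- or_and$network
  tr <- or_and$transition
  # irreducible second-order cause: intact 1/2 vs partitioned 4/9
  rec <- find_mip(net, tr, c("OR", "AND"), c("OR", "AND"), "cause")
  expect_equal(rec$alpha, log2((1 / 2) / (4 / 9)), tolerance = 1e-12) # 0.17
  expect_equal(round(rec$alpha, 2), 0.17)
  # the reverse effect link is fully reducible
  rec_e <- find_mip(net, tr, c("OR", "AND"), c("OR", "AND"), "effect")
  expect_equal(rec_e$alpha, 0)
  # singleton occurrences: alpha equals rho
  rec_1 <- find_mip(net, tr, "OR", "OR", "effect")
  expect_equal(rec_1$alpha, rec_1$rho)
  expect_equal(round(rec_1$alpha, 3), 0.415)
})

test_that("alpha_max applies exclusion and minimality", {
  net <- or_and$network
  tr <- or_and$transition
  am <- alpha_max(net, tr, "OR", "cause")
  expect_equal(round(am$alpha_max, 3), 0.415)
  # the superset {(OR,AND)_{t-1}=10} ties but is removed by minimality
  expect_candidates(am$candidates, "OR=1")
  tied <- am$table$alpha[am$table$candidate == "OR,AND"]
  expect_equal(tied, am$alpha_max, tolerance = 1e-9)

  # symmetric overdetermination: two tied, non-nested minimal causes
  fx <- paper_example("disjunction")
  am2 <- alpha_max(fx$network, fx$transition, "C", "cause")
  expect_equal(round(am2$alpha_max, 3), 0.415)
  expect_candidates(am2$candidates, c("A=1", "B=1"))

  # XNOR: single inputs carry zero effect information, no actual effect
  fx3 <- paper_example("biconditional")
  am3 <- alpha_max(fx3$network, fx3$transition, "A", "effect")
  expect_equal(am3$alpha_max, 0)
  expect_length(am3$candidates, 0L)
})

test_that("actual causes match the worked examples", {
  fx <- paper_example("conjunction")
  lk <- actual_cause(fx$network, fx$transition, "D")
  expect_equal(lk$alpha_max, 2)
  expect_candidates(lk$candidates, "A=1,B=1")

  fx <- paper_example("doc")
  lk <- actual_cause(fx$network, fx$transition, "D")
  expect_equal(round(lk$alpha_max, 3), 0.678)
  expect_candidates(lk$candidates, "C=1")

  fx <- paper_example("classifier_dsl")
  lk <- actual_cause(fx$network, fx$transition, "L")
  expect_candidates(lk$candidates, c("A=0", "B=0")) # indeterminate

  # reducible occurrences have no link
  fx <- paper_example("biconditional")
  expect_null(actual_effect(fx$network, fx$transition, "A"))
})

test_that("alpha is bounded by rho and unchanged by unconstrained extensions", {
  cases <- list(
    c("or_and_system", "cause"), c("or_and_system", "effect"),
    c("doc", "cause"), c("classifier_dsl", "cause"),
    c("double_biconditional", "effect"), c("and_xor", "effect")
  )
  for (cs in cases) {
    fx <- paper_example(cs[1])
    dir <- cs[2]
    occ_tier_vars <- if (dir == "effect") fx$network$pre$name else fx$network$post$name
    cand_tier_vars <- if (dir == "effect") fx$network$post$name else fx$network$pre$name
    for (ov in nonempty_subsets(occ_tier_vars)) {
      for (cv in nonempty_subsets(cand_tier_vars)) {
        rec <- find_mip(fx$network, fx$transition, ov, cv, dir)
        expect_lte(rec$alpha, rec$rho + 1e-12)
        if (length(ov) == 1L) expect_equal(rec$alpha, rec$rho, tolerance = 1e-12)
      }
      am <- alpha_max(fx$network, fx$transition, ov, dir)
      expect_gte(am$alpha_max, 0)
      # extending a winning candidate by a variable the occurrence leaves
      # unconstrained (its single-variable repertoire stays at the
      # unconstrained distribution) does not change alpha
      if (am$alpha_max > 0) {
        occ_states <- occurrence(
          fx$transition, ov, if (dir == "effect") "pre" else "post"
        )
        unconstrained_var <- function(v) {
          r1 <- if (dir == "effect") {
            effect_repertoire(fx$network, occ_states, v)
          } else {
            cause_repertoire(fx$network, occ_states, v)
          }
          r0 <- if (dir == "effect") {
            effect_repertoire(fx$network, integer(), v)
          } else {
            cause_repertoire(fx$network, integer(), v)
          }
          isTRUE(all.equal(r1$prob, r0$prob, tolerance = 1e-12))
        }
        for (cand in am$candidates) {
          extra <- Filter(unconstrained_var, setdiff(cand_tier_vars, names(cand)))
          for (v in extra) {
            rec_ext <- find_mip(
              fx$network, fx$transition, ov, c(names(cand), v), dir
            )
            expect_equal(rec_ext$alpha, am$alpha_max, tolerance = 1e-8)
          }
        }
      }
    }
  }
})

test_that("the OR/AND causal account contains exactly its five links", {
  acc <- causal_account(or_and$network, or_and$transition)
  expect_setequal(
    link_labels(acc),
    c(
      "effect {OR=1} {OR=1}",
      "effect {AND=0} {AND=0}",
      "cause {OR=1} {OR=1}",
      "cause {AND=0} {AND=0}",
      "cause {OR=1,AND=0} {OR=1,AND=0}"
    )
  )
  # direction asymmetry: the second-order link exists on the cause side only
  td <- tidy(acc)
  expect_false(any(td$direction == "effect" & td$order == 2))
  expect_gt(acc$A, 0)
})

test_that("prevention yields a reducible account without the idle variable", {
  fx <- paper_example("prevention")
  acc <- causal_account(fx$network, fx$transition)
  td <- tidy(acc)
  expect_equal(nrow(td), 2L)
  expect_false(any(grepl("A=", td$occurrence)) || any(grepl("A=", td$candidates)))
  expect_equal(acc$A, 0)
})

test_that("independent-input OR/AND keeps first-order links but loses the joint one", {
  fx <- paper_example("reducible_or_and")
  acc <- causal_account(fx$network, fx$transition)
  td <- tidy(acc)
  expect_setequal(
    link_labels(acc),
    c(
      "effect {A=1} {OR=1}",
      "effect {D=0} {AND=0}",
      "cause {OR=1} {A=1}",
      "cause {AND=0} {D=0}"
    )
  )
  expect_equal(acc$A, 0)
})

test_that("background conditioning preserves majority-4 links and raises alphas", {
  fxa <- paper_example("majority4")
  fxb <- paper_example("majority4_bg")
  ta <- tidy(causal_account(fxa$network, fxa$transition))
  tb <- tidy(causal_account(fxb$network, fxb$transition))
  key <- function(td) paste(td$direction, td$occurrence, td$candidates)
  expect_setequal(key(ta), key(tb))
  merged <- merge(
    data.frame(k = key(ta), a = ta$alpha),
    data.frame(k = key(tb), b = tb$alpha)
  )
  expect_true(all(merged$b > merged$a + 1e-9))
})

test_that("the double biconditional composes first- and second-order causes", {
  fx <- paper_example("double_biconditional")
  acc <- causal_account(fx$network, fx$transition)
  expect_setequal(
    link_labels(acc),
    c(
      "effect {A=1,B=1} {D=1}",
      "effect {B=1,C=1} {E=1}",
      "effect {A=1,B=1,C=1} {D=1,E=1}",
      "cause {D=1} {A=1,B=1}",
      "cause {E=1} {B=1,C=1}",
      "cause {D=1,E=1} {A=1,B=1,C=1}"
    )
  )
})

test_that("the classifier account matches the printed causal links", {
  fx <- paper_example("classifier_dsl")
  acc <- causal_account(fx$network, fx$transition)
  labels <- link_labels(acc)
  td <- tidy(acc)
  # effects listed for this transition
  expect_true("effect {A=0} {D=1,L=0}" %in% labels)
  expect_true("effect {B=0} {D=1,S=0,L=0}" %in% labels)
  expect_true("effect {A=0,B=0,C=1} {D=1}" %in% labels)
  # {C=1} by itself has no actual effect (a dot needs the 0s around it)
  expect_false(any(td$direction == "effect" & td$occurrence == "{C=1}"))
  # every subset of the output state has its own actual cause
  expect_equal(sum(td$direction == "cause"), 7L)
  expect_true("cause {D=1} {A=0,B=0,C=1}" %in% labels)
  expect_true("cause {S=0} {B=0}" %in% labels)
  expect_true("cause {L=0} {A=0} / {B=0}" %in% labels)
  expect_true("cause {D=1,S=0} {B=0}" %in% labels)
})

test_that("fig-17 style minimality picks the first-order effect", {
  fx <- paper_example("and_xor")
  lk_c <- actual_cause(fx$network, fx$transition, "AND")
  expect_equal(lk_c$alpha_max, 2)
  expect_candidates(lk_c$candidates, "A=1,B=1")
  lk_e <- actual_effect(fx$network, fx$transition, "A")
  expect_equal(lk_e$alpha_max, 1)
  expect_candidates(lk_e$candidates, "AND=1")
  # the tied superset {(AND,XOR)=(1,0)} is excluded by minimality
  tied <- lk_e$table$alpha[lk_e$table$candidate == "AND,XOR"]
  expect_equal(tied, 1, tolerance = 1e-9)
})

test_that("the enumeration guard rejects oversized networks", {
  big <- build_network(
    paste0("X", 1:12), "Y",
    list(make_gate_mechanism("OR", paste0("X", 1:12), "Y"))
  )
  tr <- make_transition(big, stats::setNames(rep(1L, 12), paste0("X", 1:12)), c(Y = 1))
  expect_error(causal_account(big, tr), class = "actualcause_guard_error")
  # the guard is a deliberate dial, not a hard limit
  fx <- paper_example("majority4")
  expect_error(
    causal_account(fx$network, fx$transition, max_vars = 3),
    class = "actualcause_guard_error"
  )
  expect_s3_class(
    causal_account(fx$network, fx$transition, max_vars = 5),
    "causal_account"
  )
})
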