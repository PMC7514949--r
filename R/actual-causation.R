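# Information, integration (MIP), exclusion and minimality.
#
# Conventions: `direction = "effect"` means the occurrence lives on the pre
# tier and candidates on the post tier (does x bring about y?); "cause" means
# the occurrence lives on the post tier and candidates on the pre tier (what
# brought y about?). All information values are log base 2, in bits.

occ_from <- function(transition, vars, direction, role = c("occurrence", "candidate")) {
  role <- match.arg(role)
  pre_side <- (direction == "effect") == (role == "occurrence")
  occurrence(transition, vars, tier = if (pre_side) "pre" else "post")
}

candidate_tier_state <- function(transition, direction) {
  if (direction == "effect") transition$after else transition$before
}

#' Cause / effect information of an occurrence about a candidate
#'
#' The effect information of a pre-tier occurrence about a candidate post-tier
#' occurrence is the log2 ratio of the candidate state's probability in the
#' occurrence's effect repertoire to its unconstrained probability; cause
#' information is the mirror image on the cause side. Positive values mean the
#' occurrence raises the probability of the candidate's actual state; the
#' value is 0 whenever either side is empty, and may be negative.
#'
#' @param net a [build_network()] object.
#' @param transition a [make_transition()] object.
#' @param occ_vars,candidate_vars character vectors of variable names (either
#'   may be empty); the occurrence is on the pre tier for
#'   `direction = "effect"` and on the post tier for `"cause"`, the candidate
#'   on the opposite tier. States are read from the transition.
#' @param direction `"cause"` or `"effect"`.
#' @return information in bits (a scalar).
#' @examples
#' fx <- paper_example("or_and_system")
#' information(fx$network, fx$transition, "OR", "OR", "effect") # 0.415 bits
#' @export
information <- function(net, transition, occ_vars, candidate_vars,
                        direction = c("cause", "effect")) {
  direction <- match.arg(direction)
  if (length(occ_vars) == 0L || length(candidate_vars) == 0L) {
    return(0)
  }
  occ <- occ_from(transition, occ_vars, direction, "occurrence")
  cand <- occ_from(transition, candidate_vars, direction, "candidate")
  purview <- names(cand)
  cards <- if (direction == "effect") post_cards(net) else pre_cards(net)
  p1 <- prob_at(rep_vec(net, occ, purview, direction), purview, cards, cand)
  p0 <- prob_at(
    rep_vec(net, stats::setNames(integer(0), character(0)), purview, direction),
    purview, cards, cand
  )
  log2(p1 / p0)
}

#' Minimum information partition of a candidate causal link
#'
#' Enumerates every permissible partition of the occurrence (paired with the
#' candidate's variables as purview), and returns the one that reduces the
#' cause/effect information the least. The integrated information alpha is the
#' log2 ratio of the intact to the partitioned repertoire probability of the
#' candidate's actual state under that partition; for singleton occurrences the
#' only partition is the full cut, so alpha equals the plain information rho.
#'
#' @inheritParams information
#' @return a `mip_record`: list with `partition`, `rho`, `rho_partitioned`,
#'   `alpha` (bits).
#' @export
find_mip <- function(net, transition, occ_vars, candidate_vars,
                     direction = c("cause", "effect")) {
  direction <- match.arg(direction)
  if (length(occ_vars) == 0L) {
    abort_schema("find_mip() needs a nonempty occurrence")
  }
  occ <- occ_from(transition, occ_vars, direction, "occurrence")
  cand <- occ_from(transition, candidate_vars, direction, "candidate")
  purview <- names(cand)
  cards <- if (direction == "effect") post_cards(net) else pre_cards(net)

  intact <- prob_at(rep_vec(net, occ, purview, direction), purview, cards, cand)
  uncon <- prob_at(
    rep_vec(net, stats::setNames(integer(0), character(0)), purview, direction),
    purview, cards, cand
  )
  q <- length(occ)
  p <- length(purview)

  if (p == 0L) {
    # empty candidate: pi(empty) = 1 on both sides, no information either way
    full_cut <- enumerate_partitions(names(occ), character(), direction)[[1L]]
    return(structure(
      list(
        partition = full_cut, rho = 0, rho_partitioned = 0, alpha = 0,
        occurrence = occ, candidate = cand, direction = direction
      ),
      class = "mip_record"
    ))
  }
  rho <- log2(intact / uncon)

  # Because parts have disjoint purviews (and the cause-side joint
  # renormalization is the identity for products of per-part distributions over
  # disjoint variable sets), a partitioned repertoire's probability at the
  # actual state is a product of per-part scalars. Precompute
  # g[occurrence block, purview subset] once and score every partition as a
  # product; the MIP maximizes that probability (least information lost).
  g <- matrix(NA_real_, nrow = 2^q, ncol = 2^p)
  g_at <- function(bo, bp) {
    v <- g[bo + 1L, bp + 1L]
    if (is.na(v)) {
      sub_occ <- occ[bitwAnd(bo, 2^(seq_len(q) - 1L)) > 0L]
      sub_pv <- purview[bitwAnd(bp, 2^(seq_len(p) - 1L)) > 0L]
      v <- if (length(sub_pv) == 0L) {
        1
      } else {
        prob_at(rep_vec(net, sub_occ, sub_pv, direction), sub_pv, cards, cand)
      }
      g[bo + 1L, bp + 1L] <<- v
    }
    v
  }

  full_pv <- 2^p - 1L
  best_prob <- g_at(0L, full_pv) # the full cut: everything unconstrained
  best_rg <- NULL
  best_assign <- NULL
  if (q >= 2L) {
    pv_bit <- 2^(seq_len(p) - 1L)
    for (rg in set_partitions(q)) {
      m <- max(rg)
      if (m < 2L) next
      block_bm <- vapply(1L:m, function(b) sum(2^(which(rg == b) - 1L)), 0)
      assign_grid <- state_grid(rep(m + 1L, p)) # block 0..m-1, m = leftover
      for (r in seq_len(nrow(assign_grid))) {
        a <- assign_grid[r, ]
        prob <- g_at(0L, sum(pv_bit[a == m])) # leftover, unconstrained
        for (b in 1L:m) {
          prob <- prob * g_at(block_bm[b], sum(pv_bit[a == (b - 1L)]))
        }
        if (prob > best_prob * (1 + PROB_TOL)) {
          best_prob <- prob
          best_rg <- rg
          best_assign <- a
        }
      }
    }
  }

  best <- if (is.null(best_rg)) {
    enumerate_partitions(names(occ), purview, direction)[[1L]]
  } else {
    m <- max(best_rg)
    new_partition(
      lapply(1L:m, function(b) {
        list(
          occurrence = names(occ)[best_rg == b],
          purview = purview[best_assign == (b - 1L)]
        )
      }),
      direction, names(occ), purview
    )
  }
  best_alpha <- log2(intact / best_prob)
  structure(
    list(
      partition = best, rho = rho,
      rho_partitioned = rho - best_alpha, alpha = best_alpha,
      occurrence = occ, candidate = cand, direction = direction
    ),
    class = "mip_record"
  )
}

#' @export
print.mip_record <- function(x, ...) {
  cat(sprintf(
    "<mip> %s %s %s: rho = %.6f, alpha = %.6f bits\n",
    fmt_occurrence(x$occurrence),
    if (x$direction == "effect") "->" else "<-",
    fmt_occurrence(x$candidate), x$rho, x$alpha
  ))
  print(x$partition)
  invisible(x)
}

all_subsets <- function(vars) {
  n <- length(vars)
  unlist(lapply(seq_len(n), function(k) {
    utils::combn(vars, k, simplify = FALSE)
  }), recursive = FALSE)
}

#' Maximally irreducible candidates of an occurrence
#'
#' Evaluates the integrated cause (or effect) information of the occurrence
#' over every nonempty sub-state of the opposite tier's actual state, takes
#' the maximum (the empty candidate supplies a floor of 0), and keeps the
#' candidates achieving it that have no strictly smaller candidate also
#' achieving it (minimality). More than one surviving candidate means the
#' actual cause/effect is indeterminate.
#'
#' @inheritParams information
#' @param occ_vars nonempty character vector naming the occurrence.
#' @return list with `alpha_max` (bits, >= 0), `candidates` (list of named
#'   state vectors; empty when `alpha_max` is 0), `mips` (their `mip_record`s)
#'   and `table` (tibble of every candidate's alpha, for diagnostics).
#' @export
alpha_max <- function(net, transition, occ_vars,
                      direction = c("cause", "effect")) {
  direction <- match.arg(direction)
  if (length(occ_vars) == 0L) {
    abort_schema("alpha_max() needs a nonempty occurrence")
  }
  opp_state <- candidate_tier_state(transition, direction)
  cands <- all_subsets(names(opp_state))
  mips <- lapply(cands, function(cv) {
    find_mip(net, transition, occ_vars, cv, direction)
  })
  alphas <- vapply(mips, `[[`, 0, "alpha")
  table <- tibble::tibble(
    candidate = vapply(cands, paste, "", collapse = ","),
    size = lengths(cands),
    alpha = alphas
  )
  amax <- max(c(0, alphas))
  if (amax <= ALPHA_TOL) {
    return(list(
      alpha_max = 0, candidates = list(), mips = list(), table = table
    ))
  }
  win <- which(alphas >= amax - ALPHA_TOL)
  # minimality: drop any winner that strictly contains another winner
  minimal <- win[vapply(win, function(i) {
    !any(vapply(win, function(j) {
      i != j && length(cands[[j]]) < length(cands[[i]]) &&
        all(cands[[j]] %in% cands[[i]])
    }, TRUE))
  }, TRUE)]
  list(
    alpha_max = amax,
    candidates = lapply(minimal, function(i) {
      occ_from(transition, cands[[i]], direction, "candidate")
    }),
    mips = mips[minimal],
    table = table
  )
}

new_causal_link <- function(direction, occ, am) {
  structure(
    list(
      direction = direction,
      occurrence = occ,
      alpha_max = am$alpha_max,
      candidates = am$candidates,
      mips = am$mips,
      table = am$table
    ),
    class = "causal_link"
  )
}

#' Actual cause and actual effect of an occurrence
#'
#' `actual_cause()` finds the maximally irreducible, minimal candidate cause(s)
#' of a post-tier occurrence; `actual_effect()` the candidate effect(s) of a
#' pre-tier occurrence. Three outcomes are possible: a unique candidate (the
#' actual cause/effect), several tied non-nested candidates (indeterminate), or
#' none (`NULL`; the occurrence is reducible, `alpha_max = 0`).
#'
#' @inheritParams information
#' @param occ_vars nonempty character vector naming the occurrence (post-tier
#'   variables for `actual_cause()`, pre-tier for `actual_effect()`).
#' @return a `causal_link` (fields `direction`, `occurrence`, `alpha_max`,
#'   `candidates`, `mips`, `table`) or `NULL` when the occurrence is reducible.
#' @examples
#' fx <- paper_example("conjunction")
#' actual_cause(fx$network, fx$transition, "D") # {A=1,B=1} at 2 bits
#' @export
actual_cause <- function(net, transition, occ_vars) {
  am <- alpha_max(net, transition, occ_vars, "cause")
  if (am$alpha_max <= ALPHA_TOL) {
    return(NULL)
  }
  new_causal_link("cause", occ_from(transition, occ_vars, "cause", "occurrence"), am)
}

#' @rdname actual_cause
#' @export
actual_effect <- function(net, transition, occ_vars) {
  am <- alpha_max(net, transition, occ_vars, "effect")
  if (am$alpha_max <= ALPHA_TOL) {
    return(NULL)
  }
  new_causal_link("effect", occ_from(transition, occ_vars, "effect", "occurrence"), am)
}

#' @export
print.causal_link <- function(x, ...) {
  arrow <- if (x$direction == "effect") "->" else "<-"
  cand <- vapply(x$candidates, fmt_occurrence, "")
  cat(sprintf(
    "<causal link> %s %s %s  (alpha = %.6f bits%s)\n",
    fmt_occurrence(x$occurrence), arrow,
    paste(cand, collapse = " / "), x$alpha_max,
    if (length(x$candidates) > 1L) ", indeterminate" else ""
  ))
  invisible(x)
}
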