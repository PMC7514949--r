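# Partitions of an occurrence and the purview it constrains.
#
# A partition severs the joint constraints of an occurrence on its purview:
# the occurrence variables are split into m >= 2 blocks, each purview variable
# is assigned to one block or left over (unconstrained), and the repertoire is
# recomputed part by part. The special "full cut" pairs the whole occurrence
# with the empty purview, so singleton occurrences have exactly one partition.

# all set-partitions of 1..n as restricted-growth strings (block id per
# element); memoized, the same sizes recur constantly
.set_partition_memo <- new.env(parent = emptyenv())

set_partitions <- function(n) {
  if (n == 0L) {
    return(list())
  }
  key <- as.character(n)
  hit <- .set_partition_memo[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  out <- list(1L)
  if (n > 1L) {
    for (i in 2L:n) {
      nxt <- vector("list", 0L)
      for (p in out) {
        m <- max(p)
        for (b in 1L:(m + 1L)) nxt[[length(nxt) + 1L]] <- c(p, b)
      }
      out <- nxt
    }
  }
  .set_partition_memo[[key]] <- out
  out
}

new_partition <- function(parts, direction, occurrence_vars, purview_vars) {
  claimed <- unlist(lapply(parts, `[[`, "purview"), use.names = FALSE)
  structure(
    list(
      direction = direction,
      parts = parts,
      leftover_purview = setdiff(purview_vars, claimed),
      occurrence_vars = occurrence_vars,
      purview_vars = purview_vars
    ),
    class = "link_partition"
  )
}

#' Enumerate permissible partitions of an occurrence over a purview
#'
#' Returns the full cut (whole occurrence paired with the empty purview) plus,
#' for every split of the occurrence variables into m >= 2 blocks, every
#' assignment of each purview variable to one of the blocks or to the leftover
#' (unconstrained) set. Occurrence blocks are never empty; purview parts may
#' be. Splits with a single block (other than the full cut) are not partitions.
#'
#' @param occurrence_vars nonempty character vector.
#' @param purview_vars character vector (may be empty).
#' @param direction `"cause"` or `"effect"` (recorded on each partition).
#' @return list of `link_partition` objects; each has `parts` (list of
#'   `occurrence`/`purview` name pairs) and `leftover_purview`.
#' @export
enumerate_partitions <- function(occurrence_vars, purview_vars,
                                 direction = c("cause", "effect")) {
  direction <- match.arg(direction)
  q <- length(occurrence_vars)
  if (q == 0L) {
    abort_schema("cannot partition an empty occurrence")
  }
  full_cut <- new_partition(
    list(list(occurrence = occurrence_vars, purview = character())),
    direction, occurrence_vars, purview_vars
  )
  out <- list(full_cut)
  if (q == 1L) {
    return(out)
  }
  p <- length(purview_vars)
  for (rg in set_partitions(q)) {
    m <- max(rg)
    if (m < 2L) next
    blocks <- lapply(1L:m, function(b) occurrence_vars[rg == b])
    # each purview variable goes to one of the m blocks or to leftover (m + 1)
    assign_grid <- state_grid(rep(m + 1L, p)) # values 0..m; m = leftover
    for (r in seq_len(nrow(assign_grid))) {
      a <- assign_grid[r, ]
      parts <- lapply(1L:m, function(b) {
        list(
          occurrence = blocks[[b]],
          purview = purview_vars[a == (b - 1L)]
        )
      })
      out[[length(out) + 1L]] <- new_partition(
        parts, direction, occurrence_vars, purview_vars
      )
    }
  }
  out
}

#' @export
print.link_partition <- function(x, ...) {
  parts <- vapply(x$parts, function(p) {
    sprintf(
      "(%s / %s)",
      paste(p$occurrence, collapse = ","),
      if (length(p$purview)) paste(p$purview, collapse = ",") else "-"
    )
  }, "")
  cat(
    "<partition>", paste(parts, collapse = " x "),
    if (length(x$leftover_purview)) {
      paste0("[leftover: ", paste(x$leftover_purview, collapse = ","), "]")
    } else {
      ""
    }, "\n"
  )
  invisible(x)
}

# repertoire lookup memoized per MIP search: the same (sub-occurrence,
# purview-part) pairs recur across partitions
rep_vec_cached <- function(net, occ, purview, direction, cache = NULL) {
  if (is.null(cache)) {
    return(rep_vec(net, occ, purview, direction))
  }
  key <- paste(
    direction, paste0(names(occ), "=", occ, collapse = ";"),
    paste(purview, collapse = ","),
    sep = "|"
  )
  val <- cache[[key]]
  if (is.null(val)) {
    val <- rep_vec(net, occ, purview, direction)
    cache[[key]] <- val
  }
  val
}

# partitioned repertoire as a plain probability vector over the full purview
partitioned_vec <- function(net, occ, purview, partition, cache = NULL) {
  direction <- partition$direction
  cards_all <- if (direction == "effect") post_cards(net) else pre_cards(net)
  cards <- cards_all[purview]
  grid <- state_grid(cards)
  out <- rep(1, nrow(grid))

  mult_in <- function(out, vars, probs) {
    pos <- match(vars, purview)
    idx <- state_index(grid[, pos, drop = FALSE], cards[pos])
    out * probs[idx]
  }

  for (part in partition$parts) {
    if (length(part$purview) == 0L) next # pi(empty) = 1
    sub_occ <- occ[intersect(names(occ), part$occurrence)]
    probs <- rep_vec_cached(net, sub_occ, part$purview, direction, cache)
    out <- mult_in(out, part$purview, probs)
  }
  lv <- partition$leftover_purview
  if (length(lv)) {
    probs <- rep_vec_cached(
      net, stats::setNames(integer(0), character(0)), lv, direction, cache
    )
    out <- mult_in(out, lv, probs)
  }
  if (direction == "cause") {
    s <- sum(out)
    if (s > 0) out <- out / s
  }
  out
}

#' Repertoire of an occurrence under a partition
#'
#' Computes the residual constraints of an occurrence on a purview after the
#' given partition severs it: the product over parts of each part's repertoire,
#' times the unconstrained repertoire of any leftover purview variables
#' (uniform, for the cause direction, with the joint product renormalized).
#' Under the full cut this is exactly the unconstrained repertoire.
#'
#' @inheritParams effect_repertoire
#' @param partition a partition from [enumerate_partitions()] over the same
#'   occurrence variables and purview.
#' @return a `repertoire` tibble over the full purview.
#' @export
partitioned_repertoire <- function(net, occ, purview, partition) {
  if (!inherits(partition, "link_partition")) {
    abort_schema("`partition` must come from enumerate_partitions()")
  }
  direction <- partition$direction
  check_repertoire_args(net, occ, purview, direction)
  if (!setequal(partition$occurrence_vars, names(occ)) ||
    !setequal(partition$purview_vars, purview)) {
    abort_schema("partition does not match the given occurrence and purview")
  }
  new_repertoire(
    net, occ, purview, direction,
    partitioned_vec(net, occ, purview, partition)
  )
}
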