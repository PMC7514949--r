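# JSON (de)serialization of networks, transitions and causal accounts.
#
# The network-spec document is plain JSON: declared variables with
# cardinalities, one gate descriptor per post node (named gate + params, or an
# explicit table keyed by comma-joined input states in declared input order),
# optional background assignments, optional transition block. Accounts
# serialize deterministically: links sorted canonically, alphas at 6 decimals.

#' Read a network specification document
#'
#' @param source path to a JSON file, a JSON string, or an already-parsed list.
#' @return list with `network` (a `causal_network`) and `transition` (a
#'   `transition` or `NULL`). Schema problems raise
#'   `actualcause_schema_error`; an impossible transition block raises
#'   `actualcause_realization_error`.
#' @export
read_network_spec <- function(source) {
  doc <- parse_document(source)
  for (field in c("pre", "post", "mechanisms")) {
    if (is.null(doc[[field]])) {
      abort_schema(sprintf("network spec is missing the '%s' field", field))
    }
  }
  pre <- parse_variables(doc$pre, "pre")
  post <- parse_variables(doc$post, "post")

  mechanisms <- lapply(doc$mechanisms, function(m) {
    if (is.null(m$node) || is.null(m$gate) || is.null(m$inputs)) {
      abort_schema("each mechanism needs 'node', 'gate' and 'inputs' fields")
    }
    inputs <- as.character(unlist(m$inputs))
    in_cards <- pre$cardinality[match(inputs, pre$name)]
    node_card <- post$cardinality[match(m$node, post$name)]
    if (anyNA(in_cards) || is.na(node_card)) {
      abort_schema(sprintf(
        "mechanism for '%s' references undeclared variables", m$node
      ))
    }
    params <- m$params %||% list()
    if (!is.null(params$groups)) params$groups <- lapply(params$groups, unlist)
    if (toupper(m$gate) == "TABLE") {
      params$table <- parse_table(m$table %||% params$table, inputs, in_cards,
        node_card,
        node = m$node
      )
    }
    make_gate_mechanism(m$gate, inputs, m$node,
      params = params,
      input_cards = in_cards, node_card = node_card
    )
  })

  # 'background' names declared pre-variables to condition out at load time;
  # 'conditioned_background' is the informational record of pins already baked
  # into the tables (written when serializing a conditioned network)
  record <- integer()
  if (!is.null(doc$conditioned_background) && length(doc$conditioned_background)) {
    record <- vapply(doc$conditioned_background, as.integer, 0L)
  }
  net <- build_network(pre, post, mechanisms, background = record)
  if (!is.null(doc$background) && length(doc$background)) {
    net <- condition_on_background(net, vapply(doc$background, as.integer, 0L))
  }

  transition <- NULL
  if (!is.null(doc$transition)) {
    tb <- doc$transition
    if (is.null(tb$before) || is.null(tb$after)) {
      abort_schema("transition block needs 'before' and 'after' states")
    }
    transition <- make_transition(
      net,
      vapply(tb$before, as.integer, 0L),
      vapply(tb$after, as.integer, 0L)
    )
  }
  list(network = net, transition = transition)
}

parse_document <- function(source) {
  if (is.list(source)) {
    return(source)
  }
  if (!is.character(source) || length(source) != 1L) {
    abort_schema("source must be a file path, JSON string, or list")
  }
  txt <- if (file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    source
  }
  tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) abort_schema(paste("invalid JSON:", conditionMessage(e)))
  )
}

parse_variables <- function(x, tier) {
  tibble::tibble(
    name = vapply(x, function(v) as.character(v$name %||% v), ""),
    cardinality = vapply(x, function(v) {
      as.integer(if (is.list(v)) v$cardinality %||% 2L else 2L)
    }, 0L)
  )
}

parse_table <- function(tab, inputs, in_cards, node_card, node) {
  if (is.null(tab)) abort_schema(sprintf("TABLE gate for '%s' has no table", node))
  grid <- state_grid(in_cards)
  keys <- apply(grid, 1L, paste, collapse = ",")
  if (ncol(grid) == 0L) keys <- ""
  out <- matrix(NA_real_, nrow = nrow(grid), ncol = node_card)
  for (key in names(tab)) {
    i <- match(gsub("[[:space:]]", "", key), keys)
    if (is.na(i)) {
      abort_schema(sprintf(
        "table row '%s' for node '%s' does not match any input state", key, node
      ))
    }
    row <- as.numeric(unlist(tab[[key]]))
    if (length(row) != node_card) {
      abort_schema(sprintf(
        "table row '%s' for node '%s' must have %d entries", key, node, node_card
      ))
    }
    if (abs(sum(row) - 1) > PROB_TOL) {
      abort_schema(sprintf(
        "table row '%s' for node '%s' sums to %.6g, not 1", key, node, sum(row)
      ))
    }
    out[i, ] <- row
  }
  if (anyNA(out)) {
    abort_schema(sprintf("table for node '%s' is missing input-state rows", node))
  }
  out
}

#' Serialize a network (and optional transition) to a spec document
#'
#' @param net a [build_network()] object.
#' @param transition optional [make_transition()] object.
#' @param path optional file path; when given, pretty JSON is written there.
#' @return the document as a list (invisibly when written to a file).
#' @export
write_network_spec <- function(net, transition = NULL, path = NULL) {
  doc <- list(
    pre = lapply(seq_len(nrow(net$pre)), function(i) {
      list(name = net$pre$name[i], cardinality = net$pre$cardinality[i])
    }),
    post = lapply(seq_len(nrow(net$post)), function(i) {
      list(name = net$post$name[i], cardinality = net$post$cardinality[i])
    }),
    mechanisms = lapply(net$mechanisms, function(m) {
      grid <- state_grid(pre_cards(net)[m$inputs])
      keys <- apply(grid, 1L, paste, collapse = ",")
      tab <- lapply(seq_len(nrow(m$table)), function(r) unname(m$table[r, ]))
      names(tab) <- keys
      list(node = m$node, gate = "TABLE", inputs = m$inputs, table = tab)
    })
  )
  names(doc$mechanisms) <- NULL
  if (length(net$background)) {
    doc$conditioned_background <- as.list(net$background)
  }
  if (!is.null(transition)) {
    doc$transition <- list(
      before = as.list(transition$before),
      after = as.list(transition$after)
    )
  }
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(doc))
  }
  doc
}

#' Serialize a causal account to a document
#'
#' Produces a deterministic, byte-stable representation: links are sorted by
#' direction, occurrence size and label; candidate lists by size then label;
#' alpha values rounded to 6 decimals.
#'
#' @param account a [causal_account()] object.
#' @param path optional file path for pretty JSON output.
#' @return the document as a list (invisibly when written to a file).
#' @export
write_account <- function(account, path = NULL) {
  links <- lapply(account$links, function(l) {
    cands <- lapply(l$candidates, function(cc) as.list(cc))
    ord <- order(
      lengths(cands),
      vapply(l$candidates, fmt_occurrence, "")
    )
    mip <- l$mips[[ord[1L]]]
    list(
      direction = l$direction,
      occurrence = as.list(l$occurrence),
      alpha = round(l$alpha_max, 6L),
      candidates = cands[ord],
      mip = lapply(mip$partition$parts, function(p) {
        list(
          occurrence = as.list(p$occurrence),
          purview = as.list(p$purview)
        )
      })
    )
  })
  ord <- order(
    vapply(account$links, `[[`, "", "direction"),
    vapply(account$links, function(l) length(l$occurrence), 0L),
    vapply(account$links, function(l) fmt_occurrence(l$occurrence), "")
  )
  doc <- list(
    transition = list(
      before = as.list(account$transition$before),
      after = as.list(account$transition$after)
    ),
    links = links[ord],
    A = round(account$A, 6L),
    settings = list(
      alpha_tolerance = ALPHA_TOL,
      probability_tolerance = PROB_TOL,
      enumeration_guard = DEFAULT_GUARD,
      tool_version = as.character(utils::packageVersion("actualcause"))
    )
  )
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(doc))
  }
  doc
}

`%||%` <- function(x, y) if (is.null(x)) y else x
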