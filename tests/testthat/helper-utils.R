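# shared helpers for the suite

# canonical label of a candidate set, for set comparisons
cand_key <- function(x) paste(sort(paste0(names(x), "=", x)), collapse = ",")

expect_candidates <- function(candidates, expected_labels) {
  expect_setequal(vapply(candidates, cand_key, ""), expected_labels)
}

# all nonempty subsets of a character vector
nonempty_subsets <- function(vars) {
  unlist(
    lapply(seq_along(vars), function(k) combn(vars, k, simplify = FALSE)),
    recursive = FALSE
  )
}

# account links as "direction occurrence -> candidates" labels
link_labels <- function(account) {
  td <- tidy(account)
  paste(td$direction, td$occurrence, td$candidates)
}

# integer partitions of n into parts >= 1 (unordered, as size vectors)
integer_partitions <- function(n, max = n) {
  if (n == 0L) {
    return(list(integer(0)))
  }
  out <- list()
  for (k in seq_len(min(n, max))) {
    for (rest in integer_partitions(n - k, k)) {
      out[[length(out) + 1L]] <- c(k, rest)
    }
  }
  out
}
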