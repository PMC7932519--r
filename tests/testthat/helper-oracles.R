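# Independent brute-force oracles shared by the metric unit tests and
# the acceptance checks (plain loops, no reuse of package internals).

neg3 <- valence_nodes("negative")
pos3 <- valence_nodes("positive")

# independent brute-force oracles (plain double loops over entries)
brute_negcon <- function(W, self = FALSE) {
  s <- 0
  for (j in neg3) for (k in neg3) {
    if (j == k && !self) next
    s <- s + abs(W[j, k])
  }
  s
}
brute_outstrength <- function(W, node, mode = "absolute", self = FALSE) {
  s <- 0
  for (j in rownames(W)) {
    if (j == node && !self) next
    s <- s + if (mode == "absolute") abs(W[j, node]) else W[j, node]
  }
  s
}
brute_cross <- function(W, from, to, mode = "absolute") {
  s <- 0
  for (j in to) for (k in from) {
    s <- s + if (mode == "absolute") abs(W[j, k]) else W[j, k]
  }
  s
}

# exhaustive cycle oracle over all ordered node tuples
brute_cycles <- function(W, nodes, max_len, positive_only = TRUE) {
  found <- character()
  tuples <- list()
  for (len in 2:max_len) {
    if (len > length(nodes)) break
    idx <- expand.grid(rep(list(nodes), len), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(idx))) {
      tup <- unlist(idx[r, ], use.names = FALSE)
      if (anyDuplicated(tup)) next
      # canonical rotation: anchor on the node earliest in network order
      if (tup[1] != tup[which.min(match(tup, nodes6))]) next
      path <- c(tup, tup[1])
      w <- mapply(function(a, b) W[b, a], utils::head(path, -1), path[-1])
      ok <- if (positive_only) all(w > 0) else all(w != 0)
      if (ok) found <- c(found, paste(path, collapse = "->"))
    }
  }
  sort(found)
}

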