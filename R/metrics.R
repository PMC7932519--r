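# Network summary statistics: negative connectivity, out-strength
# centrality, cross-valence effects, and reinforcing-cycle detection.

# Accept an affect_network or a bare named 6x6 matrix.
as_weight_matrix <- function(network) {
  if (inherits(network, "affect_network")) return(network$W)
  W <- as.matrix(network)
  if (is.null(rownames(W))) {
    if (!all(dim(W) == c(6, 6))) abort("unnamed matrix must be 6x6")
    dimnames(W) <- list(affect_nodes(), affect_nodes())
  }
  W
}

#' Connectivity among negative affect states
#'
#' Sum of absolute lagged effects over all paths between negative nodes
#' (irritated, down, lonely). Autoregressive self-loops are excluded by
#' default: "paths between" nodes are read as cross-node effects.
#'
#' @param network An `affect_network` or a named weight matrix.
#' @param include_self_loops Count the negative nodes' autoregressions
#'   too.
#' @return Non-negative scalar.
#' @examples
#' W <- matrix(0, 6, 6); W[5, 6] <- 0.2; W[6, 5] <- -0.1
#' negative_connectivity(W)  # 0.3
#' @export
negative_connectivity <- function(network, include_self_loops = FALSE) {
  W <- as_weight_matrix(network)
  neg <- intersect(valence_nodes("negative"), rownames(W))
  if (length(neg) == 0) abort("network has no negative nodes")
  sub <- abs(W[neg, neg, drop = FALSE])
  if (!include_self_loops) diag(sub) <- 0
  sum(sub)
}

#' Out-strength centrality of a node
#'
#' Sum of the connections going from `node` to the other nodes: the
#' node's overall influence on the rest of the network. `mode =
#' "absolute"` (default) sums `|b|` so inhibitory edges also count as
#' influence; `mode = "signed"` sums the raw coefficients.
#'
#' @param network An `affect_network` or weight matrix.
#' @param node Node name.
#' @param mode `"absolute"` or `"signed"`.
#' @param include_self_loop Count the autoregression too (default
#'   `FALSE`: influence on the *other* nodes).
#' @param targets Optional subset of target nodes (used e.g. to restrict
#'   influence to negative states).
#' @return Scalar (non-negative in absolute mode).
#' @examples
#' W <- matrix(0, 6, 6); W[2, 1] <- 0.3; W[5, 1] <- -0.2
#' out_strength(W, "cheerful")            # 0.5
#' out_strength(W, "cheerful", "signed")  # 0.1
#' @export
out_strength <- function(network, node, mode = c("absolute", "signed"),
                         include_self_loop = FALSE, targets = NULL) {
  mode <- match.arg(mode)
  W <- as_weight_matrix(network)
  if (!node %in% colnames(W)) abort(sprintf("unknown node '%s'", node))
  if (is.null(targets)) targets <- rownames(W)
  out <- W[targets, node]
  if (!include_self_loop) out <- out[names(out) != node]
  sum(if (mode == "absolute") abs(out) else out)
}

#' Combined effect of one valence on the other
#'
#' Sum over the nine directed edges from all nodes of `from` valence to
#' all nodes of `to` valence (absolute values by default, so the result
#' is the magnitude of cross-valence influence).
#'
#' @param network An `affect_network` or weight matrix.
#' @param from,to `"positive"` or `"negative"` (must differ).
#' @param mode `"absolute"` or `"signed"`.
#' @return Scalar.
#' @examples
#' W <- matrix(0, 6, 6); W[5, 1] <- -0.15
#' cross_valence_effect(W, "positive", "negative")  # 0.15
#' @export
cross_valence_effect <- function(network,
                                 from = c("positive", "negative"),
                                 to = c("negative", "positive"),
                                 mode = c("absolute", "signed")) {
  from <- match.arg(from); to <- match.arg(to); mode <- match.arg(mode)
  if (from == to) abort("from and to valence must differ")
  W <- as_weight_matrix(network)
  sub <- W[valence_nodes(to), valence_nodes(from), drop = FALSE]
  sum(if (mode == "absolute") abs(sub) else sub)
}

# All simple directed cycles of length 2..max_length over `nodes`,
# canonicalised to start at the smallest node index.
enumerate_simple_cycles <- function(nodes, max_length) {
  out <- list()
  for (len in 2:max_length) {
    if (len > length(nodes)) break
    subsets <- utils::combn(nodes, len, simplify = FALSE)
    for (sub in subsets) {
      first <- sub[1]   # combn emits sorted subsets; anchor the smallest
      rest <- sub[-1]
      perms <- permutations_of(rest)
      for (pm in perms) out[[length(out) + 1]] <- c(first, pm)
    }
  }
  out
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (tail in permutations_of(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], tail)
    }
  }
  out
}

#' Detect reinforcing ("vicious") cycles
#'
#' Enumerates simple directed cycles of length 2..`max_length` among a
#' subset of nodes (default: the negative states) in the
#' significance-filtered network, keeping cycles whose every edge is
#' present and (by default) positive - i.e. mutually reinforcing
#' same-valence loops such as a down<->lonely 2-cycle. Each cycle's
#' strength is its weakest edge.
#'
#' @param network An `affect_network` (filtered networks are used as-is;
#'   unfiltered ones are filtered at `alpha` first when `use_significant`)
#'   or a bare weight matrix (used as-is).
#' @param nodes Node subset to search (default negative nodes).
#' @param max_length Maximum cycle length (default 3).
#' @param require_positive_edges Keep only all-positive cycles (default
#'   `TRUE`).
#' @param use_significant Restrict to significant edges (default `TRUE`).
#' @param alpha Significance level for the filter.
#' @return A tibble with columns `cycle` (e.g. `"down->lonely->down"`),
#'   `length`, `strength` (minimum edge weight) and `min_abs_weight`;
#'   zero rows when no cycle exists.
#' @export
find_reinforcing_cycles <- function(network, nodes = valence_nodes("negative"),
                                    max_length = 3,
                                    require_positive_edges = TRUE,
                                    use_significant = TRUE, alpha = 0.05) {
  if (length(nodes) == 0) abort("node subset is empty")
  if (inherits(network, "affect_network") && use_significant &&
      !isTRUE(network$filtered)) {
    network <- significant_subnetwork(network, alpha)
  }
  W <- as_weight_matrix(network)
  nodes <- intersect(nodes, rownames(W))
  found <- list()
  for (cyc in enumerate_simple_cycles(nodes, max_length)) {
    path <- c(cyc, cyc[1])
    w <- vapply(seq_len(length(path) - 1), function(i) {
      W[path[i + 1], path[i]]   # edge path[i] -> path[i+1]
    }, numeric(1))
    present <- all(w != 0)
    signs_ok <- if (require_positive_edges) all(w > 0) else TRUE
    if (present && signs_ok) {
      found[[length(found) + 1]] <- tibble(
        cycle = paste(path, collapse = "->"),
        length = length(cyc),
        strength = min(w),
        min_abs_weight = min(abs(w)))
    }
  }
  if (length(found) == 0) {
    return(tibble(cycle = character(), length = integer(),
                  strength = numeric(), min_abs_weight = numeric()))
  }
  bind_rows(found)
}
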