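# Minimum-spanning haplotype networks: nodes are haplotype classes sized by
# frequency, edges weighted in nucleotide changes; equally parsimonious
# alternative links are reported as secondary ("dotted") edges.

#' Pairwise nucleotide changes between aligned haplotype representatives
#'
#' Entry (i, j) counts substitution columns (both non-gap, different) plus the
#' number of contiguous columns runs where exactly one sequence is gapped: an
#' indel block counts as one change regardless of its length. Shared gap
#' columns contribute nothing.
#'
#' @param representatives character vector of equal-length aligned sequences,
#'   one per haplotype.
#' @return symmetric integer matrix with zero diagonal.
#' @export
pairwise_changes <- function(representatives) {
  m <- aln_matrix(representatives)
  n <- nrow(m)
  out <- matrix(0L, n, n)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- m[i, ]
      b <- m[j, ]
      both <- a != "-" & b != "-"
      subs <- sum(both & a != b)
      gapdiff <- xor(a == "-", b == "-")
      blocks <- sum(rle(gapdiff)$values)
      out[i, j] <- out[j, i] <- as.integer(subs + blocks)
    }
  }
  out
}

# union-find
uf_find <- function(parent, i) {
  while (parent[[i]] != i) i <- parent[[i]]
  i
}

#' Build a minimum-spanning haplotype network
#'
#' Primary edges form a minimum spanning tree under the change-count weights,
#' with deterministic tie-breaking: candidate edges are taken in lexicographic
#' order of (weight, label_a, label_b) with each pair's labels sorted.
#' Secondary edges are the non-tree pairs whose direct distance equals the
#' tree-path distance between them -- equally parsimonious alternative links,
#' the "dotted lines" of haplotype-network figures. `secondary_rule =
#' "path-max"` instead flags pairs whose weight equals the maximum edge weight
#' on their tree path (the MST cycle rule); `"none"` gives a plain MST.
#'
#' @param matrix symmetric distance matrix with zero diagonal.
#' @param node_labels haplotype names (default from dimnames or H1..Hn).
#' @param node_sizes member counts (exported on nodes; not used in topology).
#' @param secondary_rule `"path-sum"` (default), `"path-max"` or `"none"`.
#' @return object of class `haplotype_network`: `nodes` (name, size), `edges`
#'   (from, to, weight, is_primary; primary edges form a spanning tree) and
#'   `distance_matrix`.
#' @export
build_network <- function(matrix, node_labels = NULL, node_sizes = NULL,
                          secondary_rule = c("path-sum", "path-max", "none")) {
  secondary_rule <- match.arg(secondary_rule)
  n <- nrow(matrix)
  stopifnot(n == ncol(matrix), all(matrix == t(matrix)),
            all(diag(matrix) == 0))
  if (is.null(node_labels)) {
    node_labels <- if (!is.null(rownames(matrix))) rownames(matrix)
                   else sprintf("H%d", seq_len(n))
  }
  if (is.null(node_sizes)) node_sizes <- rep(1L, n)
  stopifnot(length(node_labels) == n, length(node_sizes) == n,
            !anyDuplicated(node_labels))
  nodes <- data.frame(name = node_labels, size = as.integer(node_sizes),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(), to = character(), weight = numeric(),
                      is_primary = logical(), stringsAsFactors = FALSE)
  if (n == 1L) {
    return(structure(list(nodes = nodes, edges = edges,
                          distance_matrix = matrix),
                     class = "haplotype_network"))
  }
  pairs <- which(upper.tri(matrix), arr.ind = TRUE)
  cand <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                     weight = matrix[pairs],
                     la = pmin(node_labels[pairs[, 1L]], node_labels[pairs[, 2L]]),
                     lb = pmax(node_labels[pairs[, 1L]], node_labels[pairs[, 2L]]),
                     stringsAsFactors = FALSE)
  cand <- cand[order(cand$weight, cand$la, cand$lb), ]
  parent <- seq_len(n)
  in_tree <- logical(nrow(cand))
  for (e in seq_len(nrow(cand))) {
    ri <- uf_find(parent, cand$i[[e]])
    rj <- uf_find(parent, cand$j[[e]])
    if (ri != rj) {
      parent[[ri]] <- rj
      in_tree[[e]] <- TRUE
    }
  }
  tree <- cand[in_tree, , drop = FALSE]
  stopifnot(nrow(tree) == n - 1L)  # spanning tree invariant

  adj <- vector("list", n)
  for (e in seq_len(nrow(tree))) {
    adj[[tree$i[[e]]]] <- rbind(adj[[tree$i[[e]]]],
                                c(tree$j[[e]], tree$weight[[e]]))
    adj[[tree$j[[e]]]] <- rbind(adj[[tree$j[[e]]]],
                                c(tree$i[[e]], tree$weight[[e]]))
  }
  # tree-path distance (sum) and bottleneck (max) from every node, by DFS
  path_stats <- function(src) {
    dist_sum <- rep(NA_real_, n)
    dist_max <- rep(NA_real_, n)
    dist_sum[[src]] <- 0
    dist_max[[src]] <- 0
    stack <- src
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1L]
        w <- nb[r, 2L]
        if (is.na(dist_sum[[u]])) {
          dist_sum[[u]] <- dist_sum[[v]] + w
          dist_max[[u]] <- max(dist_max[[v]], w)
          stack <- c(stack, u)
        }
      }
    }
    list(sum = dist_sum, max = dist_max)
  }
  stats_by_node <- lapply(seq_len(n), path_stats)

  sec <- cand[!in_tree, , drop = FALSE]
  if (nrow(sec) && secondary_rule != "none") {
    keep <- vapply(seq_len(nrow(sec)), function(e) {
      st <- stats_by_node[[sec$i[[e]]]]
      ref <- if (secondary_rule == "path-sum") st$sum[[sec$j[[e]]]]
             else st$max[[sec$j[[e]]]]
      sec$weight[[e]] == ref
    }, logical(1L))
    sec <- sec[keep, , drop = FALSE]
  } else {
    sec <- sec[0L, , drop = FALSE]
  }
  fmt <- function(df, primary) {
    if (nrow(df) == 0L) return(NULL)
    data.frame(from = df$la, to = df$lb, weight = df$weight,
               is_primary = primary, stringsAsFactors = FALSE)
  }
  edges <- rbind(fmt(tree, TRUE), fmt(sec, FALSE))
  edges <- edges[order(!edges$is_primary, edges$weight, edges$from, edges$to), ]
  rownames(edges) <- NULL
  net <- structure(list(nodes = nodes, edges = edges, distance_matrix = matrix,
                        tree_path = lapply(stats_by_node, `[[`, "sum")),
                   class = "haplotype_network")
  net
}

#' @export
print.haplotype_network <- function(x, ...) {
  np <- sum(x$edges$is_primary)
  cat(sprintf("haplotype network: %d node(s), %d primary edge(s), %d secondary\n",
              nrow(x$nodes), np, nrow(x$edges) - np))
  invisible(x)
}

#' Central haplotype of a network
#'
#' The node minimizing eccentricity (largest tree-path distance, in
#' nucleotide changes, to any other node) on the primary spanning tree; ties
#' broken lexicographically by name.
#'
#' @param network a [build_network()] result.
#' @return the central haplotype name.
#' @export
central_haplotype <- function(network) {
  stopifnot(inherits(network, "haplotype_network"), nrow(network$nodes) >= 1L)
  if (nrow(network$nodes) == 1L) return(network$nodes$name[[1L]])
  ecc <- vapply(network$tree_path, function(d) max(d), numeric(1L))
  best <- which(ecc == min(ecc))
  sort(network$nodes$name[best])[[1L]]
}

#' Export a network as an edge-list data.frame
#' @param network a [build_network()] result.
#' @return data.frame from, to, weight, is_primary (deterministic row order).
#' @export
network_edges <- function(network) {
  network$edges
}
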