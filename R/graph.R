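#' Directed pairwise distance matrix
#'
#' Stores the inverse-NMI distances d(i, j) for ordered pairs (moving i,
#' fixed j) together with per-pair registration status and, optionally,
#' the recovered transforms. All distances lie in \[0.5, 1\]; the diagonal
#' is undefined. Pairs flagged `failed`, and pairs carrying the maximal
#' sentinel distance 1.0, are treated as pruned edges during graph
#' construction.
#'
#' @param d square numeric matrix with dimnames giving the ids; entries in
#'   \[0.5, 1\] or `NA` for unregistered pairs.
#' @param status optional character matrix of per-pair statuses.
#' @param transforms optional nested list, `transforms[[moving]][[fixed]]`
#'   an `affine_transform`.
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix <- function(d, status = NULL, transforms = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  ids <- rownames(d)
  if (is.null(ids) || is.null(colnames(d)) || !identical(ids, colnames(d)))
    stop("distance matrix needs identical row and column ids")
  diag(d) <- NA_real_
  vals <- d[!is.na(d)]
  if (length(vals) && (min(vals) < 0.5 - 1e-9 || max(vals) > 1 + 1e-9))
    stop("distances must lie in [0.5, 1]")
  structure(list(ids = ids, d = d, status = status, transforms = transforms),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix: %d images, %d registered pairs>\n",
              length(x$ids), sum(!is.na(x$d))))
  invisible(x)
}

# Usable (non-pruned) directed entries: registered, not failed, below the
# 1.0 sentinel.
usable_edges <- function(dm) {
  ok <- !is.na(dm$d) & dm$d < 1.0 - 1e-12
  if (!is.null(dm$status))
    ok <- ok & !is.na(dm$status) & dm$status != "failed"
  ok
}

#' Select the population reference
#'
#' The reference is the image closest to the rest of the population after
#' pairwise registration: the id minimising the sum of incoming distances
#' `sum_i d(i, ref)`. Ties break deterministically by id order.
#'
#' @param dm a [distance_matrix()].
#' @return The selected id.
#' @export
select_reference <- function(dm) {
  sums <- colSums(dm$d, na.rm = TRUE)
  dm$ids[which.min(sums)]
}

#' Build the rooted-tree chain graph
#'
#' Tier-based construction: the `r` images globally closest to the
#' reference join Tier 1; thereafter an unassigned image joins Tier t + 1
#' if a Tier-t node is among its `r` nearest neighbours over the whole
#' population, taking the nearest such node as its parent. When no image
#' can be added at any tier, `r` is incremented by one and construction
#' restarts from Tier 0 for the still-unassigned images (existing edges
#' are kept). Images tagged difficult are forced to be leaves: they may
#' join, but never serve as parents.
#'
#' @param dm a [distance_matrix()].
#' @param root reference id (Tier 0).
#' @param r initial rank (neighbourhood size), a positive integer.
#' @param difficult character vector of ids that must remain leaf nodes.
#' @return An object of class `chain_graph` with elements `root`,
#'   `parent` (named character), `tier` (named integer, root = 0),
#'   `edge_distance` (named numeric, d(node, parent)) and `rank_used`.
#' @export
build_graph <- function(dm, root, r, difficult = character()) {
  ids <- dm$ids
  n <- length(ids)
  if (!root %in% ids) stop("unknown root id: ", root)
  if (root %in% difficult) stop("the reference cannot be tagged difficult")
  r <- as.integer(r)
  if (r < 1) stop("rank must be a positive integer")
  ok <- usable_edges(dm)

  # Global ranking of candidates for Tier 1: ascending d(i, root).
  to_root <- dm$d[, root]
  t1_order <- ids[order(to_root, match(ids, ids), na.last = NA)]
  t1_order <- t1_order[ok[t1_order, root]]
  t1_rank <- setNames(seq_along(t1_order), t1_order)

  # Each image's neighbour list: ascending d(j, .) over usable edges.
  nbr <- lapply(ids, function(j) {
    dj <- dm$d[j, ]
    cand <- ids[ok[j, ]]
    cand[order(dj[cand])]
  })
  names(nbr) <- ids

  tier <- setNames(0L, root)
  parent <- character(0)
  edge_distance <- numeric(0)
  unassigned <- setdiff(ids, root)
  r_cur <- r

  assign_node <- function(j, p, t) {
    tier[[j]] <<- t
    parent[[j]] <<- p
    edge_distance[[j]] <<- dm$d[j, p]
    unassigned <<- setdiff(unassigned, j)
  }

  while (length(unassigned)) {
    progress <- FALSE
    # Tier 1: unassigned images whose global closeness rank to the root
    # is within r_cur connect directly to it.
    for (j in unassigned) {
      rk <- t1_rank[j]
      if (!is.na(rk) && rk <= r_cur) {
        assign_node(j, root, 1L)
        progress <- TRUE
      }
    }
    # Higher tiers: attach to a previous-tier node found among the
    # r_cur nearest neighbours.
    t <- 2L
    repeat {
      prev <- setdiff(names(tier)[tier == t - 1L], difficult)
      if (!length(prev) || !length(unassigned)) break
      added <- FALSE
      for (j in unassigned) {
        nn <- nbr[[j]]
        nn <- nn[seq_len(min(r_cur, length(nn)))]
        cand <- intersect(nn, prev)
        if (length(cand)) {
          p <- cand[which.min(dm$d[j, cand])]
          assign_node(j, p, t)
          added <- TRUE
        }
      }
      if (!added) break
      progress <- TRUE
      t <- t + 1L
    }
    if (!length(unassigned)) break
    if (!progress && r_cur >= n)
      stop("connectivity error: no registration path to '", root,
           "' for: ", paste(unassigned, collapse = ", "))
    r_cur <- r_cur + 1L
  }

  ord <- c(root, setdiff(ids, root))
  structure(list(root = root, parent = parent,
                 tier = tier[ord[ord %in% names(tier)]],
                 edge_distance = edge_distance, rank_used = r_cur,
                 ids = ids, difficult = difficult),
            class = "chain_graph")
}

#' @export
print.chain_graph <- function(x, ...) {
  cat(sprintf("<chain_graph: %d nodes, root '%s', max tier %d, rank %d>\n",
              length(x$ids), x$root, max(x$tier), x$rank_used))
  invisible(x)
}

# Path from a node to the root (inclusive).
path_to_root <- function(g, node) {
  path <- node
  while (node != g$root) {
    node <- g$parent[[node]]
    path <- c(path, node)
  }
  path
}

#' Graph-fitness measures
#'
#' For each non-root node j with path j = c(1), ..., c(n_j) = root, the
#' per-node mean inter-node distance is the mean of the consecutive edge
#' distances d(c(k), c(k-1)) along the path and the per-node minimum is
#' their minimum. The graph measures are the sums over all non-root
#' nodes: `d_mean` of the per-node means and `d_min` of the per-node
#' minima. Smaller is fitter; `d_min <= d_mean` always.
#'
#' @param g a `chain_graph`.
#' @param dm the [distance_matrix()] it was built from.
#' @return A list of class `graph_fitness` with `d_mean`, `d_min` and the
#'   per-node values `per_node_mean`, `per_node_min`.
#' @export
fitness <- function(g, dm) {
  nodes <- setdiff(g$ids, g$root)
  per_mean <- per_min <- setNames(numeric(length(nodes)), nodes)
  for (j in nodes) {
    p <- path_to_root(g, j)
    ed <- dm$d[cbind(p[-length(p)], p[-1])]
    per_mean[j] <- mean(ed)
    per_min[j] <- min(ed)
  }
  structure(list(d_mean = sum(per_mean), d_min = sum(per_min),
                 per_node_mean = per_mean, per_node_min = per_min),
            class = "graph_fitness")
}

#' @export
print.graph_fitness <- function(x, ...) {
  cat(sprintf("<graph_fitness: d_mean = %.4f, d_min = %.4f>\n",
              x$d_mean, x$d_min))
  invisible(x)
}

#' Build chain graphs over candidate ranks and keep the fittest
#'
#' Builds one graph per candidate rank and returns the one with the
#' smallest `d_mean`; ties are broken by smallest `d_min`, then by
#' smallest rank. The default candidate set is 1..n.
#'
#' @inheritParams build_graph
#' @param candidate_ranks integer vector of ranks to try; default
#'   `1:length(dm$ids)`.
#' @return The selected `chain_graph` (its `fitness` attribute holds the
#'   winning [fitness()]).
#' @export
optimise_rank <- function(dm, root, candidate_ranks = NULL,
                          difficult = character()) {
  if (is.null(candidate_ranks)) candidate_ranks <- seq_along(dm$ids)
  if (!length(candidate_ranks)) stop("candidate_ranks must be non-empty")
  best <- NULL
  best_key <- c(Inf, Inf, Inf)
  errs <- character(0)
  for (r in sort(unique(as.integer(candidate_ranks)))) {
    g <- tryCatch(build_graph(dm, root, r, difficult = difficult),
                  error = function(e) {
                    errs <<- c(errs, conditionMessage(e))
                    NULL
                  })
    if (is.null(g)) next
    f <- fitness(g, dm)
    key <- c(f$d_mean, f$d_min, r)
    if (is.null(best) ||
        key[1] < best_key[1] - 1e-15 ||
        (abs(key[1] - best_key[1]) <= 1e-15 && key[2] < best_key[2] - 1e-15)) {
      best <- g
      attr(best, "fitness") <- f
      best_key <- key
    }
  }
  if (is.null(best))
    stop("no candidate rank produced a connected graph: ",
         paste(unique(errs), collapse = "; "))
  best
}

#' Attach a new image to an existing chain graph
#'
#' The new image becomes a child of its nearest existing node that is not
#' tagged difficult, one tier below it; existing edges are untouched. This
#' is the low-cost incremental path for images arriving after the graph
#' was built on a representative subset.
#'
#' @param g a `chain_graph`.
#' @param dm_new named numeric vector of distances from the new image to
#'   existing nodes (names are node ids).
#' @param id identifier of the new image.
#' @return The extended `chain_graph`.
#' @export
add_image <- function(g, dm_new, id) {
  if (id %in% g$ids) stop("id already in graph: ", id)
  cand <- intersect(names(dm_new)[!is.na(dm_new)],
                    setdiff(names(g$tier), g$difficult))
  if (!length(cand)) stop("no usable distances to non-difficult nodes")
  p <- cand[which.min(dm_new[cand])]
  g$parent[[id]] <- p
  g$tier[[id]] <- g$tier[[p]] + 1L
  g$edge_distance[[id]] <- unname(dm_new[p])
  g$ids <- c(g$ids, id)
  g
}

#' Reference-choice connectivity sweep
#'
#' Re-runs rank-optimised graph construction once with every image as the
#' reference and counts, per ordered (child, parent) pair, how many of the
#' n graphs contain that edge. Consistently high counts indicate that the
#' construction is robust to the reference choice.
#'
#' @param dm a [distance_matrix()].
#' @param candidate_ranks passed to [optimise_rank()].
#' @param difficult passed through.
#' @return An n x n integer matrix of edge counts (rows = child,
#'   columns = parent), with an attribute `errors` naming references whose
#'   graph construction failed.
#' @export
reference_sweep <- function(dm, candidate_ranks = NULL,
                            difficult = character()) {
  ids <- dm$ids
  counts <- base::matrix(0L, length(ids), length(ids),
                         dimnames = list(child = ids, parent = ids))
  errs <- character(0)
  for (ref in setdiff(ids, difficult)) {
    g <- tryCatch(optimise_rank(dm, ref, candidate_ranks, difficult),
                  error = function(e) {
                    errs <<- c(errs, setNames(conditionMessage(e), ref))
                    NULL
                  })
    if (is.null(g)) next
    for (child in names(g$parent))
      counts[child, g$parent[[child]]] <- counts[child, g$parent[[child]]] + 1L
  }
  attr(counts, "errors") <- errs
  counts
}

#' Export a chain graph
#'
#' `graph_to_dot` writes Graphviz DOT (edges child -> parent, labelled
#' with their distance); `graph_to_json` writes nodes with tiers and edges
#' with distances plus the rank used.
#'
#' @param g a `chain_graph`.
#' @param path output file; for `graph_to_json`, `NULL` returns the JSON
#'   string instead.
#' @return The path (or JSON string), invisibly for writers.
#' @export
graph_to_dot <- function(g, path) {
  lines <- c("digraph chain {", sprintf("  rankdir=BT;"))
  for (node in names(g$tier))
    lines <- c(lines, sprintf("  \"%s\" [tier=%d];", node, g$tier[[node]]))
  for (child in names(g$parent))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%.4f\"];",
                              child, g$parent[[child]],
                              g$edge_distance[[child]]))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname graph_to_dot
#' @export
graph_to_json <- function(g, path = NULL) {
  obj <- list(
    root = g$root, rank_used = g$rank_used,
    nodes = data.frame(id = names(g$tier), tier = unname(g$tier)),
    edges = if (length(g$parent)) data.frame(
      child = names(g$parent), parent = unname(g$parent),
      distance = unname(g$edge_distance[names(g$parent)])) else
        data.frame(child = character(), parent = character(),
                   distance = numeric()),
    difficult = g$difficult)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read/write a distance matrix as CSV
#'
#' Layout: rows = moving id, columns = fixed id, empty diagonal. The
#' status matrix travels in a `<stem>_status.csv` sidecar when present.
#'
#' @param dm a [distance_matrix()].
#' @param path CSV path.
#' @return `read_distance_matrix` returns a [distance_matrix()].
#' @export
write_distance_matrix <- function(dm, path) {
  write.csv(dm$d, path, row.names = TRUE)
  if (!is.null(dm$status))
    write.csv(dm$status, sub("\\.csv$", "_status.csv", path),
              row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  d <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  spath <- sub("\\.csv$", "_status.csv", path)
  status <- if (file.exists(spath))
    as.matrix(read.csv(spath, row.names = 1, check.names = FALSE)) else NULL
  distance_matrix(d, status = status)
}
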