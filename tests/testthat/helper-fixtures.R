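# Shared fixtures, built once per test run.

# Small phantom (32^3 at 2 mm) for fast registration tests.
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_phantom(shape = c(32, 32, 32), spacing = c(2, 2, 2),
                             seed = 1)
    cache
  }
})

# Full-size phantom (64^3 at 2 mm), the generator default.
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom(seed = 1)
    cache
  }
})

# A smooth asymmetric test volume with a closed-form intensity field.
smooth_volume <- function(shape = c(24, 24, 24), spacing = c(1, 1, 1),
                          id = "smooth") {
  ax <- lapply(seq_len(3), function(k)
    ((0:(shape[k] - 1)) - (shape[k] - 1) / 2) * spacing[k])
  X <- array(ax[[1]], shape)
  Y <- array(rep(ax[[2]], each = shape[1]), shape)
  Z <- array(rep(ax[[3]], each = shape[1] * shape[2]), shape)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- -(shape - 1) / 2 * spacing
  image_volume(100 * exp(-(X^2 + 1.3 * Y^2 + 0.8 * Z^2) / 60) +
                 10 * sin(X / 3) * cos(Y / 4) + 0.5 * X,
               affine = aff, id = id)
}

# Random valid distance matrix over n images (values in [0.5, 1]).
random_dm <- function(n, ids = sprintf("v%02d", seq_len(n))) {
  d <- matrix(runif(n * n, 0.5, 1), n, n, dimnames = list(ids, ids))
  diag(d) <- NA
  distance_matrix(d)
}

# Independent rooted-tree validity check used by graph property tests.
# Returns a character vector of violations (empty if the graph is valid)
# so property loops over hundreds of graphs stay cheap.
chain_graph_violations <- function(g, dm) {
  n <- length(dm$ids)
  bad <- character(0)
  if (length(g$parent) != n - 1) bad <- c(bad, "edge count != n - 1")
  if (!setequal(names(g$tier), dm$ids)) bad <- c(bad, "node set mismatch")
  if (!identical(unname(g$tier[g$root]), 0L)) bad <- c(bad, "root tier != 0")
  for (node in setdiff(dm$ids, g$root)) {
    seen <- character(0)
    cur <- node
    while (cur != g$root) {
      if (cur %in% seen) {
        bad <- c(bad, paste("cycle through", cur))
        break
      }
      seen <- c(seen, cur)
      if (!identical(unname(g$tier[cur]), g$tier[[g$parent[[cur]]]] + 1L))
        bad <- c(bad, paste("tier increment broken at", cur))
      cur <- g$parent[[cur]]
    }
  }
  # ranking-constraint oracle: every non-tier-1 edge's parent is among the
  # child's rank_used nearest neighbours by brute-force sorting
  for (node in names(g$parent)) {
    if (g$tier[[node]] == 1L) next
    dj <- dm$d[node, ]
    nn <- names(sort(dj[!is.na(dj)]))[seq_len(min(g$rank_used, n - 1))]
    if (!g$parent[[node]] %in% nn)
      bad <- c(bad, paste("ranking constraint broken at", node))
  }
  bad
}

expect_valid_chain_graph <- function(g, dm) {
  expect_identical(chain_graph_violations(g, dm), character(0))
  invisible(g)
}
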