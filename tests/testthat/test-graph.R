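test_that("select_reference minimises the incoming-distance sum", {
  d <- matrix(c(NA, 0.9, 0.9, 0.9, NA, 0.5, 0.9, 0.5, NA), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  # column sums: a = 1.8, b = 1.4, c = 1.4 -> tie broken by id order
  expect_identical(select_reference(distance_matrix(d)), "b")

  d2 <- d
  d2["a", "c"] <- 0.8 # sums: a 1.8, b 1.4, c 1.3
  expect_identical(select_reference(distance_matrix(d2)), "c")

  # all-equal distances: first id wins
  dm <- distance_matrix(matrix(0.7, 4, 4,
                               dimnames = list(letters[1:4], letters[1:4])))
  expect_identical(select_reference(dm), "a")

  # brute-force argmin on a random matrix
  set.seed(2)
  dm3 <- random_dm(8)
  sums <- colSums(dm3$d, na.rm = TRUE)
  expect_identical(select_reference(dm3), names(which.min(sums)))
})

test_that("build_graph reproduces hand-worked tier assignments", {
  # 3 nodes: d(B,R)=0.2 (wait: stored as [0.5,1] range) -- use scaled
  # distances with the same ordering: chain A -> B -> R at r = 1.
  ids <- c("A", "B", "R")
  d <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  d["B", "R"] <- 0.6; d["A", "R"] <- 0.95; d["A", "B"] <- 0.55
  d["R", "B"] <- 0.6; d["R", "A"] <- 0.95; d["B", "A"] <- 0.55
  g <- build_graph(distance_matrix(d), "R", r = 1)
  expect_identical(g$parent[["B"]], "R")
  expect_identical(g$parent[["A"]], "B")
  expect_identical(unname(g$tier[c("A", "B", "R")]), c(2L, 1L, 0L))

  # r = n: star graph (all non-reference nodes at tier 1)
  set.seed(9)
  dm <- random_dm(6)
  star <- build_graph(dm, dm$ids[1], r = 6)
  expect_true(all(star$tier[setdiff(dm$ids, dm$ids[1])] == 1L))

  # suitably ranked distances with r = 1 give a serial chain
  ids <- sprintf("n%d", 1:5)
  d <- matrix(1, 5, 5, dimnames = list(ids, ids))
  for (i in 2:5) d[ids[i], ids[i - 1]] <- 0.5 + 0.02 * i
  for (i in 1:4) d[ids[i], ids[i + 1]] <- 0.6 + 0.02 * i
  d[lower.tri(d) | upper.tri(d)][is.na(d[lower.tri(d) | upper.tri(d)])] <- 1
  diag(d) <- NA
  g1 <- build_graph(distance_matrix(pmin(d, 1)), "n1", r = 1)
  expect_identical(unname(g1$tier[ids]), 0:4)
  for (i in 2:5) expect_identical(g1$parent[[ids[i]]], ids[i - 1])
})

test_that("difficult images are forced to be leaves", {
  set.seed(14)
  dm <- random_dm(8)
  g <- build_graph(dm, dm$ids[1], r = 2, difficult = dm$ids[2:3])
  expect_false(any(g$parent %in% dm$ids[2:3]))
  expect_error(build_graph(dm, dm$ids[1], r = 2, difficult = dm$ids[1]),
               "difficult")
})

test_that("fitness matches the hand-computed chain example", {
  ids <- c("A", "B", "R")
  d <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  d["A", "B"] <- 0.1; d["B", "R"] <- 0.2; d["A", "R"] <- 0.9
  # direct construction of the chain A -> B -> R
  g <- structure(list(root = "R",
                      parent = c(A = "B", B = "R"),
                      tier = c(R = 0L, A = 2L, B = 1L),
                      edge_distance = c(A = 0.1, B = 0.2),
                      rank_used = 1L, ids = ids, difficult = character()),
                 class = "chain_graph")
  dm <- structure(list(ids = ids, d = d, status = NULL, transforms = NULL),
                  class = "distance_matrix")
  f <- fitness(g, dm)
  expect_equal(f$per_node_mean[["A"]], 0.15, tolerance = 1e-12)
  expect_equal(f$per_node_min[["A"]], 0.1, tolerance = 1e-12)
  expect_equal(f$per_node_mean[["B"]], 0.2, tolerance = 1e-12)
  expect_equal(f$d_mean, 0.35, tolerance = 1e-12)
  expect_equal(f$d_min, 0.30, tolerance = 1e-12)

  # star graph: d_mean = d_min = sum of direct distances
  set.seed(21)
  dm2 <- random_dm(5)
  star <- build_graph(dm2, dm2$ids[2], r = 5)
  f2 <- fitness(star, dm2)
  direct <- sum(dm2$d[setdiff(dm2$ids, dm2$ids[2]), dm2$ids[2]])
  expect_equal(f2$d_mean, direct)
  expect_equal(f2$d_min, direct)
})

test_that("optimise_rank matches an exhaustive fitness-comparison oracle", {
  set.seed(31)
  for (trial in 1:10) {
    n <- sample(4:7, 1)
    dm <- random_dm(n)
    root <- dm$ids[1]
    cand <- lapply(seq_len(n), function(r) build_graph(dm, root, r))
    fits <- t(vapply(cand, function(g) {
      f <- fitness(g, dm)
      c(f$d_mean, f$d_min)
    }, numeric(2)))
    best_idx <- order(fits[, 1], fits[, 2], seq_len(n))[1]
    got <- optimise_rank(dm, root)
    gf <- attr(got, "fitness")
    expect_equal(gf$d_mean, fits[best_idx, 1], tolerance = 1e-12)
    expect_equal(gf$d_min, fits[best_idx, 2], tolerance = 1e-12)
    # output fitness no worse than any candidate graph
    expect_true(all(gf$d_mean <= fits[, 1] + 1e-12))
  }
  # n = 2: the single edge regardless of rank
  d <- matrix(c(NA, 0.7, 0.7, NA), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  g2 <- optimise_rank(distance_matrix(d), "x")
  expect_identical(g2$parent[["y"]], "x")
})

test_that("graphs from random matrices satisfy rooted-tree invariants", {
  set.seed(77)
  for (trial in 1:40) {
    n <- sample(3:15, 1)
    dm <- random_dm(n)
    g <- build_graph(dm, sample(dm$ids, 1), r = sample.int(n, 1))
    expect_valid_chain_graph(g, dm)
  }
})

test_that("graph construction is pure and prunes failed edges", {
  set.seed(55)
  dm <- random_dm(7)
  g1 <- build_graph(dm, dm$ids[3], r = 2)
  g2 <- build_graph(dm, dm$ids[3], r = 2)
  expect_identical(g1, g2)

  # sentinel distances (1.0) are pruned from neighbour lists: a node whose
  # only finite edges go to the root still joins through the root
  ids <- c("r", "p", "q")
  d <- matrix(1, 3, 3, dimnames = list(ids, ids))
  d["p", "r"] <- 0.6; d["q", "r"] <- 0.7
  diag(d) <- NA
  g <- build_graph(distance_matrix(d), "r", r = 1)
  expect_identical(g$parent[["q"]], "r")

  # fully pruned node: connectivity error naming it
  d2 <- d
  d2["q", "r"] <- 1.0
  expect_error(build_graph(distance_matrix(d2), "r", r = 1),
               "connectivity.*q")
})

test_that("add_image attaches to the nearest non-difficult node", {
  set.seed(8)
  dm <- random_dm(5)
  g <- build_graph(dm, dm$ids[1], r = 2)
  dnew <- setNames(c(0.9, 0.55, 0.8, 0.7, 0.95), dm$ids)
  g2 <- add_image(g, dnew, "new")
  expect_identical(g2$parent[["new"]], dm$ids[2])
  expect_identical(g2$tier[["new"]], g$tier[[dm$ids[2]]] + 1L)
  expect_identical(g2$parent[names(g$parent)], g$parent)

  # all nearest candidates difficult: falls through to the root
  g3 <- build_graph(dm, dm$ids[1], r = 2,
                    difficult = setdiff(dm$ids, dm$ids[1]))
  g4 <- add_image(g3, dnew, "new")
  expect_identical(g4$parent[["new"]], dm$ids[1])
})

test_that("reference_sweep counts edges across reference choices", {
  d <- matrix(c(NA, 0.7, 0.7, NA), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  counts <- reference_sweep(distance_matrix(d))
  expect_identical(counts["y", "x"], 1L)
  expect_identical(counts["x", "y"], 1L)

  # two tight clusters: within-cluster edges dominate
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  d <- matrix(0.95, 6, 6, dimnames = list(ids, ids))
  within <- rbind(expand.grid(1:3, 1:3), expand.grid(4:6, 4:6))
  for (k in seq_len(nrow(within)))
    d[within[k, 1], within[k, 2]] <- 0.55
  diag(d) <- NA
  counts <- reference_sweep(distance_matrix(d))
  block <- matrix(FALSE, 6, 6)
  block[1:3, 1:3] <- TRUE; block[4:6, 4:6] <- TRUE
  diag(block) <- FALSE
  expect_gt(sum(counts[block]), sum(counts[!block & !diag(6)]))

  # determinism
  expect_identical(counts, reference_sweep(distance_matrix(d)))
})

test_that("graph exports are well-formed", {
  set.seed(12)
  dm <- random_dm(5)
  g <- optimise_rank(dm, dm$ids[1])
  f <- withr::local_tempfile(fileext = ".json")
  graph_to_json(g, f)
  parsed <- jsonlite::fromJSON(f)
  expect_identical(parsed$root, dm$ids[1])
  expect_identical(nrow(parsed$edges), 4L)
  fd <- withr::local_tempfile(fileext = ".dot")
  graph_to_dot(g, fd)
  expect_true(any(grepl("->", readLines(fd))))
})

test_that("distance matrices round-trip through CSV", {
  set.seed(19)
  dm <- random_dm(6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_distance_matrix(dm, f)
  dm2 <- read_distance_matrix(f)
  expect_equal(dm2$d, dm$d, tolerance = 1e-12)
  expect_identical(dm2$ids, dm$ids)
})
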