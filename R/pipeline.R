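#' Configuration for an end-to-end chain-registration run
#'
#' @param dof,bins passed to the registration engine.
#' @param rank_candidates candidate ranks for [optimise_rank()]; `NULL`
#'   means 1..n.
#' @param reference id of the reference image, or `"auto"` to pick the
#'   image closest to the rest of the population ([select_reference()]).
#' @param difficult ids that must remain leaf nodes of the graph.
#' @param ref_mask optional accurate `binary_mask` of the brain on the
#'   reference, used as the ROI of the direct phase. When absent, the
#'   reference's foreground mask eroded by one voxel is used.
#' @param engine pairwise registration backend (see [pairwise_all()]).
#' @param seed seed governing any stochastic engine component.
#' @param ... further arguments passed to [registration_config()].
#' @return A list of class `chains_run_config`.
#' @export
chains_run_config <- function(dof = 9, bins = 64, rank_candidates = NULL,
                              reference = "auto", difficult = character(),
                              ref_mask = NULL, engine = register_local,
                              seed = 1, ...) {
  structure(list(reg = registration_config(dof = dof, bins = bins,
                                           seed = seed, ...),
                 rank_candidates = rank_candidates, reference = reference,
                 difficult = difficult, ref_mask = ref_mask,
                 engine = engine, seed = seed),
            class = "chains_run_config")
}

#' Indirect registration: compose transforms along graph paths
#'
#' For every node, composes the stored pairwise edge transforms along its
#' unique path to the root, innermost (the node's own edge) first; the
#' root maps to the identity.
#'
#' @param g a `chain_graph`.
#' @param transforms nested list `transforms[[child]][[parent]]` of
#'   `affine_transform`s covering every graph edge (as stored by
#'   [pairwise_all()]), or a `distance_matrix` carrying them.
#' @return Named list of `affine_transform`s (node world to root world).
#' @export
chains_indirect <- function(g, transforms) {
  if (inherits(transforms, "distance_matrix"))
    transforms <- transforms$transforms
  out <- list()
  out[[g$root]] <- identity_transform()
  get_net <- function(node) {
    if (!is.null(out[[node]])) return(out[[node]])
    p <- g$parent[[node]]
    et <- transforms[[node]][[p]]
    if (is.null(et))
      stop("missing edge transform for ", node, " -> ", p)
    net <- compose(get_net(p), et)
    out[[node]] <<- net
    net
  }
  for (node in names(g$parent)) get_net(node)
  out[names(g$tier)]
}

#' Direct registration: local refinement towards the reference
#'
#' Re-registers each image locally to the reference, initialised at its
#' indirect (composed) transform, with the reference brain mask as the
#' region of interest. Inherits the engine's monotone-acceptance
#' contract: the masked NMI of the result is never below that of the
#' initialisation. Per-image failures are recorded and the run continues.
#'
#' @param cohort named list of `image_volume`s.
#' @param indirect named list of initial transforms (from
#'   [chains_indirect()]).
#' @param reference the reference `image_volume`.
#' @param ref_brain_mask `binary_mask` on the reference lattice.
#' @param cfg a [registration_config()].
#' @param engine registration backend (default [register_local()]).
#' @return Named list of `registration_result`s.
#' @export
chains_direct <- function(cohort, indirect, reference, ref_brain_mask,
                          cfg = registration_config(),
                          engine = register_local) {
  ids <- setdiff(names(indirect), reference$id)
  out <- list()
  for (id in ids) {
    out[[id]] <- tryCatch(
      engine(cohort[[id]], reference, init = indirect[[id]], cfg = cfg,
             roi = ref_brain_mask),
      error = function(e) structure(
        list(transform = indirect[[id]], final_similarity = NA_real_,
             status = "failed", n_evaluations = 0L),
        class = "registration_result"))
  }
  out
}

# One-voxel (6-connectivity) erosion, the fallback reference brain ROI.
erode1 <- function(mask) {
  m <- mask$data
  d <- dim(m)
  shift <- function(a, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- (1 + by):d[ax]; idx_src[[ax]] <- 1:(d[ax] - by) }
    else { idx_dst[[ax]] <- 1:(d[ax] + by); idx_src[[ax]] <- (1 - by):d[ax] }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  er <- m
  for (ax in 1:3) for (by in c(-1, 1)) er <- er & shift(m, ax, by)
  binary_mask(er, affine = mask$affine, id = paste0(mask$id, "_eroded"))
}

#' Run the full chain-registration pipeline
#'
#' Orchestrates: foreground masking and pairwise registration of every
#' ordered pair ([pairwise_all()]), reference resolution, rank-optimised
#' chain-graph construction ([optimise_rank()]), indirect registration by
#' transform composition ([chains_indirect()]), direct local refinement
#' under the reference brain mask ([chains_direct()]) and resampling of
#' all volumes into the reference space. Fully deterministic given the
#' seed; no image is silently dropped (every id appears in the report
#' with a terminal status).
#'
#' @param cohort named list of at least 3 `image_volume`s (the reference
#'   must be one of them), or a `chains_cohort` (whose reference volume is
#'   appended automatically).
#' @param cfg a [chains_run_config()].
#' @param out optional output directory; when given, transforms, the
#'   distance matrix, the graph (DOT + JSON), registered volumes and a
#'   JSON-lines run log are written there.
#' @return An object of class `chains_result`: `graph`, `dm`
#'   (distance matrix), `indirect` and `direct` transform maps,
#'   `registered` volumes (direct transforms), `reference`, `report`
#'   data frame and `log`.
#' @export
run_chains <- function(cohort, cfg = chains_run_config(), out = NULL) {
  ref_mask <- cfg$ref_mask
  if (inherits(cohort, "chains_cohort")) {
    if (is.null(ref_mask)) ref_mask <- cohort$brain_mask
    ref <- cohort$reference
    ref$id <- "reference"
    vols <- c(cohort$volumes, list(reference = ref))
    if (identical(cfg$reference, "auto")) cfg$reference <- "reference"
  } else vols <- cohort
  ids <- cohort_ids(vols)
  names(vols) <- ids
  if (length(vols) < 3) stop("need at least 3 images")

  log <- list()
  stamp <- function(stage, ...) {
    log[[length(log) + 1]] <<- c(list(stage = stage), list(...))
  }
  t0 <- proc.time()[3]
  stamp("pairwise", n = length(ids))
  dm <- pairwise_all(vols, cfg$reg, engine = cfg$engine)
  stamp("pairwise_done", seconds = round(proc.time()[3] - t0, 2))

  root <- if (identical(cfg$reference, "auto")) select_reference(dm)
          else cfg$reference
  if (!root %in% ids) stop("reference id not in cohort: ", root)
  g <- optimise_rank(dm, root, cfg$rank_candidates,
                     difficult = cfg$difficult)
  stamp("graph", root = root, rank = g$rank_used, max_tier = max(g$tier))

  indirect <- chains_indirect(g, dm)
  reference <- vols[[root]]
  if (is.null(ref_mask)) ref_mask <- erode1(foreground_mask(reference))
  direct <- chains_direct(vols, indirect, reference, ref_mask, cfg$reg,
                          engine = cfg$engine)
  stamp("direct_done", seconds = round(proc.time()[3] - t0, 2))

  registered <- list()
  for (id in ids) {
    tr <- if (id == root) identity_transform() else direct[[id]]$transform
    registered[[id]] <- resample(vols[[id]], tr, reference)
  }
  report <- data.frame(
    id = ids,
    tier = unname(g$tier[ids]),
    status = vapply(ids, function(id)
      if (id == root) "reference" else direct[[id]]$status, character(1)),
    nmi_direct = vapply(ids, function(id)
      if (id == root) NA_real_ else direct[[id]]$final_similarity,
      numeric(1)),
    row.names = NULL)
  res <- structure(list(graph = g, dm = dm, indirect = indirect,
                        direct = direct, registered = registered,
                        reference = reference, ref_mask = ref_mask,
                        report = report, log = log),
                   class = "chains_result")
  if (!is.null(out)) write_chains_result(res, out)
  res
}

#' @export
print.chains_result <- function(x, ...) {
  cat(sprintf("<chains_result: %d images, root '%s', rank %d, max tier %d>\n",
              nrow(x$report), x$graph$root, x$graph$rank_used,
              max(x$graph$tier)))
  print(x$report)
  invisible(x)
}

#' @rdname run_chains
#' @param res a `chains_result`.
#' @param dir output directory.
#' @export
write_chains_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_distance_matrix(res$dm, file.path(dir, "distances.csv"))
  graph_to_dot(res$graph, file.path(dir, "graph.dot"))
  graph_to_json(res$graph, file.path(dir, "graph.json"))
  tdir <- file.path(dir, "transforms")
  dir.create(tdir, showWarnings = FALSE)
  for (id in names(res$indirect))
    write_transform(res$indirect[[id]],
                    file.path(tdir, paste0(id, "_indirect.mat")))
  for (id in names(res$direct))
    write_transform(res$direct[[id]]$transform,
                    file.path(tdir, paste0(id, "_direct.mat")))
  for (id in names(res$registered))
    write_volume(res$registered[[id]],
                 file.path(dir, paste0(id, "_registered.nii.gz")))
  write.csv(res$report, file.path(dir, "report.csv"), row.names = FALSE)
  con <- file(file.path(dir, "run_log.jsonl"), "w")
  on.exit(close(con))
  for (entry in res$log)
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
  invisible(dir)
}
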