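# Desk-scale study cohorts shared by the simulation-based tests:
# 64^3 grid at 2 mm spacing, 10 images, generator defaults, seed 1.
study_cohort <- local({
  cache <- list()
  function(kind) {
    if (is.null(cache[[kind]]))
      cache[[kind]] <<- build_cohort(
        kind, simulation_config(cohort_size = 10, seed = 1))
    cache[[kind]]
  }
})

# Engine settings used for the study runs (documented package defaults
# plus the 12000-voxel ROI sampling cap).
study_run_config <- function() {
  chains_run_config(dof = 9, max_samples = 12000, seed = 1)
}

# Per-image RDE of a set of recovered transforms against ground truth.
cohort_rdes <- function(cohort, recovered) {
  vapply(names(cohort$volumes), function(id)
    rde(residual_transform(cohort$gt_transforms[[id]], recovered[[id]]),
        cohort$brain_mask), numeric(1))
}

# Local registration of every image straight to the reference from the
# identity: the single-pass local-search baseline CHAINS is compared to.
baseline_local_rdes <- function(cohort, reg_cfg) {
  roi <- foreground_mask(cohort$reference)
  recovered <- lapply(cohort$volumes, function(v)
    register_local(v, cohort$reference, cfg = reg_cfg, roi = roi)$transform)
  cohort_rdes(cohort, recovered)
}
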