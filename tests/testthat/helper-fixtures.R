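# Shared fixtures, built in code at test time.

# small design used across tests: 24 events over 60 s
small_design <- function(seed = 11) {
  build_design(n_events = 24, run_length = 60, min_separation = 0.5,
               duration = 0.5,
               dim_levels = list(category = c("face", "house"),
                                 action = c("left", "right")),
               seed = seed)
}

# masked voxel x time matrices for each run of a simulation
sim_matrices <- function(sim) {
  idx <- which(sim$mask)
  lapply(sim$runs, function(a) {
    matrix(a, nrow = prod(dim(a)[1:3]))[idx, , drop = FALSE]
  })
}

# canonical role assignment: seed = [A1, B2], red = [A2, B1] (consistent
# on dimension 1), blue = [B1, A2] (consistent on dimension 2)
run_pipeline <- function(sim, ...) {
  m <- sim_matrices(sim)
  tca_pipeline(list(m$A1, m$B2), list(m$A2, m$B1), list(m$B1, m$A2),
               voxel_index = which(sim$mask), grid = dim(sim$mask), ...)
}

# independent straight transcription of the Williams statistic, kept
# separate from the package implementation (determinant via det())
williams_oracle <- function(r12, r13, r23, n) {
  R <- det(matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3))
  rbar <- (r12 + r13) / 2
  (r12 - r13) * sqrt(((n - 1) * (1 + r23)) /
    (2 * ((n - 1) / (n - 3)) * R + rbar^2 * (1 - r23)^3))
}
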