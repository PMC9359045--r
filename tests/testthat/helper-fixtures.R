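# Small in-code fixtures shared across the suite.

# A compact phantom spec that fits tiny grids (used where the default
# 64 x 64 x 32 geometry would be needlessly slow).
tiny_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(20, 20, 12), spacing = c(4, 4, 4), seed = seed,
               n_oars = 2L, ptv_radius_range = c(9, 13), ...)
}

# A hand-built two-structure case on a small grid with a known dose.
toy_case <- function(seed = 1, prescription = 70) {
  shape <- c(8, 8, 4)
  set.seed(seed)
  ct <- array(rnorm(prod(shape), 0, 100), shape)
  m1 <- array(0, shape); m1[3:6, 3:6, 2:3] <- 1
  m2 <- array(0, shape); m2[1:2, 7:8, 1:2] <- 1
  dose <- array(runif(prod(shape), 0, prescription), shape)
  plan_case(ct, structure_set(list(PTV = m1, spinal_cord = m2),
                              c(PTV = "target", spinal_cord = "oar")),
            dose_volume(dose), prescription = prescription,
            case_id = sprintf("toy_%d", seed))
}

# Independent brute-force DVH: explicit loop over thresholds and voxels.
brute_dvh <- function(D, M, thresholds) {
  idx <- which(M != 0)
  out <- numeric(length(thresholds))
  for (t in seq_along(thresholds)) {
    n <- 0L
    for (i in idx) if (D[i] >= thresholds[t]) n <- n + 1L
    out[t] <- n / length(idx)
  }
  out
}
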