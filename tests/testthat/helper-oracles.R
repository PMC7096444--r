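# Independent oracles used across the suite.

# naive index-by-index folding loop (oracle for fold_flux_xs)
fold_loop <- function(flux, sigma, mid, e_lo = 0, e_hi = Inf) {
  total <- 0
  for (i in seq_along(flux)) {
    if (mid[i] >= e_lo && mid[i] <= e_hi) total <- total + flux[i] * sigma[i]
  }
  total
}

# brute-force track-length integration: march a proton through the tumor in
# tiny depth steps, deposit each step's path length into the energy bin the
# proton occupies there
track_length_oracle <- function(e0, d_lo, d_hi, model, grid, dz = 1e-4) {
  r0 <- range_from_energy(e0, model)
  z <- seq(d_lo, min(r0, d_hi), by = dz)
  counts <- numeric(grid_n_bins(grid))
  edges <- grid$edges
  for (zz in z) {
    resid <- r0 - zz
    if (resid <= 0) break
    e <- energy_from_range(resid, model)
    i <- findInterval(e, edges)
    if (i >= 1 && i <= length(counts)) counts[i] <- counts[i] + dz
  }
  counts
}

shallow_case <- c(1.6, 3.0)
deep_case <- c(10.0, 11.3)
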