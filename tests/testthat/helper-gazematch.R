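# Shared fixtures, all built in code.

# the apparatus under which the default parameters (degrees) were set
paper_geom <- default_geometry()

# scaled-down display (~9.4 px/deg) so density-map tests run on small grids
toy_geom <- screen_geometry(width_m = 0.52, height_m = 0.32,
                            res_x = 400, res_y = 250, distance_m = 0.7)

# the canonical 20-trial synthetic default suite used by the invariant and
# stability tests (default distortion_spec, 16 encoding fixations)
default_suite <- function(n = 20, base_seed = 1L) {
  synthetic_suite(n, distortion_spec(), base_seed = base_seed)
}

# literal per-pair rigid objective, used to score Procrustes solutions
rigid_objective <- function(src, dst, w, R, t) {
  moved <- src %*% t(R)
  moved[, 1] <- moved[, 1] + t[1]
  moved[, 2] <- moved[, 2] + t[2]
  sum(w * rowSums((moved - dst)^2))
}

rot2 <- function(angle_rad) {
  matrix(c(cos(angle_rad), sin(angle_rad), -sin(angle_rad), cos(angle_rad)), 2, 2)
}

# brute-force rotation-angle grid search with closed-form translation per
# angle; independent oracle for the SVD Procrustes solver
grid_procrustes_objective <- function(src, dst, w, step = 1e-4) {
  W <- sum(w)
  cs <- colSums(src * w) / W
  cd <- colSums(dst * w) / W
  phis <- seq(0, 2 * pi, by = step)
  co <- cos(phis); si <- sin(phis)
  tx <- cd[1] - (co * cs[1] - si * cs[2])
  ty <- cd[2] - (si * cs[1] + co * cs[2])
  E <- 0
  for (j in seq_len(nrow(src))) {
    ex <- co * src[j, 1] - si * src[j, 2] + tx - dst[j, 1]
    ey <- si * src[j, 1] + co * src[j, 2] + ty - dst[j, 2]
    E <- E + w[j] * (ex^2 + ey^2)
  }
  min(E)
}

write_fix_csv <- function(path, lines) {
  writeLines(lines, path)
  path
}
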