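test_that("gaussian_weight matches its analytic values", {
  expect_equal(gaussian_weight(0, 45), 1)
  expect_equal(gaussian_weight(45, 45), exp(-1))
  expect_equal(gaussian_weight(90, 45), exp(-4))
  expect_error(gaussian_weight(10, 0), "positive")
  expect_error(gaussian_weight(-1, 10), ">= 0")
})

test_that("consensus targets reproduce the literal weighted-centroid formula", {
  # single encoding point: normalisation forces q = p
  q1 <- consensus_targets(matrix(c(500, 500), 1, 2), matrix(c(10, 20), 1, 2), 90)
  expect_equal(unname(q1[1, ]), c(10, 20))
  # two equidistant encoding points -> midpoint
  q2 <- consensus_targets(matrix(c(0, 0), 1, 2),
                          rbind(c(-30, 40), c(30, -40)), 90)
  expect_equal(unname(q2[1, ]), c(0, 0))
  # literal summation oracle, computed independently term by term
  enc <- rbind(c(0, 0), c(300, 0)); rel <- matrix(c(10, 0), 1, 2); wp <- 45.1
  w_a <- exp(-(10 / wp)^2); w_b <- exp(-(290 / wp)^2)
  oracle <- (w_a * enc[1, ] + w_b * enc[2, ]) / (w_a + w_b)
  q3 <- consensus_targets(rel, enc, wp)
  expect_equal(unname(q3[1, ]), oracle, tolerance = 1e-10)
  expect_lt(max(abs(q3[1, ] - c(0, 0))), 1e-10)  # near-total weight on (0,0)
})

test_that("consensus targets stay in the convex hull; far-field underflow keeps position", {
  set.seed(21)
  for (rep in 1:20) {
    enc <- matrix(runif(12, 0, 1000), ncol = 2)
    rel <- matrix(runif(8, 0, 1000), ncol = 2)
    q <- consensus_targets(rel, enc, 90)
    expect_true(all(q[, 1] >= min(enc[, 1]) - 1e-9 & q[, 1] <= max(enc[, 1]) + 1e-9))
    expect_true(all(q[, 2] >= min(enc[, 2]) - 1e-9 & q[, 2] <= max(enc[, 2]) + 1e-9))
  }
  # all encoding points astronomically far -> q = D(r), flagged
  far <- consensus_targets(matrix(c(0, 0), 1, 2),
                           matrix(c(1e9, 1e9), 1, 2), 45)
  expect_equal(unname(far[1, ]), c(0, 0))
  expect_true(attr(far, "underflow")[1])
})

test_that("weighted Procrustes solves the trivial and symmetric cases exactly", {
  set.seed(31)
  src <- matrix(runif(10, 0, 100), ncol = 2)
  tf0 <- weighted_rigid_procrustes(src, src, runif(5))
  expect_equal(tf0$rotation, diag(2), tolerance = 1e-12)
  expect_equal(tf0$translation, c(0, 0), tolerance = 1e-10)
  # {(0,0),(1,0)} -> {(0,0),(0,1)}: a pure 90-degree rotation
  tf90 <- weighted_rigid_procrustes(rbind(c(0, 0), c(1, 0)),
                                    rbind(c(0, 0), c(0, 1)), c(1, 1))
  expect_equal(tf90$rotation, rot2(pi / 2), tolerance = 1e-12)
  expect_equal(tf90$translation, c(0, 0), tolerance = 1e-12)
  # single effective point: identity rotation, pure translation
  tf1 <- weighted_rigid_procrustes(matrix(c(1, 2), 1, 2),
                                   matrix(c(5, 7), 1, 2), 1)
  expect_equal(tf1$rotation, diag(2))
  expect_equal(tf1$translation, c(4, 5))
  expect_error(weighted_rigid_procrustes(src, src, rep(0, 5)), "zero")
  expect_error(weighted_rigid_procrustes(src, src, c(1, 1)), "one per point")
})

test_that("weighted Procrustes attains the brute-force grid minimum", {
  # rotation-angle grid search with closed-form translation per angle
  set.seed(41)
  for (rep in 1:10) {
    src <- matrix(runif(12), 6, 2)
    dst <- matrix(runif(12), 6, 2)
    w <- runif(6)
    tf <- weighted_rigid_procrustes(src, dst, w)
    obj <- rigid_objective(src, dst, w, tf$rotation, tf$translation)
    obj_grid <- grid_procrustes_objective(src, dst, w, step = 1e-4)
    expect_lte(obj, obj_grid + 1e-12)          # SVD can only do better
    expect_lt(abs(obj - obj_grid) / obj_grid, 1e-6)
  }
  # collinear configurations remain well-posed proper rotations
  src <- cbind(0:4, rep(0, 5))
  dst <- cbind(rep(0, 5), 0:4) + 3
  tf <- weighted_rigid_procrustes(src, dst, rep(1, 5))
  expect_equal(det(tf$rotation), 1, tolerance = 1e-12)
  expect_equal(crossprod(tf$rotation), diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply_transform(tf, src), positions(dst), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the MLS field is exact on rigid motions and continuous", {
  set.seed(51)
  handles <- matrix(runif(16, 0, 500), ncol = 2)
  xs <- matrix(runif(10, 0, 500), ncol = 2)
  # identity handles -> identity field everywhere
  for (i in 1:5) {
    out <- mls_rigid_deform(xs[i, ], handles, handles, 200)
    expect_equal(out$position, unname(xs[i, ]), tolerance = 1e-9)
  }
  # globally rigid handle motion is reproduced exactly for ANY w_d
  R <- rot2(0.4); t <- c(-35, 80)
  moved <- apply_transform(rigid_transform(R, t), handles)
  for (wd in c(5, 200, 1e6)) {
    out <- mls_rigid_deform(xs[1, ], handles, moved, wd)
    expect_equal(out$position,
                 as.numeric(R %*% xs[1, ] + t), tolerance = 1e-8)
  }
  # single handle pair -> pure translation by convention
  out1 <- mls_rigid_deform(c(10, 10), matrix(c(0, 0), 1, 2),
                           matrix(c(5, -5), 1, 2), 100)
  expect_equal(out1$position, c(15, 5))
  # continuity: O(delta) response to a small perturbation of x
  dsts <- handles + matrix(rnorm(16, sd = 20), ncol = 2)
  a <- mls_rigid_deform(c(250, 250), handles, dsts, 150)$position
  b <- mls_rigid_deform(c(250.01, 250), handles, dsts, 150)$position
  expect_lt(sqrt(sum((a - b)^2)), 0.1)
})

test_that("relocation solves the single-pair case and near fixed points", {
  # one recall, one encoding fixation: lands exactly on it
  enc <- matrix(c(700, 300), 1, 2)
  rec <- matrix(c(100, 900), 1, 2)
  res <- relocate(enc, rec, algorithm_params(), paper_geom)
  expect_equal(unname(res$relocated[1, ]), c(700, 300), tolerance = 1e-9)
  expect_true(res$converged)
  # recall identical to an encoding subset, all other encoding fixations
  # >= 6 w_p away: a near fixed point, moves < 0.05 deg
  grid_pts <- as.matrix(expand.grid(x = c(100, 700, 1300), y = c(100, 700)))
  rec2 <- grid_pts[c(1, 4, 5), ]
  res2 <- relocate(grid_pts, rec2, algorithm_params(), paper_geom)
  move_px <- sqrt(rowSums((res2$relocated - rec2)^2))
  expect_lt(max(px_to_deg(move_px, paper_geom)), 0.05)
})

test_that("a rigidly distorted recall subset is recovered to < 0.5 deg", {
  spec <- distortion_spec(rotation_deg = 5, translation_px = c(30, -20),
                          scale_bias = 1, deform_amp_px = 0,
                          jitter_sigma_px = 0, retention = 10 / 16,
                          n_spurious = 0, seed = 1)
  tr <- generate_trial(16, spec)
  res <- relocate(tr$encoding, tr$recall, algorithm_params(), paper_geom)
  err <- sqrt(rowSums((res$relocated - tr$true_positions)^2))
  expect_lt(mean(px_to_deg(err, paper_geom)), 0.5)
  expect_true(res$converged)
})

test_that("relocation is equivariant under common rigid motions", {
  G <- rot2(17 * pi / 180); gt <- c(12, -7)
  mv <- function(m) sweep(m %*% t(G), 2, gt, `+`)
  for (seed in c(5, 23)) {
    tr <- generate_trial(16, distortion_spec(seed = seed))
    r1 <- relocate(positions(tr$encoding), positions(tr$recall),
                   algorithm_params(), paper_geom)
    r2 <- relocate(mv(positions(tr$encoding)), mv(positions(tr$recall)),
                   algorithm_params(), paper_geom)
    expect_equal(r2$iterations_run, r1$iterations_run)
    expect_lt(max(abs(mv(r1$relocated) - r2$relocated)), 1e-6)
  }
})

test_that("w_d -> infinity reduces MLS to a single global rigid fit", {
  # independent oracle: the same alternating iteration but with a single
  # uniform-weight Procrustes fit per step.  Agreement to 1e-6 px is
  # asserted at w_d = 1e9 px (at 1e6 px the residual weight variation
  # ~ (10^3 px / 10^6 px)^2 = 1e-6 still leaves ~4e-6 px of deformation).
  tr <- generate_trial(16, distortion_spec(seed = 9))
  p <- positions(tr$encoding); r <- positions(tr$recall)
  wp <- deg_to_px(2, paper_geom); tolpx <- deg_to_px(0.01, paper_geom)
  cur <- r
  for (it in 1:50) {
    q <- consensus_targets(cur, p, wp)
    new <- apply_transform(weighted_rigid_procrustes(r, q), r)
    d <- max(sqrt(rowSums((new - cur)^2)))
    cur <- new
    if (d < tolpx) break
  }
  res <- relocate(tr$encoding, tr$recall,
                  algorithm_params(w_d_deg = px_to_deg(1e9, paper_geom)),
                  paper_geom)
  expect_lt(max(abs(res$relocated - cur)), 1e-6)
})

test_that("relocation preserves global structure on the default suite", {
  rms_spread <- function(m) sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  iters <- integer(0)
  for (tr in default_suite(20)) {
    res <- relocate(tr$encoding, tr$recall, algorithm_params(), paper_geom)
    ratio <- rms_spread(res$relocated) / rms_spread(positions(tr$recall))
    expect_gt(ratio, 0.5)        # no degenerate collapse onto a centroid
    iters <- c(iters, res$iterations_run)
    expect_true(res$converged)
  }
  expect_lte(max(iters), 15)     # converges after very few iterations
})

test_that("relocate validates inputs and reports non-convergence", {
  expect_error(relocate(matrix(numeric(0), 0, 2), matrix(1, 1, 2),
                        algorithm_params(), paper_geom), "non-empty|at least one")
  tr <- generate_trial(16, distortion_spec(seed = 3))
  expect_message(
    res <- relocate(tr$encoding, tr$recall,
                    algorithm_params(max_iter = 2), paper_geom),
    "not converged")
  expect_false(res$converged)
  expect_equal(res$iterations_run, 2)
  expect_length(res$displacement_history, 2)
})
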