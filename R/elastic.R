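# Elastic consensus relocation.
#
# Recall fixations r_j (looking-at-nothing) are moved onto encoding
# fixations p_i by a spatially varying rigid map
#
#     D(x) = R_x x + t_x,
#
# where (R_x, t_x) minimise a spatially weighted orthogonal Procrustes
# objective over handle pairs (r_j -> q_j), with Gaussian weights
# theta_d(d) = exp(-d^2 / w_d^2) centred on x (moving least squares with
# rigid transforms).  Each target q_j is the Gaussian-distance-weighted
# centroid of the encoding fixations around the current relocated position
# D(r_j) (scale w_p).  Targets and map are alternated until the relocated
# positions stop moving.

#' Gaussian distance weight
#'
#' The weight kernel `exp(-d^2 / s^2)` used both for consensus targets
#' (scale `w_p`) and for the rigidity of the deformation field (scale `w_d`).
#'
#' @param distance distance(s), pixels, >= 0.
#' @param scale kernel scale in pixels, > 0.
#' @return weight(s) in `(0, 1]`.
#' @export
gaussian_weight <- function(distance, scale) {
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) || scale <= 0) {
    stop("scale must be a single positive number")
  }
  if (any(distance < 0)) stop("distance must be >= 0")
  exp(-(distance / scale)^2)
}

#' Algorithm parameters
#'
#' All spatial parameters are in degrees of visual angle and are converted
#' to pixels through the [screen_geometry()] at run time.
#'
#' @param w_p_deg consensus scale: roughly the distance at which encoding
#'   fixations still contribute to a recall fixation's target (default 2).
#' @param w_d_deg rigidity scale of the deformation field: large values make
#'   all fixations share one rigid transform, small values allow independent
#'   local transforms (default 10).
#' @param epsilon_deg matching radius for deciding which encoding fixations
#'   count as recalled (default 1).
#' @param max_iter iteration cap (default 50).
#' @param tol_deg convergence threshold on the maximum per-point displacement
#'   between iterations (default 0.01).
#' @return list of class `algorithm_params`.
#' @export
algorithm_params <- function(w_p_deg = 2, w_d_deg = 10, epsilon_deg = 1,
                             max_iter = 50, tol_deg = 0.01) {
  if (w_p_deg <= 0 || w_d_deg <= 0 || epsilon_deg <= 0 || tol_deg <= 0) {
    stop("w_p_deg, w_d_deg, epsilon_deg and tol_deg must be positive")
  }
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(w_p_deg = w_p_deg, w_d_deg = w_d_deg,
                 epsilon_deg = epsilon_deg, max_iter = as.integer(max_iter),
                 tol_deg = tol_deg),
            class = "algorithm_params")
}

#' Rigid transform in the plane
#'
#' @param rotation 2 x 2 proper rotation matrix (orthogonal, det +1).
#' @param translation length-2 translation vector, pixels.
#' @return list of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(2), translation = c(0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(2))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be orthogonal with determinant +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to positions
#'
#' @param tf a [rigid_transform()].
#' @param pts positions (n x 2 matrix or length-2 vector).
#' @return transformed positions, same shape class as an n x 2 matrix.
#' @export
apply_transform <- function(tf, pts) {
  p <- positions(pts)
  out <- p %*% t(tf$rotation)
  out[, 1] <- out[, 1] + tf$translation[1]
  out[, 2] <- out[, 2] + tf$translation[2]
  colnames(out) <- c("x", "y")
  out
}

#' Consensus targets for relocated recall fixations
#'
#' Each recall fixation is aimed at the Gaussian-distance-weighted centroid
#' of the encoding fixations, with weights computed around its *current
#' relocated* position:
#' `q_j = sum_i theta_p(||D(r_j) - p_i||) p_i / sum_i theta_p(...)`.
#'
#' Three regimes emerge naturally: one nearby encoding fixation dominates
#' (the target is that fixation); several nearby encoding fixations share
#' the weight (the target is their local centroid); or all encoding
#' fixations are far away, in which case the weights underflow and the
#' recall fixation is left where it is (flagged in the `underflow`
#' attribute).
#'
#' @param relocated current relocated recall positions `D(r_j)` (m x 2).
#' @param encoding encoding positions `p_i` (n x 2).
#' @param w_p_px consensus scale in pixels.
#' @return m x 2 matrix of targets `q_j` with a logical attribute
#'   `underflow` marking rows left unmoved.
#' @export
consensus_targets <- function(relocated, encoding, w_p_px) {
  rel <- positions(relocated); enc <- positions(encoding)
  if (nrow(enc) < 1 || nrow(rel) < 1) stop("need at least one point in each set")
  if (!is.finite(w_p_px) || w_p_px <= 0) stop("w_p_px must be positive")
  m <- nrow(rel)
  q <- matrix(NA_real_, m, 2, dimnames = list(NULL, c("x", "y")))
  under <- logical(m)
  for (j in seq_len(m)) {
    d <- sqrt((enc[, 1] - rel[j, 1])^2 + (enc[, 2] - rel[j, 2])^2)
    w <- gaussian_weight(d, w_p_px)
    s <- sum(w)
    if (s <= 0 || !is.finite(s)) {
      q[j, ] <- rel[j, ]
      under[j] <- TRUE
    } else {
      q[j, ] <- colSums(enc * w) / s
    }
  }
  attr(q, "underflow") <- under
  q
}

#' Weighted rigid Procrustes fit
#'
#' Finds the rotation `R` (proper, det +1) and translation `t` minimising
#' `sum_j w_j ||R src_j + t - dst_j||^2`, solved in closed form via the SVD
#' of the weighted cross-covariance with sign correction.  Reflections are
#' excluded: mirror-image relocations are not plausible.  For
#' rank-deficient configurations with no rotational information (a single
#' effective point, or coincident points), the rotation is the identity and
#' the translation is the weighted residual mean -- the minimal-norm,
#' continuous-limit solution.
#'
#' @param src,dst source and destination positions (n x 2).
#' @param weights nonnegative finite weights, at least one positive.
#' @return a [rigid_transform()].
#' @export
weighted_rigid_procrustes <- function(src, dst, weights = NULL) {
  X <- positions(src); Y <- positions(dst)
  n <- nrow(X)
  if (nrow(Y) != n || n < 1) stop("src and dst must have the same, positive length")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be nonnegative and finite, one per point")
  }
  W <- sum(weights)
  if (W <= 0) stop("all weights are zero")
  cs <- colSums(X * weights) / W
  cd <- colSums(Y * weights) / W
  Xc <- sweep(X, 2, cs); Yc <- sweep(Y, 2, cd)
  S <- t(Xc * weights) %*% Yc
  scale2 <- sum(weights * (rowSums(Xc^2) + rowSums(Yc^2)))
  if (sum(abs(S)) <= 1e-14 * max(scale2, .Machine$double.xmin)) {
    R <- diag(2)  # no rotational information
  } else {
    sv <- svd(S)
    s3 <- sign(det(sv$v %*% t(sv$u)))
    if (s3 == 0) s3 <- 1
    R <- sv$v %*% diag(c(1, s3)) %*% t(sv$u)
  }
  rigid_transform(R, cd - as.numeric(R %*% cs))
}

#' Moving-least-squares rigid deformation at a point
#'
#' Evaluates the elastic relocation field at `x`: fits a rigid transform to
#' the handle pairs `(r_j -> q_j)` with Gaussian weights
#' `theta_d(||x - r_j||)` of scale `w_d_px`, and applies it to `x`.  The
#' field is continuous in `x` and reproduces any globally rigid handle
#' motion exactly, for any `w_d`.
#'
#' @param x evaluation position (length-2).
#' @param handles_src handle source positions `r_j` (n x 2).
#' @param handles_dst handle target positions `q_j` (n x 2).
#' @param w_d_px rigidity scale in pixels.
#' @return list with `transform` (a [rigid_transform()]) and `position`
#'   (`D(x)`, length-2 numeric).
#' @export
mls_rigid_deform <- function(x, handles_src, handles_dst, w_d_px) {
  x <- as.numeric(positions(x))
  src <- positions(handles_src); dst <- positions(handles_dst)
  d <- sqrt((src[, 1] - x[1])^2 + (src[, 2] - x[2])^2)
  w <- gaussian_weight(d, w_d_px)
  tf <- weighted_rigid_procrustes(src, dst, w)
  list(transform = tf, position = as.numeric(apply_transform(tf, x)))
}

#' Relocate recall fixations onto encoding fixations
#'
#' The elastic consensus iteration.  Starting from the identity map, two
#' steps alternate: (a) consensus targets `q_j` are recomputed from the
#' current relocated positions `D(r_j)` against the encoding set (scale
#' `w_p`); (b) the relocated position of each recall fixation is re-evaluated
#' as the MLS rigid field at its *original* position `r_j`, with the original
#' `r_j` as source handles and the updated `q_j` as targets (scale `w_d`).
#' The source handles never move -- only the targets do -- so `D` stays a
#' single elastic mapping of the original recall configuration.  Iteration
#' stops when the maximum per-point displacement between successive
#' iterations falls below `tol_deg`, or after `max_iter` iterations
#' (returned with `converged = FALSE`).
#'
#' @param encoding encoding fixations (a [fixation_sequence()] or n x 2
#'   matrix), non-empty.
#' @param recall recall fixations, non-empty.
#' @param params an [algorithm_params()].
#' @param geom a [screen_geometry()].
#' @return object of class `relocation_result`: list with `relocated`
#'   (m x 2 matrix of `D(r_j)`), `per_point_transforms` (list of
#'   [rigid_transform()]s), `iterations_run`, `converged`,
#'   `displacement_history` (max displacement per iteration, pixels), and
#'   the `params` used.
#' @export
relocate <- function(encoding, recall, params = algorithm_params(), geom) {
  .check_geom(geom)
  p <- positions(encoding)
  r <- positions(recall)
  if (nrow(p) < 1 || nrow(r) < 1) {
    stop("encoding and recall must both contain at least one fixation")
  }
  w_p_px <- deg_to_px(params$w_p_deg, geom)
  w_d_px <- deg_to_px(params$w_d_deg, geom)
  tol_px <- deg_to_px(params$tol_deg, geom)
  m <- nrow(r)
  cur <- r                      # D = identity at start
  tfs <- vector("list", m)
  hist <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(params$max_iter)) {
    q <- consensus_targets(cur, p, w_p_px)
    new <- matrix(NA_real_, m, 2, dimnames = list(NULL, c("x", "y")))
    for (j in seq_len(m)) {
      mls <- mls_rigid_deform(r[j, ], r, q, w_d_px)
      new[j, ] <- mls$position
      tfs[[j]] <- mls$transform
    }
    disp <- max(sqrt(rowSums((new - cur)^2)))
    hist <- c(hist, disp)
    cur <- new
    iters <- it
    if (disp < tol_px) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    message(sprintf("relocate: not converged after %d iterations (last displacement %.3g px)",
                    iters, hist[length(hist)]))
  }
  structure(list(relocated = cur, per_point_transforms = tfs,
                 iterations_run = iters, converged = converged,
                 displacement_history = hist, params = params),
            class = "relocation_result")
}

#' @export
print.relocation_result <- function(x, ...) {
  cat(sprintf("<relocation_result> %d fixations relocated in %d iteration(s)%s\n",
              nrow(x$relocated), x$iterations_run,
              if (x$converged) " (converged)" else " (NOT converged)"))
  invisible(x)
}
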