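# Gaze density maps: Gaussian-smoothed spatial histograms of fixation,
# relocated-fixation or click positions on the stimulus pixel grid.

#' Build a gaze density map
#'
#' Deposits one count per point at its nearest pixel (optionally weighted,
#' e.g. by fixation duration) and convolves with an isotropic Gaussian whose
#' standard deviation is `sigma_deg` of visual angle.  The kernel is
#' normalised, so the total mass of the map equals the number of points
#' (or the weight total) whenever all points are at least ~4 sigma from the
#' image borders; mass within 4 sigma of a border partially leaks off-grid.
#'
#' Positions use the pixel-centre convention: (0, 0) is the centre of the
#' top-left pixel. Points outside the grid are clamped to the nearest pixel.
#'
#' @param points positions in pixels (n x 2 matrix, data.frame with x/y, or
#'   a [fixation_sequence()]).
#' @param image_size `c(width, height)` in pixels.
#' @param sigma_deg Gaussian kernel sigma in degrees of visual angle
#'   (default 1; clicking maps conventionally use 2).
#' @param geom a [screen_geometry()].
#' @param kind map label, one of `"encoding"`, `"recall"`,
#'   `"relocated_recall"`, `"matched_encoding"`, `"leftover"`, `"clicking"`.
#' @param weights optional nonnegative per-point weights (default: unweighted).
#' @return object of class `density_map`: list with `grid` (matrix, row = y,
#'   col = x), `kernel_sigma_deg`, `kind`.
#' @export
make_density_map <- function(points, image_size, sigma_deg = 1, geom,
                             kind = c("encoding", "recall", "relocated_recall",
                                      "matched_encoding", "leftover", "clicking"),
                             weights = NULL) {
  kind <- match.arg(kind)
  .check_geom(geom)
  if (!is.numeric(sigma_deg) || length(sigma_deg) != 1 || sigma_deg <= 0) {
    stop("sigma_deg must be a single positive number")
  }
  w <- as.integer(round(image_size[1])); h <- as.integer(round(image_size[2]))
  if (w < 1 || h < 1) stop("image_size must be positive")
  pts <- positions(points)
  n <- nrow(pts)
  grid <- matrix(0, nrow = h, ncol = w)
  if (n > 0) {
    if (is.null(weights)) weights <- rep(1, n)
    if (length(weights) != n || any(weights < 0) || any(!is.finite(weights))) {
      stop("weights must be nonnegative, finite and one per point")
    }
    col <- pmin(pmax(round(pts[, 1]), 0), w - 1) + 1L
    row <- pmin(pmax(round(pts[, 2]), 0), h - 1) + 1L
    idx <- (col - 1L) * h + row
    acc <- vapply(split(weights, idx), sum, numeric(1))
    grid[as.integer(names(acc))] <- acc
    sigma_px <- deg_to_px(sigma_deg, geom)
    grid <- .gaussian_blur(grid, sigma_px)
  }
  structure(list(grid = grid, kernel_sigma_deg = sigma_deg, kind = kind),
            class = "density_map")
}

# FFT convolution with a truncated (4 sigma), normalised Gaussian.
# Zero-padding by the kernel radius prevents wrap-around; tiny negative
# round-off values are clamped to zero.
.gaussian_blur <- function(mat, sigma_px) {
  stopifnot(sigma_px > 0)
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  nr <- nrow(mat); nc <- ncol(mat)
  pr <- nr + 2L * r; pc <- nc + 2L * r
  P <- matrix(0, pr, pc)
  P[(r + 1):(r + nr), (r + 1):(r + nc)] <- mat
  kr <- numeric(pr); kr[((-r:r) %% pr) + 1L] <- k
  kc <- numeric(pc); kc[((-r:r) %% pc) + 1L] <- k
  K <- outer(kr, kc)
  conv <- Re(stats::fft(stats::fft(P) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  out <- conv[(r + 1):(r + nr), (r + 1):(r + nc)]
  pmax(out, 0)
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> kind=%s, %d x %d px, sigma=%g deg, mass=%.4g\n",
              x$kind, ncol(x$grid), nrow(x$grid), x$kernel_sigma_deg,
              sum(x$grid)))
  invisible(x)
}

#' Plot a density map as a heat map
#'
#' @param x a `density_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.density_map <- function(x, ...) {
  g <- t(x$grid)[, rev(seq_len(nrow(x$grid))), drop = FALSE]
  graphics::image(x = seq_len(nrow(g)) - 1, y = seq_len(ncol(g)) - 1, z = g,
                  xlab = "x (px)", ylab = "y (px)", useRaster = TRUE,
                  main = paste0(x$kind, " map"), ...)
  invisible(x)
}

.map_grid <- function(m) {
  if (inherits(m, "density_map")) m$grid else if (is.matrix(m)) m else
    stop("expected a density_map or matrix")
}

#' Normalise a density map
#'
#' @param map a `density_map`.
#' @param mode `"unit_range"` divides by the maximum (baseline stays at 0);
#'   `"unit_sum"` rescales total mass to 1.
#' @return the normalised `density_map`.
#' @export
normalize_map <- function(map, mode = c("unit_range", "unit_sum")) {
  mode <- match.arg(mode)
  g <- .map_grid(map)
  denom <- if (mode == "unit_range") max(g) else sum(g)
  if (denom <= 0) stop("cannot normalise an all-zero map")
  map$grid <- g / denom
  map
}

#' Location of the density peak
#'
#' @param map a `density_map` (or plain matrix), not all zero.
#' @return `c(x, y)` pixel position of the maximum; ties are broken
#'   deterministically by smallest row (y), then smallest column (x).
#' @export
peak_location <- function(map) {
  g <- .map_grid(map)
  mx <- max(g)
  if (mx <= 0) stop("cannot locate the peak of an all-zero map")
  idx <- which(g == mx, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  c(x = unname(idx[1, 2]) - 1, y = unname(idx[1, 1]) - 1)
}

#' Has the density peak shifted between two maps?
#'
#' True iff the Euclidean distance between the two peak locations strictly
#' exceeds `threshold_deg` of visual angle.
#'
#' @param map_a,map_b `density_map`s of identical shape, neither all-zero.
#' @param threshold_deg shift threshold in degrees (default 4).
#' @param geom a [screen_geometry()].
#' @return logical.
#' @export
peak_shifted <- function(map_a, map_b, threshold_deg = 4, geom) {
  ga <- .map_grid(map_a); gb <- .map_grid(map_b)
  if (!all(dim(ga) == dim(gb))) stop("maps must have the same shape")
  pa <- peak_location(map_a); pb <- peak_location(map_b)
  sqrt(sum((pa - pb)^2)) > deg_to_px(threshold_deg, geom)
}

#' Normalised 2-D entropy of fixation positions
#'
#' Shannon entropy of the occupancy histogram of positions on an
#' `n_bins` x `n_bins` grid over the image, divided by `log(n_bins^2)` so the
#' result lies in `[0, 1]`: 0 when all points share one bin, 1 for exactly
#' uniform occupancy.  The normalisation makes the value independent of the
#' logarithm base.
#'
#' @param points positions in pixels.
#' @param image_size `c(width, height)` in pixels.
#' @param n_bins grid divisions per axis (default 16, must be >= 2).
#' @return normalised entropy in `[0, 1]`.
#' @export
fixation_entropy_2d <- function(points, image_size, n_bins = 16) {
  pts <- positions(points)
  if (nrow(pts) == 0) stop("entropy requires at least one point")
  if (n_bins < 2) stop("n_bins must be >= 2")
  bx <- pmin(pmax(floor(pts[, 1] / (image_size[1] / n_bins)), 0), n_bins - 1)
  by <- pmin(pmax(floor(pts[, 2] / (image_size[2] / n_bins)), 0), n_bins - 1)
  counts <- table(factor(bx + n_bins * by, levels = 0:(n_bins^2 - 1)))
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p)) / log(n_bins^2)
}

#' Write a density map as a TSV matrix
#'
#' @param map a `density_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(.map_grid(map), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
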