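# Epsilon-radius matching of relocated recall fixations onto encoding
# fixations, and the matched / leftover partition of the encoding set.

#' Match encoding fixations to relocated recall fixations
#'
#' An encoding fixation counts as recalled (matched) iff some relocated
#' recall fixation lies within `epsilon_deg` of it; the boundary is
#' inclusive.  Matching is many-to-many: one recall fixation may match
#' several encoding fixations (one recalled object may have drawn several
#' encoding fixations) and vice versa.  No one-to-one assignment is
#' attempted.
#'
#' @param encoding encoding positions (sequence or n x 2 matrix), non-empty.
#' @param relocated relocated recall positions; may be empty (all encoding
#'   fixations then end up leftover).
#' @param epsilon_deg matching radius in degrees (default 1).
#' @param geom a [screen_geometry()].
#' @return object of class `match_result`: list with `matched_encoding` and
#'   `leftover_encoding` (1-based index vectors partitioning the encoding
#'   set), `correspondences` (data.frame `recall`, `encoding`,
#'   `distance_px`, `distance_deg` of all pairs within the radius),
#'   `epsilon_deg` and `n_encoding`.
#' @export
match_fixations <- function(encoding, relocated, epsilon_deg = 1, geom) {
  .check_geom(geom)
  if (epsilon_deg <= 0) stop("epsilon_deg must be positive")
  p <- positions(encoding)
  n <- nrow(p)
  if (n < 1) stop("encoding set must be non-empty")
  rel <- if (is.null(relocated)) matrix(numeric(0), 0, 2) else positions(relocated)
  eps_px <- deg_to_px(epsilon_deg, geom)
  if (nrow(rel) == 0) {
    corr <- data.frame(recall = integer(0), encoding = integer(0),
                       distance_px = numeric(0), distance_deg = numeric(0))
    return(structure(list(matched_encoding = integer(0),
                          leftover_encoding = seq_len(n),
                          correspondences = corr,
                          epsilon_deg = epsilon_deg, n_encoding = n),
                     class = "match_result"))
  }
  d <- sqrt(outer(p[, 1], rel[, 1], "-")^2 + outer(p[, 2], rel[, 2], "-")^2)
  within <- d <= eps_px
  matched <- unname(which(rowSums(within) > 0))
  pair <- which(within, arr.ind = TRUE)
  corr <- data.frame(recall = as.integer(pair[, 2]),
                     encoding = as.integer(pair[, 1]),
                     distance_px = d[pair])
  corr <- corr[order(corr$recall, corr$encoding), , drop = FALSE]
  rownames(corr) <- NULL
  corr$distance_deg <- px_to_deg(corr$distance_px, geom)
  structure(list(matched_encoding = matched,
                 leftover_encoding = setdiff(seq_len(n), matched),
                 correspondences = corr,
                 epsilon_deg = epsilon_deg, n_encoding = n),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> eps=%g deg: %d/%d encoding fixations matched (reduction rate %.3f)\n",
              x$epsilon_deg, length(x$matched_encoding), x$n_encoding,
              reduction_rate(x)))
  invisible(x)
}

#' Reduction rate
#'
#' The fraction of encoding fixations left unmatched: number of leftover
#' encoding fixations divided by the total number of encoding fixations.
#'
#' @param result a [match_fixations()] result.
#' @return fraction in `[0, 1]`.
#' @export
reduction_rate <- function(result) {
  stopifnot(inherits(result, "match_result"))
  length(result$leftover_encoding) / result$n_encoding
}

#' Matched and leftover density maps
#'
#' Splits the encoding fixations by the match partition and builds a density
#' map from each part: the matched map summarises what was recalled, the
#' leftover map what was not.  Their unsmoothed counts sum to the full
#' encoding map's counts by construction.
#'
#' @param encoding the encoding [fixation_sequence()] (or n x 2 matrix)
#'   the match was computed on.
#' @param result the corresponding [match_fixations()] result.
#' @param image_size `c(width, height)` in pixels (taken from the sequence
#'   if absent).
#' @param sigma_deg Gaussian kernel sigma in degrees (default 1).
#' @param geom a [screen_geometry()].
#' @return list with `matched` and `leftover` [make_density_map()] objects.
#' @export
matched_maps <- function(encoding, result, image_size = NULL, sigma_deg = 1, geom) {
  stopifnot(inherits(result, "match_result"))
  p <- positions(encoding)
  if (nrow(p) != result$n_encoding) {
    stop("encoding set does not match the match_result (different sizes)")
  }
  if (is.null(image_size)) {
    if (inherits(encoding, "fixation_sequence") && !is.null(encoding$image_size)) {
      image_size <- encoding$image_size
    } else stop("image_size is required")
  }
  list(matched = make_density_map(p[result$matched_encoding, , drop = FALSE],
                                  image_size, sigma_deg, geom, kind = "matched_encoding"),
       leftover = make_density_map(p[result$leftover_encoding, , drop = FALSE],
                                   image_size, sigma_deg, geom, kind = "leftover"))
}

#' Reduction-rate sweep over matching radii
#'
#' @param encoding encoding positions.
#' @param relocated relocated (or raw) recall positions.
#' @param epsilons matching radii in degrees (default `1:10`).
#' @param geom a [screen_geometry()].
#' @return data.frame with columns `epsilon_deg`, `reduction_rate`,
#'   `matched_fraction`.
#' @export
epsilon_sweep <- function(encoding, relocated, epsilons = 1:10, geom) {
  rr <- vapply(epsilons, function(e) {
    reduction_rate(match_fixations(encoding, relocated, e, geom))
  }, numeric(1))
  data.frame(epsilon_deg = epsilons, reduction_rate = rr,
             matched_fraction = 1 - rr)
}
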