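# Validation metrics: map-to-map Pearson correlation and map-to-points
# ROC area (Judd-style AUC), plus the per-image comparison table against
# clicking data.

#' Pixel-wise Pearson correlation between two maps
#'
#' @param map_a,map_b `density_map`s (or matrices) of identical shape, each
#'   with positive variance.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(map_a, map_b) {
  a <- as.numeric(.map_grid(map_a)); b <- as.numeric(.map_grid(map_b))
  if (length(a) != length(b)) stop("maps must have the same shape")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("pearson_cc undefined for a constant map")
  }
  stats::cor(a, b)
}

#' ROC area of a density map against point positives (Judd convention)
#'
#' The map is treated as a classifier of pixels: thresholds sweep over the
#' distinct map values attained at the positive locations; at each
#' threshold the true-positive rate is the fraction of positives at or
#' above it and the false-positive rate is the fraction of the remaining
#' (non-positive) pixels at or above it.  The area under the resulting ROC
#' curve is computed by trapezoidal integration.  Because only the ordering
#' of map values matters, the AUC is invariant under strictly monotone
#' transforms of the map.
#'
#' @param map a `density_map` (or matrix).
#' @param positives positions in pixels (n x 2), inside the map.
#' @return AUC in `[0, 1]`; a constant map returns 0.5 with a warning.
#' @export
auc_judd <- function(map, positives) {
  g <- .map_grid(map)
  pts <- positions(positives)
  if (nrow(pts) < 1) stop("at least one positive location is required")
  h <- nrow(g); w <- ncol(g)
  col <- round(pts[, 1]) + 1L
  row <- round(pts[, 2]) + 1L
  if (any(col < 1 | col > w | row < 1 | row > h)) {
    stop("positive locations must lie inside the map")
  }
  if (diff(range(g)) == 0) {
    warning("constant map: AUC is 0.5 by convention")
    return(0.5)
  }
  lin <- (col - 1L) * h + row
  v <- g[lin]
  rest <- g[-unique(lin)]
  th <- sort(unique(v), decreasing = TRUE)
  # counts >= threshold via sorted vectors (O((n+m) log))
  sv <- sort(v); sr <- sort(rest)
  n_ge <- function(sorted, t) length(sorted) - findInterval(t, sorted, left.open = TRUE)
  tp <- vapply(th, function(t) n_ge(sv, t), numeric(1)) / length(v)
  fp <- if (length(sr)) vapply(th, function(t) n_ge(sr, t), numeric(1)) / length(sr)
        else rep(0, length(th))
  fp <- c(0, fp, 1); tp <- c(0, tp, 1)
  ord <- order(fp, tp)
  fp <- fp[ord]; tp <- tp[ord]
  sum(diff(fp) * (tp[-1] + tp[-length(tp)]) / 2)
}

#' Compare map kinds against clicking data
#'
#' For each image, every supplied map kind is scored against the clicking
#' data twice: Pearson correlation against the clicking *map* (built from
#' the clicks at `click_sigma_deg`), and Judd AUC using the raw click
#' *positions* as positives.  Missing kinds for an image are skipped with a
#' message; images without clicks are skipped likewise.
#'
#' @param maps_by_kind named list: one entry per image id, each a named list
#'   of `density_map`s keyed by kind (`encoding`, `matched_encoding`, ...).
#' @param clicks a [load_clicks()] table (columns `participant`, `image`,
#'   `x`, `y`).
#' @param geom a [screen_geometry()].
#' @param click_sigma_deg kernel for the clicking map, degrees (default 2).
#' @return data.frame with columns `image`, `map_kind`, `metric`
#'   (`"cc"` or `"auc"`), `value`; aggregate means available via
#'   [aggregate_scores()].
#' @export
compare_conditions <- function(maps_by_kind, clicks, geom, click_sigma_deg = 2) {
  rows <- list()
  for (img in names(maps_by_kind)) {
    kinds <- maps_by_kind[[img]]
    ck <- clicks[clicks$image == img, , drop = FALSE]
    if (nrow(ck) == 0) {
      message("no clicks for image ", img, "; skipped")
      next
    }
    any_map <- kinds[[1]]
    image_size <- c(ncol(any_map$grid), nrow(any_map$grid))
    click_map <- make_density_map(ck, image_size, click_sigma_deg, geom,
                                  kind = "clicking")
    click_pts <- positions(ck)
    for (kind in names(kinds)) {
      m <- kinds[[kind]]
      if (is.null(m)) {
        message("image ", img, ": no '", kind, "' map; cell absent")
        next
      }
      cc <- tryCatch(pearson_cc(m, click_map), error = function(e) NA_real_)
      auc <- tryCatch(suppressWarnings(auc_judd(m, click_pts)),
                      error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        image = img, map_kind = kind,
        metric = c("cc", "auc"), value = c(cc, auc))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(image = character(0), map_kind = character(0),
                                      metric = character(0), value = numeric(0))
  rownames(out) <- NULL
  out
}

#' Aggregate a score table over images
#'
#' @param scores a [compare_conditions()] table.
#' @return data.frame of mean `value` per (`map_kind`, `metric`).
#' @export
aggregate_scores <- function(scores) {
  stats::aggregate(value ~ map_kind + metric, data = scores,
                   FUN = mean, na.rm = TRUE)
}
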