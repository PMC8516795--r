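# End-to-end synthetic validation: do the maps produced by relocation and
# matching agree with independently "clicked" important regions better than
# maps from randomly paired recall sequences?

#' Synthetic clicking-validation experiment
#'
#' Generates a suite of synthetic trials, simulates click data by sampling
#' encoding positions (plus isotropic noise of `click_sigma_deg`) -- i.e.
#' clicks concentrate on the synthetic scene's fixated objects -- then
#' relocates and matches each trial and scores the four map kinds
#' (`encoding`, `matched_encoding`, `recall`, `relocated_recall`) against
#' the clicking data with [compare_conditions()].  With `permute = TRUE`
#' the recall sequences are cyclically permuted across images before
#' relocation, the random-pairing baseline: scores should drop.
#'
#' @param n_images number of images (one trial each).
#' @param spec a [distortion_spec()].
#' @param params an [algorithm_params()].
#' @param geom a [screen_geometry()].
#' @param n_encoding encoding fixations per trial.
#' @param image_size stimulus size in pixels.
#' @param n_clicks clicks simulated per image.
#' @param sigma_deg kernel for the gaze density maps, degrees.
#' @param base_seed RNG seed.
#' @param permute if `TRUE`, recall sequences are permuted across images
#'   before relocation (identity pairing otherwise).
#' @return list with `scores` (the [compare_conditions()] table),
#'   `aggregate` (its mean per kind/metric) and `clicks`.
#' @export
validation_experiment <- function(n_images = 10, spec = distortion_spec(),
                                  params = algorithm_params(),
                                  geom = default_geometry(),
                                  n_encoding = 16, image_size = c(1024, 768),
                                  n_clicks = 8, sigma_deg = 1,
                                  base_seed = 1L, permute = FALSE) {
  trials <- synthetic_suite(n_images, spec, n_encoding, image_size, geom,
                            base_seed)
  ids <- vapply(trials, function(t) t$encoding$image_id, character(1))
  clicks <- .with_seed(as.integer(base_seed) + 7777L, {
    do.call(rbind, lapply(trials, function(tr) {
      enc <- positions(tr$encoding)
      src <- enc[sample(nrow(enc), n_clicks, replace = TRUE), , drop = FALSE]
      pos <- src + matrix(stats::rnorm(2 * n_clicks,
                                       sd = deg_to_px(0.5, geom)), ncol = 2)
      pos[, 1] <- pmin(pmax(pos[, 1], 0), image_size[1] - 1)
      pos[, 2] <- pmin(pmax(pos[, 2], 0), image_size[2] - 1)
      data.frame(participant = "click", image = tr$encoding$image_id,
                 x = pos[, 1], y = pos[, 2], latency = NA_real_)
    }))
  })
  pairing <- if (permute && n_images > 1) c(2:n_images, 1L) else seq_len(n_images)
  maps <- stats::setNames(vector("list", n_images), ids)
  for (i in seq_len(n_images)) {
    tr <- trials[[i]]
    rec <- trials[[pairing[i]]]$recall
    res <- relocate(tr$encoding, rec, params, geom)
    mt <- match_fixations(tr$encoding, res$relocated, params$epsilon_deg, geom)
    mm <- matched_maps(tr$encoding, mt, image_size, sigma_deg, geom)
    maps[[ids[i]]] <- list(
      encoding = make_density_map(tr$encoding, image_size, sigma_deg, geom,
                                  kind = "encoding"),
      matched_encoding = mm$matched,
      recall = make_density_map(rec, image_size, sigma_deg, geom,
                                kind = "recall"),
      relocated_recall = make_density_map(res$relocated, image_size,
                                          sigma_deg, geom,
                                          kind = "relocated_recall"))
  }
  scores <- compare_conditions(maps, clicks, geom)
  list(scores = scores, aggregate = aggregate_scores(scores), clicks = clicks)
}
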