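# Synthetic encoding/recall trials with ground-truth correspondence.
#
# The generator emulates the data regime of a looking-at-nothing session on
# the default apparatus: about 16 encoding fixations (5 s of free viewing)
# clustered on a few scene objects with a central bias, and about 11 recall
# fixations that revisit a retained subset of encoding positions, distorted
# by a global rigid transform, a shrink toward the image centre, a smooth
# low-frequency deformation field, per-fixation jitter, and the occasional
# spurious fixation unrelated to any encoding position.

#' Distortion specification for synthetic recall data
#'
#' Defaults state the regime the relocation algorithm targets: a modest
#' global misalignment (3 degrees rotation, tens of pixels of translation,
#' 10% shrink toward the centre reflecting the central bias of recall),
#' a smooth local deformation of about 20 px RMS with a long correlation
#' length (so ground truth stays recoverable), small per-fixation jitter,
#' roughly two thirds of encoding fixations retained (16 encoding vs ~11
#' recall fixations), and one spurious fixation per trial.
#'
#' @param rotation_deg global rotation about the image centre, degrees.
#' @param translation_px global translation `c(dx, dy)`, pixels.
#' @param scale_bias shrink factor toward the image centre (1 = none).
#' @param deform_amp_px RMS magnitude of the smooth deformation field, px.
#' @param deform_scale_px correlation length of the deformation field, px.
#' @param jitter_sigma_px per-fixation isotropic Gaussian jitter, px.
#' @param retention fraction of encoding fixations revisited in recall,
#'   in `(0, 1]`.
#' @param n_spurious number of unrelated recall fixations.
#' @param seed RNG seed for trial generation.
#' @return list of class `distortion_spec`.
#' @export
distortion_spec <- function(rotation_deg = 3, translation_px = c(40, -25),
                            scale_bias = 0.9, deform_amp_px = 20,
                            deform_scale_px = 300, jitter_sigma_px = 5,
                            retention = 0.65, n_spurious = 1, seed = 1L) {
  if (retention <= 0 || retention > 1) stop("retention must be in (0, 1]")
  if (scale_bias <= 0) stop("scale_bias must be positive")
  if (deform_amp_px < 0 || jitter_sigma_px < 0) stop("amplitudes must be >= 0")
  if (deform_scale_px <= 0) stop("deform_scale_px must be positive")
  if (n_spurious < 0) stop("n_spurious must be >= 0")
  if (length(translation_px) != 2) stop("translation_px must be length 2")
  structure(list(rotation_deg = rotation_deg,
                 translation_px = as.numeric(translation_px),
                 scale_bias = scale_bias, deform_amp_px = deform_amp_px,
                 deform_scale_px = deform_scale_px,
                 jitter_sigma_px = jitter_sigma_px, retention = retention,
                 n_spurious = as.integer(n_spurious),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "distortion_spec")
}

# run expr under a private RNG stream seeded with `seed` (NULL = use the
# ambient stream), restoring the caller's stream afterwards
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# smooth random displacement field: sum of K random-plane-wave sinusoids per
# component, band-limited at wavelength `scale`, scaled so that the vector
# displacement has RMS `amp` over random phases
.random_deform_field <- function(amp, scale, K = 6L) {
  if (amp <= 0) return(function(p) matrix(0, nrow(p), 2))
  dirs <- matrix(stats::rnorm(2 * K * 2), ncol = 2)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  phases <- stats::runif(2 * K, 0, 2 * pi)
  coef <- stats::rnorm(2 * K)
  # each component: sum_k c_k sin(2 pi <p, u_k>/scale + phi_k); variance over
  # phases is sum c_k^2 / 2 -> normalise each component to sd amp/sqrt(2)
  c1 <- coef[1:K]; c1 <- c1 / sqrt(sum(c1^2) / 2) * amp / sqrt(2)
  c2 <- coef[(K + 1):(2 * K)]; c2 <- c2 / sqrt(sum(c2^2) / 2) * amp / sqrt(2)
  function(p) {
    p <- positions(p)
    dx <- numeric(nrow(p)); dy <- numeric(nrow(p))
    for (k in seq_len(K)) {
      dx <- dx + c1[k] * sin(2 * pi * (p %*% dirs[k, ]) / scale + phases[k])
      dy <- dy + c2[k] * sin(2 * pi * (p %*% dirs[K + k, ]) / scale + phases[K + k])
    }
    cbind(dx, dy)
  }
}

.rot2 <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Generate one synthetic encoding/recall trial
#'
#' Encoding positions are drawn from a mixture of 2--4 Gaussian "object"
#' clusters plus a broad central-bias component.  Recall positions are a
#' retained subset of the encoding positions (`round(retention * n)`),
#' shrunk toward the image centre, rotated and translated globally,
#' displaced by a smooth random deformation field (evaluated at the source
#' positions), jittered, and presented in shuffled order together with
#' `n_spurious` unrelated fixations drawn uniformly over the central 80% of
#' the image.  Durations mimic the empirical regime (encoding ~278 ms,
#' recall ~452 ms).  Trials are bit-reproducible given `spec$seed`.
#'
#' @param n_encoding number of encoding fixations (default 16, >= 2).
#' @param spec a [distortion_spec()].
#' @param image_size stimulus size `c(width, height)` px (default
#'   `c(1024, 768)`).
#' @param geom a [screen_geometry()].
#' @param participant_id,image_id labels for the generated sequences.
#' @param cluster_sd_deg within-cluster fixation spread, degrees.  The
#'   default 0.5 (refixations on an object subtending about 2 degrees) was
#'   calibrated so the per-trial 2-D fixation entropy averages about 0.40
#'   on the default 16 x 16 grid -- inside the plausible empirical range and
#'   clearly below the ceiling of 0.5 attainable by 16 fixations.
#' @return object of class `synthetic_trial`: list with `encoding` and
#'   `recall` ([fixation_sequence()]s), `truth` (per recall fixation, the
#'   1-based encoding index it came from, `NA` for spurious) and
#'   `true_positions` (the undistorted source positions, rows of `NA` for
#'   spurious fixations).
#' @export
generate_trial <- function(n_encoding = 16, spec = distortion_spec(),
                           image_size = c(1024, 768),
                           geom = default_geometry(),
                           participant_id = "synth", image_id = "img1",
                           cluster_sd_deg = 0.5) {
  stopifnot(inherits(spec, "distortion_spec"))
  if (n_encoding < 2) stop("n_encoding must be >= 2")
  .with_seed(spec$seed, {
    ctr <- image_size / 2
    # --- encoding: 2-4 object clusters + central bias
    k <- sample(2:4, 1)
    cl_ctr <- cbind(stats::runif(k, 0.15, 0.85) * image_size[1],
                    stats::runif(k, 0.15, 0.85) * image_size[2])
    cl_sd <- deg_to_px(cluster_sd_deg, geom)
    from_center <- stats::runif(n_encoding) < 0.25
    which_cl <- sample(k, n_encoding, replace = TRUE)
    enc <- matrix(NA_real_, n_encoding, 2)
    for (i in seq_len(n_encoding)) {
      enc[i, ] <- if (from_center[i]) {
        ctr + stats::rnorm(2, sd = 0.15 * image_size)
      } else {
        cl_ctr[which_cl[i], ] + stats::rnorm(2, sd = cl_sd)
      }
    }
    margin <- 5
    enc[, 1] <- pmin(pmax(enc[, 1], margin), image_size[1] - margin)
    enc[, 2] <- pmin(pmax(enc[, 2], margin), image_size[2] - margin)
    dur_enc <- pmax(stats::rnorm(n_encoding, 278, 73.4), 50)

    # --- recall: retained subset, distorted
    n_ret <- max(1L, as.integer(round(spec$retention * n_encoding)))
    sel <- sort(sample(n_encoding, n_ret))
    true_pos <- enc[sel, , drop = FALSE]
    pos <- sweep(sweep(true_pos, 2, ctr), 2, rep(spec$scale_bias, 2), `*`)
    pos <- sweep(pos %*% t(.rot2(spec$rotation_deg)), 2, ctr, `+`)
    pos <- sweep(pos, 2, spec$translation_px, `+`)
    field <- .random_deform_field(spec$deform_amp_px, spec$deform_scale_px)
    pos <- pos + field(true_pos)
    if (spec$jitter_sigma_px > 0) {
      pos <- pos + matrix(stats::rnorm(2 * n_ret, sd = spec$jitter_sigma_px),
                          ncol = 2)
    }
    truth <- sel
    if (spec$n_spurious > 0) {
      sp <- cbind(stats::runif(spec$n_spurious, 0.1, 0.9) * image_size[1],
                  stats::runif(spec$n_spurious, 0.1, 0.9) * image_size[2])
      pos <- rbind(pos, sp)
      truth <- c(truth, rep(NA_integer_, spec$n_spurious))
      true_pos <- rbind(true_pos, matrix(NA_real_, spec$n_spurious, 2))
    }
    ord <- sample(nrow(pos))   # temporal order is not preserved in recall
    pos <- pos[ord, , drop = FALSE]
    truth <- truth[ord]
    true_pos <- true_pos[ord, , drop = FALSE]
    dur_rec <- pmax(stats::rnorm(nrow(pos), 452.2, 308), 80)

    structure(list(
      encoding = fixation_sequence(enc[, 1], enc[, 2], dur_enc,
                                   phase = "encoding",
                                   participant_id = participant_id,
                                   image_id = image_id,
                                   image_size = image_size),
      recall = fixation_sequence(pos[, 1], pos[, 2], dur_rec,
                                 phase = "recall",
                                 participant_id = participant_id,
                                 image_id = image_id,
                                 image_size = image_size),
      truth = truth,
      true_positions = true_pos),
      class = "synthetic_trial")
  })
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> %d encoding, %d recall fixations (%d spurious)\n",
              length(x$encoding), length(x$recall), sum(is.na(x$truth))))
  invisible(x)
}

#' A default suite of synthetic trials
#'
#' @param n_trials number of trials.
#' @param spec base [distortion_spec()]; per-trial seeds are derived from
#'   `base_seed`.
#' @param n_encoding encoding fixations per trial.
#' @param image_size,geom as in [generate_trial()].
#' @param base_seed integer seed from which per-trial seeds are derived.
#' @return list of `synthetic_trial`s.
#' @export
synthetic_suite <- function(n_trials, spec = distortion_spec(),
                            n_encoding = 16, image_size = c(1024, 768),
                            geom = default_geometry(), base_seed = 1L) {
  lapply(seq_len(n_trials), function(i) {
    sp <- spec
    sp$seed <- (as.integer(base_seed) * 1009L + i) %% 2147483647L
    generate_trial(n_encoding, sp, image_size, geom,
                   participant_id = "synth",
                   image_id = sprintf("img%03d", i))
  })
}

#' Relocation recovery experiment on synthetic trials
#'
#' Runs [relocate()] and [match_fixations()] on a suite of generated trials
#' and scores the result against the known ground truth: the mean relocation
#' error (distance from each relocated non-spurious recall fixation to its
#' true encoding source, in degrees), matched fractions over a sweep of
#' matching radii for both relocated and raw recall positions, and the
#' false-match fraction (correspondence pairs whose recall fixation is
#' spurious).
#'
#' @param n_trials number of trials (>= 1).
#' @param spec a [distortion_spec()].
#' @param params an [algorithm_params()].
#' @param geom a [screen_geometry()].
#' @param n_encoding encoding fixations per trial.
#' @param image_size stimulus size in pixels.
#' @param epsilons matching radii to sweep, degrees.
#' @param base_seed seed for the trial suite.
#' @return list of class `recovery_summary` with elements `per_trial`
#'   (data.frame: relocation error, matched fractions at `epsilons[1]`,
#'   iterations, convergence, false-match fraction), `curves` (mean matched
#'   fraction and reduction rate per epsilon, relocated and raw) and
#'   `summary` (named means).
#' @export
recovery_experiment <- function(n_trials = 100, spec = distortion_spec(),
                                params = algorithm_params(),
                                geom = default_geometry(),
                                n_encoding = 16, image_size = c(1024, 768),
                                epsilons = 1:10, base_seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  trials <- synthetic_suite(n_trials, spec, n_encoding, image_size, geom,
                            base_seed)
  ne <- length(epsilons)
  rr_rel <- matrix(NA_real_, n_trials, ne)
  rr_raw <- matrix(NA_real_, n_trials, ne)
  per <- data.frame(trial = seq_len(n_trials), relocation_error_deg = NA_real_,
                    matched_fraction_relocated = NA_real_,
                    matched_fraction_raw = NA_real_,
                    false_match_fraction = NA_real_,
                    iterations = NA_integer_, converged = NA)
  for (i in seq_len(n_trials)) {
    tr <- trials[[i]]
    res <- relocate(tr$encoding, tr$recall, params, geom)
    raw <- positions(tr$recall)
    ok <- !is.na(tr$truth)
    err_px <- sqrt(rowSums((res$relocated[ok, , drop = FALSE] -
                            tr$true_positions[ok, , drop = FALSE])^2))
    per$relocation_error_deg[i] <- mean(px_to_deg(err_px, geom))
    for (e in seq_len(ne)) {
      rr_rel[i, e] <- reduction_rate(
        match_fixations(tr$encoding, res$relocated, epsilons[e], geom))
      rr_raw[i, e] <- reduction_rate(
        match_fixations(tr$encoding, raw, epsilons[e], geom))
    }
    m1 <- match_fixations(tr$encoding, res$relocated, epsilons[1], geom)
    per$matched_fraction_relocated[i] <- 1 - rr_rel[i, 1]
    per$matched_fraction_raw[i] <- 1 - rr_raw[i, 1]
    per$false_match_fraction[i] <- if (nrow(m1$correspondences)) {
      mean(is.na(tr$truth[m1$correspondences$recall]))
    } else 0
    per$iterations[i] <- res$iterations_run
    per$converged[i] <- res$converged
  }
  curves <- data.frame(
    epsilon_deg = epsilons,
    reduction_rate_relocated = colMeans(rr_rel),
    reduction_rate_raw = colMeans(rr_raw),
    matched_fraction_relocated = 1 - colMeans(rr_rel),
    matched_fraction_raw = 1 - colMeans(rr_raw))
  structure(list(
    per_trial = per, curves = curves,
    reduction_by_trial = list(relocated = rr_rel, raw = rr_raw),
    summary = c(mean_relocation_error_deg = mean(per$relocation_error_deg),
                mean_matched_fraction_relocated = mean(per$matched_fraction_relocated),
                mean_matched_fraction_raw = mean(per$matched_fraction_raw),
                mean_false_match_fraction = mean(per$false_match_fraction),
                mean_iterations = mean(per$iterations),
                convergence_rate = mean(per$converged))),
    class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("<recovery_summary>\n")
  s <- x$summary
  for (nm in names(s)) cat(sprintf("  %-34s %.4f\n", nm, s[[nm]]))
  invisible(x)
}
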