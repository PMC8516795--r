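#' Fixation sequence
#'
#' An ordered set of fixations for one participant, image and phase.
#' Positions are in screen pixels with the image convention: origin at the
#' top-left, x rightward, y downward.
#'
#' @param x,y fixation positions in pixels.
#' @param duration fixation durations in ms (>= 0); recycled if scalar.
#' @param onset fixation onsets in ms; if `NULL`, synthesised as the
#'   cumulative sum of preceding durations (keeps input order).
#' @param phase `"encoding"` (viewing the stimulus) or `"recall"`
#'   (looking-at-nothing on a blank screen).
#' @param participant_id,image_id labels identifying the trial.
#' @param image_size stimulus size `c(width, height)` in pixels, or `NULL`.
#' @param index ordinal index of each fixation (0-based); defaults to the
#'   onset order.
#'
#' @return An object of class `fixation_sequence`: a list with element
#'   `fixations` (a data.frame with columns `x`, `y`, `duration`, `onset`,
#'   `index`, sorted by onset) plus the identifying fields.
#' @export
fixation_sequence <- function(x, y, duration = 0, onset = NULL,
                              phase = c("encoding", "recall"),
                              participant_id = "p1", image_id = "img1",
                              image_size = NULL, index = NULL) {
  phase <- match.arg(phase)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n > 0 && (any(!is.finite(x)) || any(!is.finite(y)))) {
    stop("fixation positions must be finite")
  }
  duration <- rep_len(as.numeric(duration), n)
  if (any(duration < 0)) stop("durations must be >= 0")
  if (is.null(onset)) {
    onset <- if (n > 0) cumsum(c(0, duration[-n])) else numeric(0)
  }
  onset <- rep_len(as.numeric(onset), n)
  if (any(onset < 0)) stop("onsets must be >= 0")
  ord <- order(onset)
  if (is.null(index)) index <- seq_len(n) - 1L
  index <- rep_len(as.integer(index), n)
  if (anyDuplicated(index)) stop("fixation indices must be unique within a sequence")
  fx <- data.frame(x = as.numeric(x)[ord], y = as.numeric(y)[ord],
                   duration = duration[ord], onset = onset[ord],
                   index = index[ord])
  if (!is.null(image_size)) {
    image_size <- as.numeric(image_size)
    if (length(image_size) != 2 || any(!is.finite(image_size)) || any(image_size <= 0)) {
      stop("image_size must be c(width, height), both positive")
    }
  }
  structure(list(fixations = fx, phase = phase,
                 participant_id = as.character(participant_id),
                 image_id = as.character(image_id),
                 image_size = image_size),
            class = "fixation_sequence")
}

#' @export
print.fixation_sequence <- function(x, ...) {
  cat(sprintf("<fixation_sequence> %s / %s / %s: %d fixations\n",
              x$participant_id, x$image_id, x$phase, nrow(x$fixations)))
  invisible(x)
}

#' @export
length.fixation_sequence <- function(x) nrow(x$fixations)

#' Extract fixation positions as an n x 2 matrix
#'
#' @param x a `fixation_sequence`, an n x 2 matrix, or a data.frame with
#'   `x`/`y` columns.
#' @return numeric matrix with columns `x`, `y`.
#' @export
positions <- function(x) {
  if (inherits(x, "fixation_sequence")) {
    return(cbind(x = x$fixations$x, y = x$fixations$y))
  }
  if (is.data.frame(x)) return(cbind(x = as.numeric(x$x), y = as.numeric(x$y)))
  if (is.matrix(x)) {
    if (ncol(x) != 2) stop("position matrices must have two columns")
    colnames(x) <- c("x", "y")
    return(x)
  }
  if (is.numeric(x) && length(x) == 2) return(matrix(x, 1, 2, dimnames = list(NULL, c("x", "y"))))
  stop("cannot interpret object as positions")
}

# ---------------------------------------------------------------------------
# IO

#' Column dialect for delimited fixation files
#'
#' Maps the package's canonical column names onto the column headers of a
#' particular file format.  `phase_value` supplies a constant phase for files
#' that carry only one phase and no phase column (e.g. eye-tracker exports).
#'
#' @param sep field separator.
#' @param participant,image,phase,x,y,duration,onset column names in the file.
#' @param phase_value optional constant phase label used when the file has no
#'   phase column.
#' @return a named list of class `fixation_dialect`.
#' @export
fixation_dialect <- function(sep = ",", participant = "participant",
                             image = "image", phase = "phase",
                             x = "x", y = "y", duration = "duration",
                             onset = "onset", phase_value = NULL) {
  structure(list(sep = sep, participant = participant, image = image,
                 phase = phase, x = x, y = y, duration = duration,
                 onset = onset, phase_value = phase_value),
            class = "fixation_dialect")
}

#' Dialect for EyeLink fixation-report exports
#'
#' Tab-separated fixation reports with `CURRENT_FIX_X`, `CURRENT_FIX_Y`,
#' `CURRENT_FIX_DURATION` and `CURRENT_FIX_START` columns.  Such exports
#' contain a single phase, given by `phase_value`.
#'
#' @param phase_value phase label to assign to every row.
#' @return a `fixation_dialect`.
#' @export
eyelink_dialect <- function(phase_value = "encoding") {
  fixation_dialect(sep = "\t",
                   participant = "RECORDING_SESSION_LABEL",
                   image = "TRIAL_INDEX", phase = "phase",
                   x = "CURRENT_FIX_X", y = "CURRENT_FIX_Y",
                   duration = "CURRENT_FIX_DURATION",
                   onset = "CURRENT_FIX_START",
                   phase_value = phase_value)
}

#' Read fixation sequences from a delimited text file
#'
#' @param path file path.
#' @param dialect a [fixation_dialect()] describing the columns.
#' @param image_size optional stimulus size attached to every sequence.
#'
#' @details Mandatory columns are participant, image, phase (unless
#'   `phase_value` is set in the dialect), x, y and duration; a missing
#'   mandatory column is a schema error naming that column.  Rows with
#'   unparseable numeric fields raise an error naming the offending data
#'   rows; nothing is silently dropped.  Onsets, when absent, are
#'   synthesised from cumulative durations within each sequence.
#'
#' @return a list of [fixation_sequence()] objects, grouped by
#'   participant x image x phase and sorted by onset; an empty file yields
#'   an empty list with a warning.
#' @export
load_fixations <- function(path, dialect = fixation_dialect(), image_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (nrow(df) == 0) {
    warning("no data rows in ", path)
    return(list())
  }
  need <- c("participant", "image", "x", "y", "duration")
  if (is.null(dialect$phase_value)) need <- c(need, "phase")
  for (canon in need) {
    col <- dialect[[canon]]
    if (!col %in% names(df)) {
      stop(sprintf("missing mandatory column '%s' (expected for '%s') in %s",
                   col, canon, path))
    }
  }
  num <- function(canon, mandatory = TRUE) {
    col <- dialect[[canon]]
    if (!col %in% names(df)) {
      if (mandatory) stop(sprintf("missing mandatory column '%s'", col))
      return(NULL)
    }
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & raw != "" & toupper(raw) != "NA")
    if (length(bad)) {
      stop(sprintf("column '%s': non-numeric value on data row(s) %s",
                   col, paste(bad, collapse = ", ")))
    }
    val
  }
  out <- data.frame(
    participant = df[[dialect$participant]],
    image = df[[dialect$image]],
    phase = if (is.null(dialect$phase_value)) df[[dialect$phase]] else dialect$phase_value,
    x = num("x"), y = num("y"), duration = num("duration"),
    stringsAsFactors = FALSE)
  onset <- num("onset", mandatory = FALSE)
  out$onset <- if (is.null(onset)) NA_real_ else onset
  bad_phase <- !out$phase %in% c("encoding", "recall")
  if (any(bad_phase)) {
    stop("unknown phase value(s): ", paste(unique(out$phase[bad_phase]), collapse = ", "))
  }
  key <- paste(out$participant, out$image, out$phase, sep = "\r")
  lapply(split(seq_len(nrow(out)), factor(key, levels = unique(key))), function(i) {
    g <- out[i, ]
    fixation_sequence(g$x, g$y, g$duration,
                      onset = if (all(is.na(g$onset))) NULL else g$onset,
                      phase = g$phase[1], participant_id = g$participant[1],
                      image_id = g$image[1], image_size = image_size)
  }) |> unname()
}

# full-precision numeric formatting so that write -> read round-trips
# reproduce doubles bit-identically
.fmt_num <- function(v) {
  out <- sprintf("%.17g", v)
  out[!is.finite(v)] <- as.character(v[!is.finite(v)])
  out
}

#' Write fixation sequences to CSV
#'
#' Writes the canonical schema (`participant,image,phase,x,y,duration,onset`)
#' with full-precision numerics, so a write/read round trip reproduces
#' positions and durations bit-identically.  Extra per-fixation columns
#' (e.g. relocated positions) can be supplied via `extra`.
#'
#' @param seqs a list of [fixation_sequence()] objects (or a single one).
#' @param path output file path.
#' @param extra optional data.frame with one row per written fixation,
#'   appended column-wise.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(seqs, path, extra = NULL) {
  if (inherits(seqs, "fixation_sequence")) seqs <- list(seqs)
  rows <- lapply(seqs, function(s) {
    f <- s$fixations
    data.frame(participant = s$participant_id, image = s$image_id,
               phase = s$phase, x = .fmt_num(f$x), y = .fmt_num(f$y),
               duration = .fmt_num(f$duration), onset = .fmt_num(f$onset),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(participant = character(0), image = character(0),
                                    phase = character(0), x = character(0),
                                    y = character(0), duration = character(0),
                                    onset = character(0))
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == nrow(df))
    for (cn in names(extra)) {
      df[[cn]] <- if (is.numeric(extra[[cn]])) .fmt_num(extra[[cn]]) else extra[[cn]]
    }
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a click table
#'
#' Click positions mark scene regions participants judged subjectively
#' important; they are used to build clicking maps for validation.
#'
#' @param path CSV with columns `participant,image,x,y` and optionally
#'   `latency` (seconds).
#' @param image_size optional `c(width, height)`; when given, clicks outside
#'   the image bounds are removed (with a message stating how many).
#' @return data.frame of class `click_table`.
#' @export
load_clicks <- function(path, image_size = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "image", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column '", miss[1], "' in ", path)
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  if (!"latency" %in% names(df)) df$latency <- NA_real_
  if (!is.null(image_size)) {
    keep <- df$x >= 0 & df$x <= image_size[1] & df$y >= 0 & df$y <= image_size[2]
    if (any(!keep)) message("dropping ", sum(!keep), " click(s) outside image bounds")
    df <- df[keep, , drop = FALSE]
  }
  class(df) <- c("click_table", class(df))
  df
}

#' Remove an initial centre fixation
#'
#' Gaze recordings that start from a central fixation marker begin with a
#' fixation on the display centre that carries no information about the
#' stimulus; by convention it is removed before building density maps.
#' Removal is positional -- the first fixation is dropped only if it lies
#' within `radius_deg` of the image centre -- so genuine first fixations on
#' centred content of interest are kept when they fall outside the radius.
#'
#' @param seq a [fixation_sequence()] with a known `image_size`.
#' @param geom a [screen_geometry()].
#' @param radius_deg removal radius around the centre, degrees (default 1).
#' @return the sequence, with its first fixation removed iff it was central.
#'   An empty sequence is returned unchanged.
#' @export
drop_first_center_fixation <- function(seq, geom, radius_deg = 1) {
  stopifnot(inherits(seq, "fixation_sequence"))
  if (nrow(seq$fixations) == 0) return(seq)
  if (is.null(seq$image_size)) stop("sequence has no image_size; cannot locate the centre")
  ctr <- seq$image_size / 2
  f1 <- seq$fixations[1, ]
  d <- sqrt((f1$x - ctr[1])^2 + (f1$y - ctr[2])^2)
  if (d <= deg_to_px(radius_deg, geom)) {
    seq$fixations <- seq$fixations[-1, , drop = FALSE]
  }
  seq
}
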