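#' Viewport-proportional areas of interest
#'
#' Webcam gaze estimates arrive as raw x/y pixel coordinates, so the two
#' picture regions are reconstructed post hoc as fixed proportions of each
#' participant's viewport: the left AOI spans 15%-45% of the screen width,
#' the right AOI 55%-85%, and both start at 22.5% of the screen height and
#' are half the screen high, ending at 72.5% (screen origin top-left, y
#' increasing downward). On a 1920 x 1080 screen the left AOI therefore runs
#' from x = 288 to x = 864 and from y = 0.225 x 1080 = 243 to
#' y = (0.225 + 0.5) x 1080 = 783 pixels. AOI membership uses half-open intervals `[start, end)` on
#' both axes so every point maps to exactly one of left / right / neither.
#'
#' @param viewport list or data.frame row with `width_px` and `height_px`
#'   (positive).
#' @return an object of class `aoi_pair`: list with `left` and `right` boxes
#'   (each `x_start_px`, `x_end_px`, `y_start_px`, `y_end_px`) and the
#'   viewport.
#' @export
#' @examples
#' compute_aois(list(width_px = 1920, height_px = 1080))$left
compute_aois <- function(viewport) {
  w <- as.numeric(viewport$width_px)
  h <- as.numeric(viewport$height_px)
  if (length(w) != 1 || length(h) != 1 || !is.finite(w) || !is.finite(h) ||
      w <= 0 || h <= 0)
    stop("invalid viewport: width_px and height_px must be positive scalars")
  box <- function(x0, x1) list(x_start_px = x0 * w, x_end_px = x1 * w,
                               y_start_px = 0.225 * h, y_end_px = 0.725 * h)
  out <- list(left = box(0.15, 0.45), right = box(0.55, 0.85),
              viewport = list(width_px = w, height_px = h))
  class(out) <- "aoi_pair"
  out
}

#' @export
print.aoi_pair <- function(x, ...) {
  cat(sprintf("<aoi_pair> viewport %g x %g px\n", x$viewport$width_px,
              x$viewport$height_px))
  for (s in c("left", "right"))
    cat(sprintf("  %-5s x [%g, %g), y [%g, %g)\n", s,
                x[[s]]$x_start_px, x[[s]]$x_end_px,
                x[[s]]$y_start_px, x[[s]]$y_end_px))
  invisible(x)
}

.in_box <- function(x, y, box) {
  x >= box$x_start_px & x < box$x_end_px &
    y >= box$y_start_px & y < box$y_end_px
}

#' Assign coordinate gaze samples to target / foil / none
#'
#' Classifies raw gaze coordinates against an AOI pair given the trial's
#' target side. A sample inside the box on `target_side` is `target`, inside
#' the opposite box `foil`, and otherwise `none` (to be discarded from
#' proportion denominators downstream). Membership is half-open
#' `[start, end)`, so a sample exactly on a box's right or bottom edge falls
#' outside it.
#'
#' @param x_px,y_px numeric vectors of pixel coordinates (recycled together).
#' @param aois an [compute_aois()] result.
#' @param target_side `"left"` or `"right"` (scalar or vector).
#' @return character vector in `{"target", "foil", "none"}`.
#' @export
#' @examples
#' aois <- compute_aois(list(width_px = 1920, height_px = 1080))
#' assign_sample(480, 540, aois, "left")
assign_sample <- function(x_px, y_px, aois, target_side) {
  stopifnot(inherits(aois, "aoi_pair"))
  if (anyNA(x_px) || anyNA(y_px))
    stop("already labeled: coordinate-mode samples required (x/y present)")
  n <- max(length(x_px), length(y_px), length(target_side))
  x_px <- rep_len(x_px, n); y_px <- rep_len(y_px, n)
  target_side <- rep_len(as.character(target_side), n)
  if (!all(target_side %in% c("left", "right")))
    stop("target_side must be 'left' or 'right'")
  in_l <- .in_box(x_px, y_px, aois$left)
  in_r <- .in_box(x_px, y_px, aois$right)
  side_hit <- ifelse(in_l, "left", ifelse(in_r, "right", "none"))
  ifelse(side_hit == "none", "none",
         ifelse(side_hit == target_side, "target", "foil"))
}

#' Label a mixed-modality gaze stream
#'
#' Gives every gaze sample a `target` / `foil` / `none` label. Lab-style rows
#' that already carry an AOI label (label mode) pass through verbatim;
#' web-style rows with raw coordinates are classified with
#' [assign_sample()] using the owning participant's viewport and the trial's
#' target side. Samples labeled `none` are flagged `discarded` but retained
#' in the returned table; downstream binning excludes them from proportion
#' denominators.
#'
#' @param gaze gaze-sample table: `participant_id`, `trial_id`, `modality`,
#'   `timestamp_ms`, and either `aoi_label` or `x_px`/`y_px` per row.
#' @param trials trial table carrying `trial_id` and `target_side` (one row
#'   per trial or per participant-modality-trial).
#' @param viewports viewport table: `participant_id`, `modality`,
#'   `width_px`, `height_px` (needed for coordinate-mode rows only).
#' @return the gaze table with `aoi_label` filled in and a logical
#'   `discarded` column (`TRUE` where `aoi_label == "none"`).
#' @export
label_stream <- function(gaze, trials, viewports = NULL) {
  out <- as.data.frame(gaze)
  n <- nrow(out)
  lab <- if ("aoi_label" %in% names(out)) as.character(out$aoi_label)
         else rep(NA_character_, n)

  sides <- unique(as.data.frame(trials)[, c("trial_id", "target_side")])
  if (anyDuplicated(sides$trial_id))
    stop("trial table maps a trial_id to more than one target_side")
  side_of <- match(out$trial_id, sides$trial_id)
  if (anyNA(side_of))
    stop("unmatched trial id(s) in gaze stream: ",
         paste(sort(unique(out$trial_id[is.na(side_of)])), collapse = ", "))

  coord <- which(is.na(lab))
  if (length(coord)) {
    if (is.null(viewports))
      stop("coordinate-mode samples present but no viewport table given")
    vp <- as.data.frame(viewports)
    if (any(vp$width_px <= 0) || any(vp$height_px <= 0))
      stop("invalid viewport: nonpositive dimensions")
    vkey <- paste(vp$participant_id, vp$modality)
    gkey <- paste(out$participant_id[coord], out$modality[coord])
    vi <- match(gkey, vkey)
    if (anyNA(vi))
      stop("no viewport for: ",
           paste(unique(gkey[is.na(vi)]), collapse = ", "))
    w <- vp$width_px[vi]; h <- vp$height_px[vi]
    x <- out$x_px[coord]; y <- out$y_px[coord]
    ts <- sides$target_side[side_of[coord]]
    # vectorized form of assign_sample()'s half-open box rule
    in_y <- y >= 0.225 * h & y < 0.725 * h
    in_l <- x >= 0.15 * w & x < 0.45 * w & in_y
    in_r <- x >= 0.55 * w & x < 0.85 * w & in_y
    on_tgt <- (in_l & ts == "left") | (in_r & ts == "right")
    lab[coord] <- c("target", "foil", "none")[3L - (in_l | in_r) - on_tgt]
  }
  out$aoi_label <- lab
  out$discarded <- lab == "none"
  cc <- attr(gaze, "cell_codes")
  if (!is.null(cc) && length(cc$gid) == n) attr(out, "cell_codes") <- cc
  out
}
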