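#' Stimulus geometry
#'
#' Bundle of the pixel dimensions that define a stimulus: the noise canvas,
#' the centered target region (which doubles as the default area of
#' interest), the elliptical frame, and the central fixation cross.  The
#' defaults are the full-scale design: a 300 x 350 canvas with a 200 x 220
#' target region, a 238 x 294 elliptical frame and a 12 x 12 cross.
#' Down-scaled geometries (see [make_fixtures()]) keep the same proportions
#' for fast test fixtures.
#'
#' Coordinates are row-major with row = vertical (height) and
#' col = horizontal (width).  Offsets count pixels skipped before a region
#' starts, so the default target region spans columns 51..250 and rows
#' 66..285 in 1-based R indexing.
#'
#' @param canvas_w,canvas_h canvas width and height in pixels.
#' @param target_w,target_h width and height of the centered target region.
#' @param ellipse_w,ellipse_h axis-aligned bounding box of the elliptical
#'   frame.
#' @param frame_stroke stroke width of the frame outline, pixels.
#' @param cross_size side of the square bounding box of the central cross.
#' @param cross_thickness arm thickness of the cross, pixels.
#' @return An object of class `stim_geometry`.
#' @export
stim_geometry <- function(canvas_w = 300, canvas_h = 350,
                          target_w = 200, target_h = 220,
                          ellipse_w = 238, ellipse_h = 294,
                          frame_stroke = 2,
                          cross_size = 12, cross_thickness = 2) {
  stopifnot(canvas_w > 0, canvas_h > 0, target_w > 0, target_h > 0)
  if (target_w > canvas_w || target_h > canvas_h) {
    stop("target region does not fit inside the canvas", call. = FALSE)
  }
  if ((canvas_w - target_w) %% 2L != 0L || (canvas_h - target_h) %% 2L != 0L) {
    stop("target region cannot be centered: canvas minus target must be even",
         call. = FALSE)
  }
  structure(
    list(canvas_w = as.integer(canvas_w), canvas_h = as.integer(canvas_h),
         target_w = as.integer(target_w), target_h = as.integer(target_h),
         ellipse_w = as.integer(ellipse_w), ellipse_h = as.integer(ellipse_h),
         frame_stroke = as.integer(frame_stroke),
         cross_size = as.integer(cross_size),
         cross_thickness = as.integer(cross_thickness)),
    class = "stim_geometry")
}

#' @export
print.stim_geometry <- function(x, ...) {
  cat("Stimulus geometry\n")
  cat(sprintf("  canvas : %d x %d (w x h)\n", x$canvas_w, x$canvas_h))
  cat(sprintf("  target : %d x %d, offsets (col %d, row %d)\n",
              x$target_w, x$target_h,
              (x$canvas_w - x$target_w) %/% 2L,
              (x$canvas_h - x$target_h) %/% 2L))
  cat(sprintf("  frame  : %d x %d ellipse, stroke %d\n",
              x$ellipse_w, x$ellipse_h, x$frame_stroke))
  cat(sprintf("  cross  : %d x %d, arm thickness %d\n",
              x$cross_size, x$cross_size, x$cross_thickness))
  invisible(x)
}

#' Area-of-interest specification
#'
#' Rectangular sub-region of a canvas, given as zero-based offsets plus a
#' size (half-open convention: the region covers `width` columns starting
#' after `x_offset` skipped columns).  The default AOI of a geometry is the
#' centered target region, e.g. a 200 x 220 region at offsets (50, 65) on
#' the full-scale canvas.
#'
#' @param x_offset,y_offset pixels skipped before the region starts
#'   (columns, rows).
#' @param width,height region size in pixels.
#' @return An object of class `aoi_spec`.
#' @export
aoi_spec <- function(x_offset, y_offset, width, height) {
  stopifnot(x_offset >= 0, y_offset >= 0, width > 0, height > 0)
  structure(list(x_offset = as.integer(x_offset),
                 y_offset = as.integer(y_offset),
                 width = as.integer(width), height = as.integer(height)),
            class = "aoi_spec")
}

#' @rdname aoi_spec
#' @param geometry a [stim_geometry()].
#' @export
default_aoi <- function(geometry = stim_geometry()) {
  aoi_spec((geometry$canvas_w - geometry$target_w) %/% 2L,
           (geometry$canvas_h - geometry$target_h) %/% 2L,
           geometry$target_w, geometry$target_h)
}

#' @export
print.aoi_spec <- function(x, ...) {
  cat(sprintf("AOI: %d x %d at offsets (col %d, row %d)\n",
              x$width, x$height, x$x_offset, x$y_offset))
  invisible(x)
}

#' Crop a plane to an area of interest
#'
#' @param plane a numeric matrix (rows = height).
#' @param aoi an [aoi_spec()]; must lie fully inside `plane`.
#' @return The sub-matrix covered by the AOI.
#' @export
crop_aoi <- function(plane, aoi) {
  stopifnot(is.matrix(plane), inherits(aoi, "aoi_spec"))
  if (aoi$y_offset + aoi$height > nrow(plane) ||
      aoi$x_offset + aoi$width > ncol(plane)) {
    stop("AOI extends outside the plane", call. = FALSE)
  }
  plane[(aoi$y_offset + 1L):(aoi$y_offset + aoi$height),
        (aoi$x_offset + 1L):(aoi$x_offset + aoi$width), drop = FALSE]
}

# Column-major flat indices (within an h x w plane) of the AOI pixels,
# ordered AOI-column-major so they can index plane vectors directly.
aoi_flat_index <- function(aoi, h, w) {
  rows <- (aoi$y_offset + 1L):(aoi$y_offset + aoi$height)
  cols <- (aoi$x_offset + 1L):(aoi$x_offset + aoi$width)
  as.vector(outer(rows, (cols - 1L) * h, "+"))
}
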