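#' Generate a Gaussian noise canvas
#'
#' Draws an independent Gaussian deviate per pixel, quantizes (round half
#' away from zero) and clips to the 8-bit range \[0, 255\].  The same seed
#' always reproduces the same canvas bit for bit.
#'
#' @param width,height canvas size in pixels (width = columns).
#' @param mean,sd luminance mean and standard deviation of the generating
#'   Gaussian, on the 0--255 scale.  Defaults give a mid-gray canvas with
#'   clearly visible contrast.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param id identifier for the canvas; defaults to one derived from the
#'   seed.
#' @return A `noise_canvas`: list with `pixels` (height x width integer
#'   matrix), `seed` and `id`.
#' @examples
#' n1 <- generate_noise(30, 34, seed = 1)
#' n2 <- generate_noise(30, 34, seed = 1)
#' identical(n1$pixels, n2$pixels)
#' @export
generate_noise <- function(width = 300, height = 350, mean = 128, sd = 30,
                           seed = NULL, id = NULL) {
  if (width <= 0 || height <= 0) {
    stop("canvas dimensions must be positive", call. = FALSE)
  }
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  px <- with_seed(seed, matrix(stats::rnorm(width * height, mean, sd),
                               nrow = height, ncol = width))
  structure(list(pixels = quantize_luminance(px),
                 seed = seed,
                 id = id %||% paste0("noise-", seed %||% "stream")),
            class = "noise_canvas")
}

#' @export
print.noise_canvas <- function(x, ...) {
  cat(sprintf("Noise canvas '%s': %d x %d (w x h), mean %.1f\n",
              x$id, ncol(x$pixels), nrow(x$pixels), mean(x$pixels)))
  invisible(x)
}

# Accept a noise_canvas, target_image, composite_stimulus or bare matrix.
pixels_of <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && is.matrix(x$pixels)) return(x$pixels)
  stop("cannot extract a pixel matrix from this object", call. = FALSE)
}

#' Composite a target onto the center of a noise canvas
#'
#' Alpha-blends a target image into the centered target region of a noise
#' canvas: inside the region each pixel becomes
#' `(1 - opacity) * noise + opacity * target` (quantized to 8 bits);
#' outside the region the noise is untouched.  With `target = NULL` or
#' `opacity = 0` the composite is pixel-identical to its source noise,
#' which is how target-absent (pure noise) stimuli are represented.
#'
#' @param noise a `noise_canvas` (or integer matrix).
#' @param target a `target_image` from [make_target_bank()], or `NULL` for
#'   a target-absent composite.
#' @param opacity blend fraction in \[0, 1\].
#' @param geometry a [stim_geometry()] whose canvas/target sizes must match
#'   the inputs.
#' @return A `composite_stimulus`: list with `pixels`, `source_noise_id`,
#'   `target_ref` (or `NULL`), `opacity`, `framed`.
#' @export
composite_target <- function(noise, target = NULL, opacity = 0,
                             geometry = NULL) {
  if (opacity < 0 || opacity > 1) {
    stop("opacity must lie in [0, 1]", call. = FALSE)
  }
  np <- pixels_of(noise)
  if (is.null(geometry)) {
    geometry <- if (is.null(target)) {
      stim_geometry(canvas_w = ncol(np), canvas_h = nrow(np),
                    target_w = 2L, target_h = 2L,
                    ellipse_w = ncol(np), ellipse_h = nrow(np))
    } else {
      tp0 <- pixels_of(target)
      stim_geometry(canvas_w = ncol(np), canvas_h = nrow(np),
                    target_w = ncol(tp0), target_h = nrow(tp0),
                    ellipse_w = ncol(np), ellipse_h = nrow(np))
    }
  }
  if (nrow(np) != geometry$canvas_h || ncol(np) != geometry$canvas_w) {
    stop("noise canvas does not match the geometry", call. = FALSE)
  }
  out <- np
  target_ref <- NULL
  if (!is.null(target) && opacity > 0) {
    tp <- pixels_of(target)
    if (nrow(tp) != geometry$target_h || ncol(tp) != geometry$target_w) {
      stop("target image does not match the geometry", call. = FALSE)
    }
    r0 <- (geometry$canvas_h - geometry$target_h) %/% 2L
    c0 <- (geometry$canvas_w - geometry$target_w) %/% 2L
    rows <- (r0 + 1L):(r0 + geometry$target_h)
    cols <- (c0 + 1L):(c0 + geometry$target_w)
    out[rows, cols] <- quantize_luminance(
      (1 - opacity) * np[rows, cols] + opacity * tp)
    target_ref <- if (is.list(target)) {
      list(category = target$category, index = target$index)
    } else {
      list(category = "custom", index = NA_integer_)
    }
  }
  structure(list(pixels = out,
                 source_noise_id = if (is.list(noise)) noise$id else NA_character_,
                 target_ref = target_ref,
                 opacity = opacity,
                 framed = FALSE),
            class = "composite_stimulus")
}

#' @export
print.composite_stimulus <- function(x, ...) {
  what <- if (is.null(x$target_ref)) "target-absent" else
    sprintf("%s #%d at opacity %.2f", x$target_ref$category,
            x$target_ref$index, x$opacity)
  cat(sprintf("Composite stimulus (%s)%s, noise '%s'\n", what,
              if (x$framed) ", framed" else "", x$source_noise_id))
  invisible(x)
}

# Squared normalized elliptical radius of every pixel center, for an
# axis-aligned ellipse with bounding box ew x eh centered on the canvas.
ellipse_r2 <- function(h, w, ew, eh) {
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  a <- ew / 2
  b <- eh / 2
  xs <- ((seq_len(w) - cx) / a)^2
  ys <- ((seq_len(h) - cy) / b)^2
  outer(ys, xs, "+")
}

#' Central fixation cross mask
#'
#' Logical canvas-sized mask of the centered cross: a horizontal and a
#' vertical bar of length `cross_size` and thickness `cross_thickness`,
#' intersecting at the canvas center.  The number of `TRUE` pixels is
#' `2 * size * thickness - thickness^2` (the arms overlap in a
#' thickness x thickness square).
#'
#' @param geometry a [stim_geometry()].
#' @return Logical matrix of canvas size.
#' @export
cross_mask <- function(geometry = stim_geometry()) {
  h <- geometry$canvas_h; w <- geometry$canvas_w
  sz <- geometry$cross_size; th <- geometry$cross_thickness
  m <- matrix(FALSE, h, w)
  # half-open pixel bands around the canvas center
  rows_bar <- (h %/% 2L - th %/% 2L + 1L):(h %/% 2L - th %/% 2L + th)
  cols_arm <- (w %/% 2L - sz %/% 2L + 1L):(w %/% 2L - sz %/% 2L + sz)
  rows_arm <- (h %/% 2L - sz %/% 2L + 1L):(h %/% 2L - sz %/% 2L + sz)
  cols_bar <- (w %/% 2L - th %/% 2L + 1L):(w %/% 2L - th %/% 2L + th)
  m[rows_bar, cols_arm] <- TRUE
  m[rows_arm, cols_bar] <- TRUE
  m
}

#' Draw the elliptical frame and central cross on a stimulus
#'
#' Renders the display form of a composite stimulus: pixels outside the
#' elliptical aperture are set to the black background (0), the ellipse
#' outline is stroked in black, and the central cross is drawn in black.
#' Framing is recorded on the object and applying it twice is an error.
#'
#' @param stim a `composite_stimulus` with `framed = FALSE`.
#' @param geometry a [stim_geometry()] matching the stimulus.
#' @return The framed `composite_stimulus`.
#' @export
apply_frame_and_cross <- function(stim, geometry = stim_geometry()) {
  stopifnot(inherits(stim, "composite_stimulus"))
  if (isTRUE(stim$framed)) {
    stop("stimulus is already framed", call. = FALSE)
  }
  px <- stim$pixels
  h <- nrow(px); w <- ncol(px)
  if (h != geometry$canvas_h || w != geometry$canvas_w) {
    stop("stimulus does not match the geometry", call. = FALSE)
  }
  r2_out <- ellipse_r2(h, w, geometry$ellipse_w, geometry$ellipse_h)
  r2_in <- ellipse_r2(h, w,
                      geometry$ellipse_w - 2L * geometry$frame_stroke,
                      geometry$ellipse_h - 2L * geometry$frame_stroke)
  px[r2_out > 1] <- 0L            # masked background outside the aperture
  px[r2_out <= 1 & r2_in > 1] <- 0L  # frame outline
  px[cross_mask(geometry)] <- 0L
  stim$pixels <- px
  stim$framed <- TRUE
  stim
}

#' Read and write 8-bit grayscale stimulus PNGs
#'
#' All persisted stimuli round-trip bit-exactly through 8-bit grayscale
#' PNG.
#'
#' @param x a pixel matrix or any object with a `pixels` field.
#' @param path file path.
#' @return `read_stimulus_png()` returns an integer matrix in \[0, 255\].
#' @export
write_stimulus_png <- function(x, path) {
  px <- pixels_of(x)
  stopifnot(all(px >= 0), all(px <= 255))
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' @rdname write_stimulus_png
#' @export
read_stimulus_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # gray written as-is; guard
  out <- round_half_up(img * 255)
  storage.mode(out) <- "integer"
  out
}
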