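# Procedural target banks: synthetic stand-ins for photographic face and
# letter stimuli.  Faces are top-heavy two-eyes-plus-mouth layouts with
# jittered geometry; letters are stroke-grid glyphs.  All drawing is in
# luminance on the 0-255 scale, dark features on a light ground.

fill_ellipse <- function(px, cx, cy, rx, ry, value) {
  h <- nrow(px); w <- ncol(px)
  rows <- max(1L, floor(cy - ry)):min(h, ceiling(cy + ry))
  cols <- max(1L, floor(cx - rx)):min(w, ceiling(cx + rx))
  if (!length(rows) || !length(cols)) return(px)
  d <- outer(((rows - cy) / ry)^2, ((cols - cx) / rx)^2, "+")
  sub <- px[rows, cols, drop = FALSE]
  sub[d <= 1] <- value
  px[rows, cols] <- sub
  px
}

draw_segment <- function(px, x0, y0, x1, y1, halfwidth, value) {
  h <- nrow(px); w <- ncol(px)
  rows <- max(1L, floor(min(y0, y1) - halfwidth)):min(h, ceiling(max(y0, y1) + halfwidth))
  cols <- max(1L, floor(min(x0, x1) - halfwidth)):min(w, ceiling(max(x0, x1) + halfwidth))
  if (!length(rows) || !length(cols)) return(px)
  X <- matrix(rep(cols, each = length(rows)), nrow = length(rows))
  Y <- matrix(rep(rows, times = length(cols)), nrow = length(rows))
  dx <- x1 - x0; dy <- y1 - y0
  L2 <- dx^2 + dy^2
  t <- if (L2 == 0) 0 else pmin(pmax(((X - x0) * dx + (Y - y0) * dy) / L2, 0), 1)
  d2 <- (X - (x0 + t * dx))^2 + (Y - (y0 + t * dy))^2
  sub <- px[rows, cols, drop = FALSE]
  sub[d2 <= halfwidth^2] <- value
  px[rows, cols] <- sub
  px
}

draw_face <- function(width, height, species = c("human", "chimpanzee")) {
  species <- match.arg(species)
  bg <- 175; fg <- 45
  px <- matrix(bg, height, width)
  jit <- function(scale) stats::runif(1, -scale, scale)
  # head outline: large mid-dark oval
  px <- fill_ellipse(px, width * (0.5 + jit(0.02)), height * (0.5 + jit(0.02)),
                     width * (0.42 + jit(0.03)), height * (0.44 + jit(0.03)), 140)
  # species-dependent proportions: chimp eyes slightly lower and closer,
  # mouth wider
  eye_y <- if (species == "human") 0.38 else 0.41
  eye_dx <- if (species == "human") 0.18 else 0.15
  mouth_w <- if (species == "human") 0.14 else 0.16
  eye_r <- if (species == "human") 0.07 else 0.085
  ex_l <- width * (0.5 - eye_dx + jit(0.03))
  ex_r <- width * (0.5 + eye_dx + jit(0.03))
  ey <- height * (eye_y + jit(0.03))
  er_x <- width * (eye_r + jit(0.015))
  er_y <- height * (0.05 + jit(0.012))
  px <- fill_ellipse(px, ex_l, ey, er_x, er_y, fg)
  px <- fill_ellipse(px, ex_r, ey, er_x, er_y, fg)
  # nose hint
  px <- fill_ellipse(px, width * (0.5 + jit(0.02)), height * (0.55 + jit(0.02)),
                     width * 0.035, height * 0.04, 100)
  # mouth below the eyes
  px <- fill_ellipse(px, width * (0.5 + jit(0.03)), height * (0.72 + jit(0.025)),
                     width * (mouth_w + jit(0.02)), height * (0.035 + jit(0.01)), fg)
  px
}

draw_letter <- function(width, height) {
  bg <- 175; fg <- 45
  px <- matrix(bg, height, width)
  # anchor grid inside a margin, strokes between random anchors
  gx <- seq(0.2, 0.8, length.out = 4) * width
  gy <- seq(0.15, 0.85, length.out = 4) * height
  n_strokes <- sample(4:7, 1)
  hw <- max(1.5, 0.025 * width)
  for (k in seq_len(n_strokes)) {
    a <- c(sample(gx, 1), sample(gy, 1))
    b <- c(sample(gx, 1), sample(gy, 1))
    if (all(a == b)) b <- b + c(width * 0.2, 0)
    px <- draw_segment(px, a[1], a[2], b[1], b[2], hw, fg)
  }
  px
}

#' Generate a bank of procedural target images
#'
#' Produces `n` distinct targets of one category, deterministically under
#' `seed`.  Face categories are drawn as top-heavy layouts (two dark eye
#' blobs above a dark mouth inside a head oval, geometry jittered per
#' item); letters are glyphs assembled from thick strokes on an anchor
#' grid.  These are synthetic stand-ins for photographic stimuli, suitable
#' for driving template-matching observers.
#'
#' @param category one of `"chimpanzee_face"`, `"human_face"`, `"letter"`.
#' @param n number of targets (the full-scale design uses 20 per
#'   category).
#' @param seed integer seed; the same seed reproduces the identical bank.
#' @param width,height target size in pixels (defaults 200 x 220).
#' @return List of `n` `target_image` objects (fields `pixels`, `category`,
#'   `index`).
#' @export
make_target_bank <- function(category, n = 20, seed = NULL,
                             width = 200, height = 220) {
  if (!category %in% c("chimpanzee_face", "human_face", "letter")) {
    stop("unknown target category: ", category, call. = FALSE)
  }
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  with_seed(seed, {
    bank <- vector("list", n)
    for (i in seq_len(n)) {
      px <- switch(category,
        chimpanzee_face = draw_face(width, height, "chimpanzee"),
        human_face = draw_face(width, height, "human"),
        letter = draw_letter(width, height))
      px <- quantize_luminance(px)
      # distinctness guard: jitter should always separate items, but make
      # the contract unconditional
      while (i > 1L &&
             any(vapply(bank[seq_len(i - 1L)],
                        function(t) identical(t$pixels, px), logical(1)))) {
        px[1L, 1L] <- (px[1L, 1L] + 1L) %% 256L
      }
      bank[[i]] <- structure(list(pixels = px, category = category,
                                  index = i),
                             class = "target_image")
    }
    bank
  })
}

#' @export
print.target_image <- function(x, ...) {
  cat(sprintf("Target image %s #%d: %d x %d (w x h)\n", x$category, x$index,
              ncol(x$pixels), nrow(x$pixels)))
  invisible(x)
}

#' Mean image of a target bank
#'
#' Pixelwise mean of the bank, used as the default internal template of a
#' template-matching observer.
#'
#' @param bank list of `target_image` as returned by [make_target_bank()].
#' @return Real-valued matrix of the bank's common size.
#' @export
bank_mean <- function(bank) {
  stopifnot(length(bank) >= 1)
  Reduce(`+`, lapply(bank, function(t) pixels_of(t))) / length(bank)
}
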