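#' Luminance enhancement
#'
#' Contrast enhancement applied to average and difference images for
#' display: `E(i,j) = (L(i,j) - M) * gain + offset`, quantized
#' (round half away from zero) and clipped to \[0, 255\].  `M` defaults to
#' the mean of the whole plane, so a constant plane maps to a uniform
#' `offset` (128), and the sign pattern of `L - M` is preserved wherever
#' no clipping occurs.  Statistics are always computed on raw planes,
#' never on enhanced ones.
#'
#' @param plane real-valued matrix (an average image, or a difference of
#'   averages).
#' @param M reference luminance subtracted before scaling; by convention
#'   the average of the entire image.
#' @param gain,offset enhancement gain and mid-gray offset.
#' @return Integer matrix in \[0, 255\].
#' @export
enhance <- function(plane, M = mean(plane), gain = 20, offset = 128) {
  stopifnot(is.matrix(plane))
  quantize_luminance((plane - M) * gain + offset)
}

#' Classification image of a choice dataset
#'
#' Computes the selected and unselected average images, their raw
#' difference (selected minus unselected, real-valued), and enhanced
#' 8-bit renderings of all three.  The difference is taken on the raw
#' averages and then enhanced, with `M` for the difference equal to the
#' mean of the difference plane over the entire image.
#'
#' @param ds a `choice_dataset`.
#' @param gain,offset enhancement parameters, see [enhance()].
#' @param aoi the [aoi_spec()] attached to the result (defaults to the
#'   dataset's).
#' @return A `classification_image`: raw planes `selected_mean`,
#'   `unselected_mean`, `difference`; enhanced planes
#'   `enhanced_selected`, `enhanced_unselected`, `enhanced_difference`;
#'   `M` (the three reference luminances), `n_trials`, `aoi`, `category`.
#' @export
classification_image <- function(ds, gain = 20, offset = 128,
                                 aoi = ds$aoi) {
  stopifnot(inherits(ds, "choice_dataset"))
  sel <- average_planes(ds, "selected")
  uns <- average_planes(ds, "unselected")
  diff <- sel - uns
  M <- c(selected = mean(sel), unselected = mean(uns),
         difference = mean(diff))
  structure(list(
    selected_mean = sel, unselected_mean = uns, difference = diff,
    enhanced_selected = enhance(sel, M[["selected"]], gain, offset),
    enhanced_unselected = enhance(uns, M[["unselected"]], gain, offset),
    enhanced_difference = enhance(diff, M[["difference"]], gain, offset),
    M = M, gain = gain, offset = offset,
    n_trials = n_trials(ds), aoi = aoi,
    category = unique(ds$trials$category)),
    class = "classification_image")
}

#' @export
print.classification_image <- function(x, ...) {
  cat(sprintf("Classification image (%s): %d trials, %d x %d planes\n",
              paste(x$category, collapse = ", "), x$n_trials,
              ncol(x$difference), nrow(x$difference)))
  cat(sprintf("  AOI mean difference: %.4f\n",
              mean(crop_aoi(x$difference, x$aoi))))
  invisible(x)
}

#' @export
plot.classification_image <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show <- function(m, main) {
    graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256, 0, 1),
                    axes = FALSE, main = main, useRaster = TRUE)
  }
  show(x$enhanced_selected, "selected")
  show(x$enhanced_unselected, "unselected")
  show(x$enhanced_difference, "difference")
  invisible(x)
}

#' Write a classification image to disk
#'
#' Enhanced planes go to 8-bit grayscale PNGs, the raw difference plane
#' to a lossless tab-separated text grid, and a one-row CSV summary
#' (trial count, AOI mean difference) alongside.
#'
#' @param ci a `classification_image`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @export
write_classification_image <- function(ci, dir, prefix = "ci") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stimulus_png(ci$enhanced_selected,
                     file.path(dir, paste0(prefix, "_selected.png")))
  write_stimulus_png(ci$enhanced_unselected,
                     file.path(dir, paste0(prefix, "_unselected.png")))
  write_stimulus_png(ci$enhanced_difference,
                     file.path(dir, paste0(prefix, "_difference.png")))
  write_plane_tsv(ci$difference,
                  file.path(dir, paste0(prefix, "_difference_raw.tsv")))
  utils::write.csv(
    data.frame(n_trials = ci$n_trials,
               aoi_mean_difference = mean(crop_aoi(ci$difference, ci$aoi))),
    file.path(dir, paste0(prefix, "_summary.csv")), row.names = FALSE)
  invisible(dir)
}

#' Lossless text serialization of a real-valued plane
#'
#' Tab-separated grid with full floating-point precision (`%.17g`), so
#' planes round-trip bit-exactly.
#'
#' @param plane numeric matrix.
#' @param path file path.
#' @export
write_plane_tsv <- function(plane, path) {
  lines <- apply(plane, 1, function(r) paste(sprintf("%.17g", r),
                                             collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_plane_tsv
#' @export
read_plane_tsv <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}
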