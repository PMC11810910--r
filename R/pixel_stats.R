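#' Benjamini-Hochberg FDR adjustment over a plane
#'
#' Step-up false-discovery-rate adjustment over all non-missing entries
#' jointly (one analysis = one family).  Adjusted p-values are monotone
#' non-decreasing in the raw p-values and never smaller than them.
#'
#' @param p numeric vector or matrix of raw p-values; `NA` entries are
#'   ignored and stay `NA`.
#' @param q FDR level in (0, 1).
#' @return List: `p_fdr` (same shape as `p`) and `sig` (logical mask,
#'   `p_fdr <= q`, `FALSE` where missing).
#' @export
fdr_adjust <- function(p, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  ok <- !is.na(p)
  if (!any(ok)) stop("all p-values are missing", call. = FALSE)
  p_fdr <- p
  p_fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  sig <- !is.na(p_fdr) & p_fdr <= q
  list(p_fdr = p_fdr, sig = sig)
}

# Exact closed-form REML + Satterthwaite inference for the balanced
# paired two-condition mixed model
#   luminance ~ condition + (1 | participant) + (1 | trial)
# vectorized over pixels.  Per trial t let d_t = selected - unselected
# and s_t = (selected + unselected)/2.  The design splits into three
# independent strata with expected mean squares
#   S1 (pair differences,      df n-1):  2 * sigma_e^2
#   S2 (s within participants, df n-g):  sigma_trial^2 + sigma_e^2 / 2
#   S3 (s between participants,df g-1):  sigma_trial^2 + sigma_e^2 / 2
#                                        + m * sigma_participant^2
# The condition estimate is mean(d) with Var = 2 sigma_e^2 / n.  When a
# variance component is truncated at zero, REML pools the corresponding
# strata into the sigma_e^2 estimate, and the Satterthwaite df of the
# t-statistic is the total df of the pooled strata.  This reproduces
# lmerTest to numerical precision on balanced data, including at the
# boundary.
fast_paired_fit <- function(d, s, part) {
  n <- nrow(d)
  if (n < 3) stop("need at least 3 trials", call. = FALSE)
  P <- ncol(d)
  part <- factor(part)
  g <- nlevels(part)
  est <- colMeans(d)
  S1 <- pmax(colSums(d * d) - n * est^2, 0)
  df1 <- n - 1
  singular <- S1 < 1e-9
  if (g > 1L) {
    mp <- as.vector(table(part))
    mean_p <- rowsum(s, part) / mp
    sbar <- colSums(s) / n
    between <- colSums(mp * mean_p^2)
    S3 <- pmax(between - n * sbar^2, 0)
    S2 <- pmax(colSums(s * s) - between, 0)
    df2 <- n - g
    df3 <- g - 1
  } else {
    sbar <- colMeans(s)
    S2 <- pmax(colSums(s * s) - n * sbar^2, 0)
    df2 <- n - 1
    S3 <- numeric(P)
    df3 <- 0L
  }
  MS1 <- S1 / df1
  MS2 <- if (df2 > 0) S2 / df2 else rep(Inf, P)
  MS3 <- if (df3 > 0) S3 / df3 else rep(Inf, P)
  Varb <- MS1 / n
  df <- rep(df1, P)
  v_boundary <- df2 > 0 & MS2 < MS1 / 4
  pool_all <- rep(FALSE, P)
  if (df3 > 0) {
    # trial variance interior, participant variance truncated: pooling
    # strata 2+3 only matters if it pushes the trial variance negative
    th23 <- (S2 + S3) / (df2 + df3)
    pool_all <- (!v_boundary & MS3 < MS2 & th23 < MS1 / 4)
  }
  if (any(v_boundary)) {
    se12 <- (S1 / 2 + 2 * S2) / (df1 + df2)
    if (df3 > 0) {
      pa_v <- v_boundary & MS3 < se12 / 2
      pool_all <- pool_all | pa_v
      keep <- v_boundary & !pa_v
    } else {
      keep <- v_boundary
    }
    Varb[keep] <- 2 * se12[keep] / n
    df[keep] <- df1 + df2
  }
  if (any(pool_all)) {
    sea <- (S1 / 2 + 2 * S2 + 2 * S3) / (df1 + df2 + df3)
    Varb[pool_all] <- 2 * sea[pool_all] / n
    df[pool_all] <- df1 + df2 + df3
  }
  tval <- est / sqrt(Varb)
  p <- 2 * stats::pt(-abs(tval), df)
  p[singular] <- NA_real_
  list(estimate = est, p = p, df = df, singular = singular)
}

# One-pixel mixed model through lmerTest, used by the generic variants.
lmer_pixel_fit <- function(sel_j, uns_j, part, variant) {
  n <- length(sel_j)
  dat <- data.frame(lum = c(sel_j, uns_j),
                    cond = rep(c(1, 0), each = n),
                    participant = rep(part, 2L),
                    trial = factor(rep(seq_len(n), 2L)))
  form <- if (variant == "group") {
    lum ~ cond + (1 | participant) + (1 | trial)
  } else {
    lum ~ cond + (1 | trial)
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = dat,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (is.null(fit)) return(c(NA_real_, NA_real_))
  cf <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(cf) || !"cond" %in% rownames(cf)) return(c(NA_real_, NA_real_))
  c(cf["cond", "Estimate"], cf["cond", "Pr(>|t|)"])
}

#' Per-pixel mixed-model map of the selected-versus-unselected contrast
#'
#' Fits, for every pixel of the area of interest, a Gaussian-response
#' linear mixed model of luminance on stimulus type (selected versus
#' unselected-mean), and assembles the fixed-effect estimates, raw
#' p-values (Satterthwaite), Benjamini-Hochberg-adjusted p-values and
#' the significance mask into a statistical map.
#'
#' Variants:
#' \describe{
#'   \item{`fast_paired`}{the default: an exact closed-form
#'     reduction of the group model for the paired balanced design,
#'     vectorized over pixels (the per-trial difference carries the
#'     condition effect; see the methods vignette for the derivation and
#'     its boundary handling).  Tractable for full-AOI runs.}
#'   \item{`group`}{per-pixel `lmerTest` fit with participant and trial
#'     random intercepts (trials are unique per participant, so the trial
#'     factor is automatically nested); used for spot verification.}
#'   \item{`individual`}{per-pixel `lmerTest` fit with a trial random
#'     intercept only, for single-participant analyses.}
#' }
#' Pixels with degenerate data (zero variance of the per-trial
#' difference) or failed fits are flagged, their p-value set missing and
#' excluded from the FDR family; the count is reported on the object.
#'
#' @param ds a `choice_dataset`.
#' @param aoi [aoi_spec()] over which to fit (default: the dataset's).
#' @param variant `"fast_paired"`, `"group"` or `"individual"`.
#' @param q FDR level.
#' @param pixels optional integer vector of AOI-local pixel indices
#'   (column-major) to restrict the fit to, e.g. a random subset for the
#'   slow generic variants; unfitted pixels stay `NA`.
#' @return An object of class `pixel_map` with matrix fields `estimate`,
#'   `p_raw`, `p_fdr`, `sig` (AOI-shaped), plus `q`, `variant`,
#'   `n_trials`, `n_singular`, `aoi`.
#' @export
fit_pixel_map <- function(ds, aoi = ds$aoi,
                          variant = c("fast_paired", "group", "individual"),
                          q = 0.05, pixels = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(ds, "choice_dataset"))
  n <- n_trials(ds)
  part <- factor(ds$trials$participant)
  if (variant == "group" && nlevels(part) < 2) {
    stop("the group variant needs at least 2 participants", call. = FALSE)
  }
  idx <- aoi_flat_index(aoi, ds$dim[["h"]], ds$dim[["w"]])
  P <- length(idx)
  use <- pixels %||% seq_len(P)
  stopifnot(all(use >= 1), all(use <= P))
  mats <- sel_unsel_matrices(ds, idx[use])
  est <- p_raw <- rep(NA_real_, P)
  singular <- rep(FALSE, P)
  if (variant == "fast_paired") {
    d <- mats$selected - mats$unselected_mean
    s <- (mats$selected + mats$unselected_mean) / 2
    ff <- fast_paired_fit(d, s, part)
    est[use] <- ff$estimate
    p_raw[use] <- ff$p
    singular[use] <- ff$singular
  } else {
    for (k in seq_along(use)) {
      r <- lmer_pixel_fit(mats$selected[, k], mats$unselected_mean[, k],
                          part, variant)
      est[use[k]] <- r[1]
      p_raw[use[k]] <- r[2]
      singular[use[k]] <- is.na(r[2])
    }
  }
  shape <- function(v) matrix(v, nrow = aoi$height, ncol = aoi$width)
  fitted <- logical(P); fitted[use] <- TRUE
  adj <- if (all(is.na(p_raw))) {
    list(p_fdr = p_raw, sig = rep(FALSE, P))  # every pixel degenerate
  } else {
    fdr_adjust(p_raw, q)
  }
  structure(list(estimate = shape(est), p_raw = shape(p_raw),
                 p_fdr = shape(adj$p_fdr), sig = shape(adj$sig),
                 q = q, variant = variant, n_trials = n,
                 n_participants = nlevels(part),
                 n_singular = sum(singular & fitted),
                 n_fitted = sum(fitted), aoi = aoi),
            class = "pixel_map")
}

#' @export
print.pixel_map <- function(x, ...) {
  cat(sprintf("Pixel map (%s): %d x %d AOI, %d trials, %d participant(s)\n",
              x$variant, x$aoi$width, x$aoi$height, x$n_trials,
              x$n_participants))
  cat(sprintf("  fitted %d pixels (%d singular/excluded); %d significant at FDR %.2g\n",
              x$n_fitted, x$n_singular, sum(x$sig), x$q))
  invisible(x)
}

#' @export
summary.pixel_map <- function(object, ...) {
  print(object)
  ok <- !is.na(object$p_raw)
  cat(sprintf("  estimate range [%.3f, %.3f]; min raw p %.3g; min adj p %.3g\n",
              min(object$estimate[ok]), max(object$estimate[ok]),
              min(object$p_raw[ok]), min(object$p_fdr[ok])))
  invisible(object)
}

#' @export
coef.pixel_map <- function(object, ...) object$estimate

#' @export
as.data.frame.pixel_map <- function(x, ...) {
  h <- x$aoi$height; w <- x$aoi$width
  data.frame(row = rep(seq_len(h), times = w),
             col = rep(seq_len(w), each = h),
             estimate = as.vector(x$estimate),
             p_raw = as.vector(x$p_raw),
             p_fdr = as.vector(x$p_fdr),
             sig = as.vector(x$sig))
}

#' Heatmap display of a pixel map
#'
#' Renders the FDR-adjusted p-values (or the estimates) of a
#' [fit_pixel_map()] result as an image: small adjusted p-values are hot,
#' non-significant pixels fade to white.
#'
#' @param x a `pixel_map`.
#' @param what `"p_fdr"`, `"p_raw"` or `"estimate"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.pixel_map <- function(x, what = c("p_fdr", "p_raw", "estimate"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  if (what == "estimate") {
    pal <- grDevices::hcl.colors(64, "Blue-Red 2")
  } else {
    m <- -log10(pmax(m, 1e-12))
    pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  }
  graphics::image(t(m)[, nrow(m):1], col = pal, axes = FALSE,
                  main = paste0(what, " (", x$variant, ")"),
                  useRaster = TRUE, ...)
  invisible(x)
}

heatmap_rgb <- function(m, lo, hi, pal) {
  t01 <- (pmin(pmax(m, lo), hi) - lo) / (hi - lo)
  t01[is.na(t01)] <- 0
  cols <- grDevices::colorRamp(pal)(as.vector(t01)) / 255
  array(cols, dim = c(nrow(m), ncol(m), 3))
}

#' @rdname plot.pixel_map
#' @param path output PNG path.
#' @export
write_heatmap_png <- function(x, path, what = c("p_fdr", "p_raw")) {
  what <- match.arg(what)
  m <- -log10(pmax(x[[what]], 1e-12))
  rgb <- heatmap_rgb(m, 0, max(4, max(m, na.rm = TRUE)),
                     c("white", "yellow", "orange", "red", "darkred"))
  png::writePNG(rgb, target = path)
  invisible(path)
}

#' CSV serialization of a pixel map
#'
#' One row per AOI pixel (`row`, `col`, `estimate`, `p_raw`, `p_fdr`,
#' `sig`), with the map's metadata in `#`-prefixed header lines.
#' Numbers are written with full floating-point precision so a map
#' round-trips identically.
#'
#' @param x a `pixel_map`.
#' @param path file path.
#' @export
write_pixel_map_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- sprintf("# %s=%s",
                  c("variant", "q", "n_trials", "n_participants",
                    "n_singular", "n_fitted",
                    "aoi_x_offset", "aoi_y_offset", "aoi_width",
                    "aoi_height"),
                  c(x$variant, sprintf("%.17g", x$q), x$n_trials,
                    x$n_participants, x$n_singular, x$n_fitted,
                    x$aoi$x_offset, x$aoi$y_offset, x$aoi$width,
                    x$aoi$height))
  writeLines(meta, con)
  df <- as.data.frame(x)
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  writeLines("row,col,estimate,p_raw,p_fdr,sig", con)
  writeLines(paste(df$row, df$col, num(df$estimate), num(df$p_raw),
                   num(df$p_fdr), df$sig, sep = ","), con)
  invisible(path)
}

#' @rdname write_pixel_map_csv
#' @export
read_pixel_map_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- strsplit(sub("^# ", "", meta_lines), "=", fixed = TRUE)
  kv <- stats::setNames(vapply(meta, `[`, "", 2), vapply(meta, `[`, "", 1))
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  h <- as.integer(kv[["aoi_height"]]); w <- as.integer(kv[["aoi_width"]])
  shape <- function(v) {
    m <- matrix(NA_real_, h, w)
    m[cbind(df$row, df$col)] <- v
    m
  }
  sig <- matrix(FALSE, h, w)
  sig[cbind(df$row, df$col)] <- df$sig
  structure(list(estimate = shape(df$estimate), p_raw = shape(df$p_raw),
                 p_fdr = shape(df$p_fdr), sig = sig,
                 q = as.numeric(kv[["q"]]), variant = kv[["variant"]],
                 n_trials = as.integer(kv[["n_trials"]]),
                 n_participants = as.integer(kv[["n_participants"]]),
                 n_singular = as.integer(kv[["n_singular"]]),
                 n_fitted = as.integer(kv[["n_fitted"]]),
                 aoi = aoi_spec(as.integer(kv[["aoi_x_offset"]]),
                                as.integer(kv[["aoi_y_offset"]]), w, h)),
            class = "pixel_map")
}
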