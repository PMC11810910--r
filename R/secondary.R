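#' Log response-time mixed model
#'
#' Models natural-log response times of the test sessions with fixed
#' effects of trial type (easy / difficult / test), stimulus category
#' (when more than one is present) and their interaction, and a
#' participant random intercept.  Correction trials are excluded (their
#' count is reported); both correct and incorrect trials are included.
#' Pairwise trial-type contrasts with 95% confidence intervals are
#' computed per category on the log scale.
#'
#' With a single participant the random intercept is dropped and an
#' ordinary linear model is used instead (with a message).
#'
#' @param log trial log from [run_experiment()].
#' @return An `rt_model`: list with the fitted model (`fit`), `contrasts`
#'   (data frame: category, contrast, estimate, lower, upper),
#'   `n_excluded_corrections`, `n_dropped` (missing RTs).
#' @export
log_rt_mixed_model <- function(log) {
  stopifnot(is.data.frame(log))
  n_corr <- sum(log$is_correction)
  d <- log[!log$is_correction, , drop = FALSE]
  n_na <- sum(is.na(d$rt_ms) | d$rt_ms <= 0)
  d <- d[!is.na(d$rt_ms) & d$rt_ms > 0, , drop = FALSE]
  d$log_rt <- log(d$rt_ms)
  d$trial_type <- factor(d$trial_type,
                         levels = c("baseline_easy", "baseline_difficult",
                                    "test"),
                         labels = c("easy", "difficult", "test"))
  d$category <- factor(d$category)
  d$participant <- factor(d$participant)
  multi_cat <- nlevels(d$category) > 1
  rhs <- if (multi_cat) "trial_type * category" else "trial_type"
  if (nlevels(d$participant) > 1) {
    fit <- lmerTest::lmer(stats::as.formula(
      paste("log_rt ~", rhs, "+ (1 | participant)")), data = d)
  } else {
    message("single participant: fitting a fixed-effects model")
    fit <- stats::lm(stats::as.formula(paste("log_rt ~", rhs)), data = d)
  }
  spec <- if (multi_cat) ~ trial_type | category else ~ trial_type
  em <- emmeans::emmeans(fit, spec)
  ci <- as.data.frame(stats::confint(emmeans::contrast(em, "pairwise"), level = 0.95))
  contrasts <- data.frame(
    category = if (multi_cat) as.character(ci$category) else
      as.character(unique(d$category)),
    contrast = as.character(ci$contrast),
    estimate = ci$estimate,
    lower = ci[[grep("lower", names(ci), value = TRUE)[1]]],
    upper = ci[[grep("upper", names(ci), value = TRUE)[1]]],
    stringsAsFactors = FALSE)
  structure(list(fit = fit, contrasts = contrasts,
                 n_excluded_corrections = n_corr, n_dropped = n_na),
            class = "rt_model")
}

#' @export
print.rt_model <- function(x, ...) {
  cat("Log response-time mixed model\n")
  cat(sprintf("  %d correction trials excluded, %d rows dropped (missing RT)\n",
              x$n_excluded_corrections, x$n_dropped))
  print(x$contrasts, digits = 3)
  invisible(x)
}

#' Position-bias chi-square
#'
#' Goodness-of-fit statistic of the chosen grid cells on test trials
#' against the uniform expectation over the 6 cells,
#' `sum((O - E)^2 / E)` with `E = n / 6`, computed per participant and
#' category.
#'
#' @param log trial log.
#' @return Data frame: participant, category, n (test trials),
#'   chi_square.
#' @export
position_bias_chisq <- function(log) {
  d <- log[log$trial_type == "test" & !log$is_correction, , drop = FALSE]
  if (nrow(d) == 0) stop("no test trials in the log", call. = FALSE)
  groups <- split(d, list(d$participant, d$category), drop = TRUE)
  out <- lapply(groups, function(gd) {
    obs <- tabulate(gd$chosen_cell + 1L, nbins = 6L)
    e <- nrow(gd) / 6
    data.frame(participant = gd$participant[1], category = gd$category[1],
               n = nrow(gd), chi_square = sum((obs - e)^2 / e),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spearman rank correlation
#'
#' Midrank-tied Spearman correlation with a two-sided (default) or
#' one-tailed p-value, as used to relate position bias to heatmap
#' clarity across participant-by-category conditions.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return List: `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y, alternative = "two.sided") {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for constant input", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = alternative,
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Median split of a choice dataset by response time
#'
#' Splits test trials into a faster and a slower half per participant
#' (and category): trials with response time less than or equal to that
#' participant's median go to the faster half, strictly longer ones to
#' the slower half.  With heavily tied response times one half can be
#' empty, which is flagged with a warning.
#'
#' @param ds a `choice_dataset`.
#' @return List of two `choice_dataset`s, `faster` and `slower`, whose
#'   trials partition the input.
#' @export
rt_median_split <- function(ds) {
  stopifnot(inherits(ds, "choice_dataset"))
  key <- interaction(ds$trials$participant, ds$trials$category, drop = TRUE)
  med <- stats::ave(ds$trials$rt_ms, key, FUN = stats::median)
  faster <- ds$trials$rt_ms <= med
  if (all(faster) || !any(faster)) {
    warning("degenerate median split: one half is empty")
  }
  list(faster = ds[which(faster)], slower = ds[which(!faster)])
}

#' Brightness-difference contrasts between categories
#'
#' Compares the average brightness difference (selected minus unselected)
#' between stimulus categories, treating each AOI coordinate's difference
#' value as one observation.  Reports the per-category mean and standard
#' error and all pairwise contrasts with 95% confidence intervals, either
#' from an ordinary linear model (`variant = "plain"`) or with row and
#' column random intercepts absorbing spatial structure
#' (`variant = "rowcol"`).
#'
#' @param planes named list of difference planes (matrices), one per
#'   category; all the same shape.
#' @param aoi optional [aoi_spec()] to crop each plane to first.
#' @param variant `"plain"` or `"rowcol"`.
#' @return List: `summary` (category, mean, se, n), `contrasts`
#'   (contrast, estimate, lower, upper), `variant`.
#' @export
brightness_difference_model <- function(planes, aoi = NULL,
                                        variant = c("plain", "rowcol")) {
  variant <- match.arg(variant)
  stopifnot(is.list(planes), length(planes) >= 2,
            !is.null(names(planes)))
  if (!is.null(aoi)) planes <- lapply(planes, crop_aoi, aoi = aoi)
  shp <- dim(planes[[1]])
  if (!all(vapply(planes, function(p) identical(dim(p), shp), logical(1)))) {
    stop("difference planes have mismatched shapes", call. = FALSE)
  }
  d <- do.call(rbind, lapply(names(planes), function(cat) {
    data.frame(value = as.vector(planes[[cat]]), category = cat,
               row = factor(rep(seq_len(shp[1]), times = shp[2])),
               col = factor(rep(seq_len(shp[2]), each = shp[1])),
               stringsAsFactors = FALSE)
  }))
  d$category <- factor(d$category, levels = names(planes))
  summ <- do.call(rbind, lapply(split(d$value, d$category), function(v) {
    data.frame(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
               n = length(v))
  }))
  summ <- cbind(category = rownames(summ), summ)
  rownames(summ) <- NULL
  fit <- if (variant == "plain") {
    stats::lm(value ~ category, data = d)
  } else {
    # spatially flat inputs push the row/col variances to the boundary;
    # that is expected, not a defect
    suppressMessages(lmerTest::lmer(
      value ~ category + (1 | row) + (1 | col), data = d,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
  }
  em <- emmeans::emmeans(fit, ~category)
  ci <- as.data.frame(stats::confint(emmeans::contrast(em, "pairwise"), level = 0.95))
  contrasts <- data.frame(contrast = as.character(ci$contrast),
                          estimate = ci$estimate,
                          lower = ci[[grep("lower", names(ci),
                                           value = TRUE)[1]]],
                          upper = ci[[grep("upper", names(ci),
                                           value = TRUE)[1]]],
                          stringsAsFactors = FALSE)
  list(summary = summ, contrasts = contrasts, variant = variant)
}

#' Radially averaged Fourier amplitude spectrum
#'
#' Removes the mean, takes the 2D discrete Fourier transform, and
#' averages the amplitude over integer-radius frequency bins
#' (`r = round(sqrt(u^2 + v^2))` in cycles per image), yielding a 1D
#' profile of length `floor(min(height, width) / 2)`.
#'
#' @param plane numeric matrix.
#' @return Numeric vector, the mean amplitude per radial bin 1..R.
#' @export
radial_amplitude_spectrum <- function(plane) {
  if (!is.matrix(plane)) stop("input must be a 2D matrix", call. = FALSE)
  h <- nrow(plane); w <- ncol(plane)
  A <- Mod(stats::fft(plane - mean(plane)))
  fr <- seq_len(h) - 1L; fr <- ifelse(fr > h / 2, fr - h, fr)
  fc <- seq_len(w) - 1L; fc <- ifelse(fc > w / 2, fc - w, fc)
  r <- round(sqrt(outer(fr^2, fc^2, "+")))
  R <- floor(min(h, w) / 2)
  keep <- r >= 1 & r <= R
  as.vector(tapply(A[keep], factor(r[keep], levels = seq_len(R)), mean))
}

#' Correlation between radial amplitude spectra
#'
#' Pearson correlation of the log radial amplitude profiles of two
#' images (or of two precomputed profiles), a scalar similarity of their
#' spatial-frequency content.
#'
#' @param a,b matrices (profiles are computed) or numeric vectors
#'   (treated as profiles).
#' @return Correlation coefficient.
#' @export
spectrum_correlation <- function(a, b) {
  pa <- if (is.matrix(a)) radial_amplitude_spectrum(a) else a
  pb <- if (is.matrix(b)) radial_amplitude_spectrum(b) else b
  if (length(pa) != length(pb)) {
    stop("profiles have different lengths", call. = FALSE)
  }
  eps <- .Machine$double.xmin
  stats::cor(log(pmax(pa, eps)), log(pmax(pb, eps)))
}

#' Euclidean distance between images
#'
#' `sqrt(sum((a - b)^2))` over all pixels (crop to an AOI first if
#' needed).
#'
#' @param a,b equal-shaped numeric matrices.
#' @return Non-negative scalar.
#' @export
euclidean_image_distance <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("images have mismatched shapes", call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}
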