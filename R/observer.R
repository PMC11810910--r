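#' Template-matching synthetic observer
#'
#' Parameterizes the choice and response-time policy of a simulated
#' observer in the oddity task.  On each trial the observer computes the
#' Pearson correlation between its internal template and the
#' area-of-interest pixels of each of the three stimuli; choices follow a
#' softmax over `beta * similarity + position_bias`, mixed with a uniform
#' lapse; response times decrease linearly in the strongest similarity.
#'
#' The defaults describe a reliable, near-deterministic template matcher:
#' `beta = 50` makes baseline choices essentially evidence-driven, and
#' `lapse = 0.06` reproduces a baseline error rate of about 4% (a lapse
#' picks one of the two distractors two times in three).  Response-time
#' defaults (base 1300 ms, slope 1200 ms per unit similarity, residual SD
#' 150 ms) put easy-trial responses well under test-trial responses, with
#' log-RT contrasts of roughly 0.4-0.6.
#'
#' @param template numeric matrix, the internal template; sized like the
#'   AOI.  Must have non-zero variance.  Typically [bank_mean()] of a
#'   target bank.
#' @param beta softmax inverse temperature (>= 0) applied to template
#'   similarity.
#' @param position_bias additive utility per grid cell, length 6
#'   (cells 0-5, row-major on the 3 x 2 grid).
#' @param lapse probability of a uniform random choice, in \[0, 1\].
#' @param rt_base,rt_slope,rt_sd response-time model, milliseconds:
#'   `rt = rt_base - rt_slope * max(similarity) + N(0, rt_sd)`, floored at
#'   1 ms.
#' @return An object of class `observer`.
#' @export
observer <- function(template, beta = 50, position_bias = rep(0, 6),
                     lapse = 0.06, rt_base = 1300, rt_slope = 1200,
                     rt_sd = 150) {
  stopifnot(is.matrix(template), is.numeric(template))
  if (stats::sd(template) == 0) {
    stop("template has zero variance", call. = FALSE)
  }
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  if (lapse < 0 || lapse > 1) stop("lapse must lie in [0, 1]", call. = FALSE)
  if (length(position_bias) != 6) {
    stop("position_bias must have one utility per grid cell (6)",
         call. = FALSE)
  }
  if (rt_sd < 0) stop("rt_sd must be non-negative", call. = FALSE)
  structure(list(template = template, beta = beta,
                 position_bias = as.numeric(position_bias), lapse = lapse,
                 rt_base = rt_base, rt_slope = rt_slope, rt_sd = rt_sd),
            class = "observer")
}

#' @export
print.observer <- function(x, ...) {
  cat("Template-matching observer\n")
  cat(sprintf("  template     : %d x %d (w x h)\n",
              ncol(x$template), nrow(x$template)))
  cat(sprintf("  beta = %.3g, lapse = %.3g\n", x$beta, x$lapse))
  if (any(x$position_bias != 0)) {
    cat("  position bias:", paste(sprintf("%.2f", x$position_bias),
                                  collapse = " "), "\n")
  }
  cat(sprintf("  rt ~ %.0f - %.0f * max(s) + N(0, %.0f) ms\n",
              x$rt_base, x$rt_slope, x$rt_sd))
  invisible(x)
}
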