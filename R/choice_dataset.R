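#' Assemble the reverse-correlation dataset from a trial log
#'
#' Collects, for every non-correction test trial, the three noise-pattern
#' pixel planes together with which one the observer chose.  From these
#' the selected plane and the pixelwise mean of the two unselected planes
#' are derived on demand, which is the unit of analysis for
#' classification images and per-pixel statistics.
#'
#' @param log trial log from [run_experiment()] (or read back with
#'   [read_trial_log()]).
#' @param store environment (or list) mapping stimulus ids to integer
#'   pixel matrices, as produced by [run_experiment()].
#' @param aoi the default [aoi_spec()] carried by the dataset (normally
#'   `default_aoi(geometry)` of the generating geometry); `NULL` falls
#'   back to the full plane.
#' @return A `choice_dataset`: fields `trials` (data frame: participant,
#'   session, trial, category, rt_ms, rewarded), `planes` (n x 3 x npix
#'   integer array, planes flattened column-major), `chosen` (slot index
#'   per trial), `dim` (height, width), `aoi`.
#' @export
build_choice_dataset <- function(log, store, aoi = NULL) {
  stopifnot(is.data.frame(log))
  tl <- log[log$trial_type == "test" & !log$is_correction, , drop = FALSE]
  if (nrow(tl) == 0) stop("log contains no test trials", call. = FALSE)
  get_plane <- function(id) {
    p <- if (is.environment(store)) {
      if (exists(id, envir = store, inherits = FALSE)) {
        get(id, envir = store, inherits = FALSE)
      } else NULL
    } else store[[id]]
    if (is.null(p)) {
      stop("stimulus image missing from the store: ", id, call. = FALSE)
    }
    p
  }
  first <- get_plane(tl$stim_id_1[1])
  h <- nrow(first); w <- ncol(first)
  n <- nrow(tl)
  planes <- array(NA_integer_, dim = c(n, 3L, h * w))
  chosen <- integer(n)
  for (i in seq_len(n)) {
    ids <- c(tl$stim_id_1[i], tl$stim_id_2[i], tl$stim_id_3[i])
    for (j in 1:3) {
      p <- get_plane(ids[j])
      if (nrow(p) != h || ncol(p) != w) {
        stop("stimulus planes have inconsistent sizes", call. = FALSE)
      }
      planes[i, j, ] <- as.vector(p)
    }
    chosen[i] <- tl$chosen_slot[i]
  }
  if (is.null(aoi)) aoi <- aoi_spec(0, 0, w, h)
  structure(list(
    trials = data.frame(participant = tl$participant, session = tl$session,
                        trial = tl$trial, category = tl$category,
                        rt_ms = tl$rt_ms, rewarded = tl$rewarded,
                        stringsAsFactors = FALSE),
    planes = planes, chosen = chosen, dim = c(h = h, w = w), aoi = aoi),
    class = "choice_dataset")
}

#' @export
print.choice_dataset <- function(x, ...) {
  cat(sprintf("Choice dataset: %d test trials, %d participant(s), %d x %d planes\n",
              nrow(x$trials), length(unique(x$trials$participant)),
              x$dim[["w"]], x$dim[["h"]]))
  print(x$aoi)
  invisible(x)
}

#' @export
summary.choice_dataset <- function(object, ...) {
  cat(sprintf("Choice dataset (%s)\n",
              paste(unique(object$trials$category), collapse = ", ")))
  print(table(object$trials$participant))
  cat(sprintf("median RT %.0f ms; reward rate %.3f\n",
              stats::median(object$trials$rt_ms),
              mean(object$trials$rewarded)))
  invisible(object)
}

#' @export
`[.choice_dataset` <- function(x, i) {
  structure(list(trials = x$trials[i, , drop = FALSE],
                 planes = x$planes[i, , , drop = FALSE],
                 chosen = x$chosen[i], dim = x$dim, aoi = x$aoi),
            class = "choice_dataset")
}

#' Number of trials in a choice dataset
#' @param x a `choice_dataset`.
#' @export
n_trials <- function(x) nrow(x$trials)

#' Selected and unselected-mean pixel planes
#'
#' `selected_matrix()` returns the chosen stimulus' pixels per trial;
#' `unselected_mean_matrix()` the pixelwise arithmetic mean of the two
#' non-chosen stimuli.  Rows are trials, columns are pixels (column-major
#' flattening of the height x width plane), so `colMeans()` of these are
#' the average images.
#'
#' @param ds a `choice_dataset`.
#' @param flat_index optional integer vector of flat pixel indices (e.g.
#'   from an AOI) to restrict the columns.
#' @return Numeric matrix, trials x pixels.
#' @export
selected_matrix <- function(ds, flat_index = NULL) {
  sel_unsel_matrices(ds, flat_index)$selected
}

#' @rdname selected_matrix
#' @export
unselected_mean_matrix <- function(ds, flat_index = NULL) {
  sel_unsel_matrices(ds, flat_index)$unselected_mean
}

sel_unsel_matrices <- function(ds, flat_index = NULL) {
  n <- n_trials(ds)
  idx <- flat_index %||% seq_len(dim(ds$planes)[3])
  sel <- matrix(NA_real_, n, length(idx))
  tot <- matrix(0, n, length(idx))
  for (j in 1:3) {
    pj <- ds$planes[, j, idx, drop = FALSE]
    dim(pj) <- c(n, length(idx))
    tot <- tot + pj
    rows <- ds$chosen == j
    if (any(rows)) sel[rows, ] <- pj[rows, , drop = FALSE]
  }
  list(selected = sel, unselected_mean = (tot - sel) / 2)
}

#' Average plane over trials
#'
#' Elementwise arithmetic mean over trials of the selected (or
#' unselected-mean) planes, unrounded.
#'
#' @param ds a `choice_dataset`; must be non-empty.
#' @param which `"selected"` or `"unselected"`.
#' @return Real-valued height x width matrix.
#' @export
average_planes <- function(ds, which = c("selected", "unselected")) {
  which <- match.arg(which)
  if (n_trials(ds) == 0) stop("empty dataset", call. = FALSE)
  m <- if (which == "selected") selected_matrix(ds) else
    unselected_mean_matrix(ds)
  matrix(colMeans(m), nrow = ds$dim[["h"]], ncol = ds$dim[["w"]])
}

#' Random-selection null dataset
#'
#' Re-draws the "selected" stimulus of every trial uniformly at random
#' among the three presented noise patterns (computer-chosen selection),
#' leaving everything else in place.  Analyzing the result calibrates the
#' null distribution of the classification-image statistics.
#'
#' @param ds a `choice_dataset` retaining all three planes per trial.
#' @param seed integer seed; fixed seed reproduces identical selections.
#' @return A `choice_dataset` with resampled `chosen`.
#' @export
random_selection_null <- function(ds, seed = NULL) {
  stopifnot(inherits(ds, "choice_dataset"))
  ds$chosen <- with_seed(seed, sample.int(3L, n_trials(ds), replace = TRUE))
  ds
}
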