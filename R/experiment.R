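#' Plan an oddity experiment
#'
#' Builds the trial plan for one participant: `n_sessions` sessions whose
#' composition follows the test-session design (by default 48 trials per
#' session: 12 easy baseline + 24 difficult baseline + 12 test trials,
#' presented in random order).  Baseline trials carry one target-bearing
#' stimulus at a random slot; test trials are three target-absent noise
#' patterns.  Every noise pattern id is unique across the whole
#' experiment.  Stimulus positions are a random 3 of the 6 cells of the
#' 3 x 2 grid (cells indexed 0-5, row-major).
#'
#' @param category stimulus category, one of `"chimpanzee_face"`,
#'   `"human_face"`, `"letter"`.
#' @param n_sessions number of sessions (25 in the full design, giving 300
#'   test trials).
#' @param seed integer seed; the same seed reproduces the identical plan.
#' @param composition named counts per session:
#'   `c(easy = , difficult = , test = )`.
#' @param opacity named blend fractions `c(easy = , difficult = )` for the
#'   two baseline difficulties.
#' @param n_targets size of the target bank to draw target indices from.
#' @param id_prefix prefix for stimulus ids, used to keep ids unique
#'   across participants in a cohort.
#' @return Data frame of planned trials (one row each), columns: `session`,
#'   `trial`, `trial_type`, `category`, `stim_id_1..3`, `cell_1..3`,
#'   `correct_slot`, `correct_cell`, `target_index`, `opacity`.
#' @export
build_experiment <- function(category, n_sessions = 25, seed = NULL,
                             composition = c(easy = 12, difficult = 24,
                                             test = 12),
                             opacity = c(easy = 0.5, difficult = 0.2),
                             n_targets = 20, id_prefix = "P1") {
  if (n_sessions < 1) stop("n_sessions must be at least 1", call. = FALSE)
  stopifnot(all(c("easy", "difficult", "test") %in% names(composition)),
            all(composition >= 0))
  with_seed(seed, {
    per_session <- sum(composition)
    n <- n_sessions * per_session
    counter <- 0L
    next_id <- function(k) {
      ids <- sprintf("%s-n%07d", id_prefix, counter + seq_len(k))
      counter <<- counter + k
      ids
    }
    rows <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      types <- sample(rep(c("baseline_easy", "baseline_difficult", "test"),
                          times = composition[c("easy", "difficult", "test")]))
      cells <- t(vapply(seq_len(per_session),
                        function(i) sample(0:5, 3), integer(3)))
      is_test <- types == "test"
      slot <- ifelse(is_test, NA_integer_, sample(1:3, per_session,
                                                  replace = TRUE))
      tgt <- ifelse(is_test, NA_integer_, sample(seq_len(n_targets),
                                                 per_session, replace = TRUE))
      op <- ifelse(is_test, 0,
                   ifelse(types == "baseline_easy", opacity[["easy"]],
                          opacity[["difficult"]]))
      ids <- matrix(next_id(3L * per_session), ncol = 3, byrow = TRUE)
      rows[[s]] <- data.frame(
        session = s, trial = seq_len(per_session), trial_type = types,
        category = category,
        stim_id_1 = ids[, 1], stim_id_2 = ids[, 2], stim_id_3 = ids[, 3],
        cell_1 = cells[, 1], cell_2 = cells[, 2], cell_3 = cells[, 3],
        correct_slot = slot,
        correct_cell = ifelse(is_test, NA_integer_,
                              cells[cbind(seq_len(per_session),
                                          ifelse(is_test, 1L, slot))]),
        target_index = tgt, opacity = op,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

# Template similarity of one stimulus: Pearson correlation between the
# observer template and the stimulus AOI pixels (0 if the patch is flat).
template_similarity <- function(template_v, pixels, aoi) {
  v <- as.vector(crop_aoi(pixels, aoi))
  if (stats::sd(v) == 0) return(0)
  stats::cor(template_v, v)
}

#' Simulate one oddity choice
#'
#' Applies the observer policy to one planned trial: softmax over
#' `beta * similarity + position_bias` with a uniform lapse, an
#' evidence-dependent Gaussian response time floored at 1 ms, and the
#' reward rule (baseline: reward iff correct; test: Bernoulli(0.5)
#' regardless of choice).  Uses the current RNG stream.
#'
#' @param stimuli list of 3 stimuli (objects with `pixels`, or matrices),
#'   aligned with the plan row's slots.
#' @param plan one row of a [build_experiment()] plan.
#' @param obs an [observer()].
#' @param aoi the [aoi_spec()] over which similarity is computed; the
#'   observer template must have this size.
#' @return List: `chosen_slot`, `rt_ms`, `correct` (NA on test trials),
#'   `rewarded`, `similarity` (length 3).
#' @export
simulate_choice <- function(stimuli, plan, obs, aoi) {
  stopifnot(length(stimuli) == 3L, inherits(obs, "observer"))
  template_v <- as.vector(obs$template)
  if (nrow(obs$template) != aoi$height || ncol(obs$template) != aoi$width) {
    stop("observer template does not match the AOI size", call. = FALSE)
  }
  s <- vapply(stimuli,
              function(st) template_similarity(template_v, pixels_of(st), aoi),
              numeric(1))
  cells <- c(plan$cell_1, plan$cell_2, plan$cell_3)
  u <- obs$beta * s + obs$position_bias[cells + 1L]
  p <- exp(u - max(u))
  p <- p / sum(p)
  p <- (1 - obs$lapse) * p + obs$lapse / 3
  chosen <- sample.int(3L, 1L, prob = p)
  rt <- obs$rt_base - obs$rt_slope * max(s) + stats::rnorm(1, 0, obs$rt_sd)
  rt <- max(1, round_half_up(rt))
  is_test <- plan$trial_type == "test"
  correct <- if (is_test) NA else chosen == plan$correct_slot
  rewarded <- if (is_test) stats::runif(1) < 0.5 else isTRUE(correct)
  list(chosen_slot = chosen, rt_ms = rt, correct = correct,
       rewarded = rewarded, similarity = s)
}

#' Run a planned experiment with a synthetic observer
#'
#' Generates the stimuli for every planned trial (fresh Gaussian noise
#' canvases; baseline trials composite a bank target at the planned
#' opacity), simulates the observer's choices, applies the correction
#' procedure (after an incorrect baseline trial, one flagged correction
#' trial re-presents the target alone and is always resolved), and
#' returns the trial log together with a store of the test-trial noise
#' patterns for downstream reverse correlation.
#'
#' @param plans plan data frame from [build_experiment()].
#' @param obs an [observer()]; its template must match the geometry's
#'   AOI size.
#' @param geometry a [stim_geometry()].
#' @param noise_mean,noise_sd Gaussian noise parameters on the 0-255
#'   luminance scale.
#' @param seed integer seed for the whole run (stimuli, choices, rewards);
#'   `NULL` uses the current stream.
#' @param target_bank optional target bank; generated from the plan's
#'   category when `NULL`.
#' @param participant participant label recorded in the log.
#' @param store environment keyed by stimulus id that receives the
#'   test-trial noise pixel matrices; `NULL` disables storage.
#' @return List with `log` (data frame, one row per executed trial
#'   including corrections) and `store`.
#' @export
run_experiment <- function(plans, obs, geometry = stim_geometry(),
                           noise_mean = 128, noise_sd = 30, seed = NULL,
                           target_bank = NULL, participant = "P1",
                           store = new.env(parent = emptyenv())) {
  stopifnot(is.data.frame(plans), nrow(plans) > 0)
  aoi <- default_aoi(geometry)
  with_seed(seed, {
    if (is.null(target_bank)) {
      target_bank <- make_target_bank(plans$category[1],
                                      n = max(plans$target_index, 1,
                                              na.rm = TRUE),
                                      width = geometry$target_w,
                                      height = geometry$target_h)
    }
    n <- nrow(plans)
    cap <- 2L * n  # room for one correction per baseline error
    template_v <- as.vector(obs$template)
    col_na <- rep(NA_integer_, cap)
    out <- list(
      participant = rep(participant, cap), session = col_na,
      trial = col_na, trial_type = rep(NA_character_, cap),
      category = rep(plans$category[1], cap),
      stim_id_1 = rep(NA_character_, cap), stim_id_2 = rep(NA_character_, cap),
      stim_id_3 = rep(NA_character_, cap),
      cell_1 = col_na, cell_2 = col_na, cell_3 = col_na,
      chosen_slot = col_na, chosen_cell = col_na,
      chosen_stim = rep(NA_character_, cap), rt_ms = rep(NA_real_, cap),
      rewarded = rep(NA, cap), correct = rep(NA, cap),
      is_correction = rep(FALSE, cap))
    k <- 0L
    npx <- geometry$canvas_w * geometry$canvas_h
    for (i in seq_len(n)) {
      pl <- plans[i, ]
      noise <- lapply(1:3, function(j) {
        quantize_luminance(matrix(stats::rnorm(npx, noise_mean, noise_sd),
                                  nrow = geometry$canvas_h))
      })
      stim <- noise
      is_test <- pl$trial_type == "test"
      if (!is_test) {
        tgt <- target_bank[[pl$target_index]]
        blend <- composite_target(noise[[pl$correct_slot]], tgt,
                                  opacity = pl$opacity, geometry = geometry)
        stim[[pl$correct_slot]] <- blend$pixels
      }
      ch <- simulate_choice(stim, pl, obs, aoi)
      k <- k + 1L
      ids <- c(pl$stim_id_1, pl$stim_id_2, pl$stim_id_3)
      cells <- c(pl$cell_1, pl$cell_2, pl$cell_3)
      out$session[k] <- pl$session; out$trial[k] <- pl$trial
      out$trial_type[k] <- pl$trial_type
      out$stim_id_1[k] <- ids[1]; out$stim_id_2[k] <- ids[2]
      out$stim_id_3[k] <- ids[3]
      out$cell_1[k] <- cells[1]; out$cell_2[k] <- cells[2]
      out$cell_3[k] <- cells[3]
      out$chosen_slot[k] <- ch$chosen_slot
      out$chosen_cell[k] <- cells[ch$chosen_slot]
      out$chosen_stim[k] <- ids[ch$chosen_slot]
      out$rt_ms[k] <- ch$rt_ms
      out$rewarded[k] <- ch$rewarded
      out$correct[k] <- ch$correct
      if (is_test && !is.null(store)) {
        for (j in 1:3) assign(ids[j], noise[[j]], envir = store)
      }
      if (!is_test && !isTRUE(ch$correct)) {
        # correction: the previous target alone, always resolved
        s_t <- template_similarity(template_v,
                                   stim[[pl$correct_slot]], aoi)
        rt_c <- max(1, round_half_up(obs$rt_base - obs$rt_slope * s_t +
                                       stats::rnorm(1, 0, obs$rt_sd)))
        k <- k + 1L
        out$session[k] <- pl$session; out$trial[k] <- pl$trial
        out$trial_type[k] <- "correction"
        out$stim_id_1[k] <- ids[pl$correct_slot]
        out$cell_1[k] <- pl$correct_cell
        out$chosen_slot[k] <- 1L
        out$chosen_cell[k] <- pl$correct_cell
        out$chosen_stim[k] <- ids[pl$correct_slot]
        out$rt_ms[k] <- rt_c
        out$rewarded[k] <- TRUE
        out$correct[k] <- TRUE
        out$is_correction[k] <- TRUE
      }
    }
    log <- as.data.frame(lapply(out, function(col) col[seq_len(k)]),
                         stringsAsFactors = FALSE)
    list(log = log, store = store)
  })
}

#' Simulate a cohort of participants
#'
#' Runs one planned experiment per participant with derived seeds,
#' sharing a single stimulus store; stimulus ids are prefixed per
#' participant so that every noise pattern is unique across the cohort.
#'
#' @param n_participants number of participants (labelled `P1`, `P2`,
#'   ...).
#' @param category stimulus category.
#' @param n_sessions sessions per participant.
#' @param obs an [observer()], or a list of one observer per participant.
#' @param seed master seed; per-participant plan and run seeds are
#'   derived from it.
#' @inheritParams run_experiment
#' @inheritParams build_experiment
#' @return List with combined `log`, shared `store`, and `plans` (list per
#'   participant).
#' @export
simulate_cohort <- function(n_participants, category, n_sessions, obs,
                            geometry = stim_geometry(), seed = 1,
                            composition = c(easy = 12, difficult = 24,
                                            test = 12),
                            opacity = c(easy = 0.5, difficult = 0.2),
                            noise_mean = 128, noise_sd = 30) {
  store <- new.env(parent = emptyenv())
  logs <- vector("list", n_participants)
  plans <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    label <- sprintf("P%d", p)
    o <- if (inherits(obs, "observer")) obs else obs[[p]]
    plans[[p]] <- build_experiment(category, n_sessions,
                                   seed = derive_seed(seed, paste0("plan-", label)),
                                   composition = composition,
                                   opacity = opacity, id_prefix = label)
    res <- run_experiment(plans[[p]], o, geometry = geometry,
                          noise_mean = noise_mean, noise_sd = noise_sd,
                          seed = derive_seed(seed, paste0("run-", label)),
                          participant = label, store = store)
    logs[[p]] <- res$log
  }
  list(log = do.call(rbind, logs), store = store, plans = plans)
}

#' Read and write trial logs
#'
#' Plain-CSV serialization of the trial log produced by
#' [run_experiment()].
#'
#' @param log trial log data frame.
#' @param path file path.
#' @export
write_trial_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
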