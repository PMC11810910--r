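# Shared fixtures, built once per test run and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# Tiny-scale template observer experiment, 1200 test trials (nested
# supersets give matched-seed trial-count comparisons).
tiny_fx <- function() cached("tiny1200", make_fixtures("tiny", seed = 5,
                                                       n_trials = 1200))

# Small-scale cohort of 5 participants, 100 test trials total.
small_fx <- function() cached("small5", make_fixtures("small", seed = 11,
                                                      n_participants = 5,
                                                      n_trials = 100))

# The tiny-scale geometry without simulating anything.
tiny_geom <- function() {
  stim_geometry(canvas_w = 30, canvas_h = 34, target_w = 20, target_h = 22,
                ellipse_w = 24, ellipse_h = 28, frame_stroke = 1,
                cross_size = 2, cross_thickness = 1)
}

# Correlation between a pixel map's estimate plane and a template.
template_r <- function(map, template) {
  stats::cor(as.vector(coef(map)), as.vector(template))
}

# Brute-force Benjamini-Hochberg step-up, the independent oracle for
# fdr_adjust(): adj_i = min_{j >= i} m * p_(j) / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Minimal hand-built trial log with the columns the analyses consume.
mini_log <- function(trial_type, chosen_cell = 0L, rt_ms = 1000,
                     participant = "P1", category = "human_face",
                     is_correction = FALSE) {
  n <- max(lengths(list(trial_type, chosen_cell, rt_ms, participant,
                        category, is_correction)))
  data.frame(participant = rep_len(participant, n),
             session = 1L, trial = seq_len(n),
             trial_type = rep_len(trial_type, n),
             category = rep_len(category, n),
             stim_id_1 = sprintf("a%d", seq_len(n)),
             stim_id_2 = sprintf("b%d", seq_len(n)),
             stim_id_3 = sprintf("c%d", seq_len(n)),
             cell_1 = 0L, cell_2 = 1L, cell_3 = 2L,
             chosen_slot = 1L,
             chosen_cell = rep_len(chosen_cell, n),
             chosen_stim = sprintf("a%d", seq_len(n)),
             rt_ms = rep_len(rt_ms, n),
             rewarded = TRUE, correct = NA,
             is_correction = rep_len(is_correction, n),
             stringsAsFactors = FALSE)
}

# Hand-built choice dataset from explicit per-trial plane triples.
mini_dataset <- function(triples, chosen, participant = "P1",
                         rt_ms = NULL, aoi = NULL) {
  n <- length(triples)
  h <- nrow(triples[[1]][[1]]); w <- ncol(triples[[1]][[1]])
  store <- new.env(parent = emptyenv())
  log <- mini_log(rep("test", n), participant = participant,
                  rt_ms = rt_ms %||% rep(1000, n))
  log$chosen_slot <- chosen
  log$chosen_stim <- c("a", "b", "c")[chosen]
  for (i in seq_len(n)) {
    for (j in 1:3) {
      m <- triples[[i]][[j]]
      storage.mode(m) <- "integer"
      assign(sprintf("%s%d", c("a", "b", "c")[j], i), m, envir = store)
    }
  }
  build_choice_dataset(log, store, aoi = aoi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
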