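test_that("the choice dataset records selected and unselected-mean planes", {
  # two unselected planes valued 100 and 150 average to 125 everywhere
  m <- function(v) matrix(as.integer(v), 4, 5)
  ds <- mini_dataset(list(list(m(80), m(100), m(150)),
                          list(m(60), m(200), m(90))),
                     chosen = c(1L, 2L))
  expect_equal(selected_matrix(ds), matrix(c(80, 200), 2, 20))
  expect_equal(unselected_mean_matrix(ds), matrix(c(125, 75), 2, 20))

  # subsetting keeps a dataset a dataset
  sub <- ds[1]
  expect_s3_class(sub, "choice_dataset")
  expect_equal(n_trials(sub), 1)
  expect_equal(average_planes(sub, "selected"), matrix(80, 4, 5))
})

test_that("average planes equal the brute-force pixel loop", {
  set.seed(14)
  triples <- lapply(1:5, function(i)
    lapply(1:3, function(j) matrix(sample(0:255, 20, TRUE), 4, 5)))
  chosen <- c(1L, 3L, 2L, 2L, 1L)
  ds <- mini_dataset(triples, chosen)
  sel <- average_planes(ds, "selected")
  uns <- average_planes(ds, "unselected")
  for (r in 1:4) for (cc in 1:5) {
    sel_vals <- vapply(1:5, function(i) triples[[i]][[chosen[i]]][r, cc],
                       numeric(1))
    uns_vals <- vapply(1:5, function(i) {
      others <- setdiff(1:3, chosen[i])
      (triples[[i]][[others[1]]][r, cc] +
         triples[[i]][[others[2]]][r, cc]) / 2
    }, numeric(1))
    expect_equal(sel[r, cc], mean(sel_vals))
    expect_equal(uns[r, cc], mean(uns_vals))
  }
  # linearity: difference of averages = average of per-trial differences
  per_trial <- selected_matrix(ds) - unselected_mean_matrix(ds)
  expect_equal(as.vector(sel - uns), colMeans(per_trial))
  expect_error(average_planes(ds[0]), "empty")
})

test_that("luminance enhancement follows E = (L - M) * gain + offset", {
  # fixed point: L = M everywhere -> uniform 128
  expect_true(all(enhance(matrix(57.3, 7, 9)) == 128L))
  # printed-equation arithmetic: M = 100, L = 105 -> 228
  expect_equal(enhance(matrix(105, 1, 1), M = 100)[1, 1], 228L)
  # clipping: M = 100, L = 110 -> 328 clamped to 255
  expect_equal(enhance(matrix(110, 1, 1), M = 100)[1, 1], 255L)
  expect_equal(enhance(matrix(80, 1, 1), M = 100)[1, 1], 0L)
  # sign pattern of L - M preserved wherever unclipped
  set.seed(3)
  L <- matrix(rnorm(200, 10, 1), 10, 20)
  E <- enhance(L)
  unclipped <- E > 0L & E < 255L
  expect_true(all(sign(E[unclipped] - 128L) ==
                    sign(round(L - mean(L), 10))[unclipped] |
                    E[unclipped] == 128L))
})

test_that("classification images assemble raw and enhanced planes coherently", {
  fx <- tiny_fx()
  ds <- fx$dataset[1:60]
  ci <- classification_image(ds)
  expect_equal(ci$difference, ci$selected_mean - ci$unselected_mean)
  expect_equal(ci$n_trials, 60)
  expect_equal(ci$M[["difference"]], mean(ci$difference))
  expect_true(all(ci$enhanced_difference >= 0 &
                    ci$enhanced_difference <= 255))
  expect_identical(ci$enhanced_difference,
                   enhance(ci$difference, mean(ci$difference)))

  # serialization: raw difference plane round-trips losslessly
  dir <- tempfile("ci")
  write_classification_image(ci, dir)
  expect_identical(read_plane_tsv(file.path(dir, "ci_difference_raw.tsv")),
                   ci$difference)
  expect_true(file.exists(file.path(dir, "ci_selected.png")))
  unlink(dir, recursive = TRUE)
})

test_that("random selection leaves no structure in the difference image", {
  fx <- tiny_fx()
  ds <- random_selection_null(fx$dataset[1:300], seed = 4)
  ci <- classification_image(ds)
  aoi_mean <- mean(crop_aoi(ci$difference, fx$aoi))
  # pixel-noise bound: |mean| < 3 * sd / sqrt(n_trials)
  expect_lt(abs(aoi_mean), 3 * 30 / sqrt(300))
  # and the null selection is seed-reproducible
  expect_identical(random_selection_null(fx$dataset, seed = 4)$chosen[1:300],
                   ds$chosen)
})
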