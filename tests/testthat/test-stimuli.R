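test_that("noise generation is seeded, Gaussian and 8-bit clipped", {
  # zero variance collapses to the mean everywhere
  flat <- generate_noise(300, 350, mean = 128, sd = 0, seed = 1)
  expect_true(all(flat$pixels == 128L))
  expect_equal(dim(flat$pixels), c(350L, 300L))

  # seeded determinism, bit for bit
  a <- generate_noise(300, 350, seed = 7)
  b <- generate_noise(300, 350, seed = 7)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, generate_noise(300, 350, seed = 8)$pixels))

  # CLT bounds at n = 105,000 pixels: mean within 128 +/- 1, sd within
  # 30 +/- 1 (clipping at 0/255 is > 4 sigma away and negligible)
  expect_lt(abs(mean(a$pixels) - 128), 1)
  expect_lt(abs(sd(a$pixels) - 30), 1)

  expect_true(all(a$pixels >= 0L & a$pixels <= 255L))
  expect_error(generate_noise(0, 350), "positive")
  expect_error(generate_noise(300, -1), "positive")
})

test_that("compositing blends only the centered target region", {
  geom <- stim_geometry()
  noise <- generate_noise(seed = 3)
  tgt <- matrix(200L, geom$target_h, geom$target_w)

  # opacity 0 is the identity; opacity 1 replaces the central region
  expect_identical(composite_target(noise, NULL, 0, geom)$pixels,
                   noise$pixels)
  full <- composite_target(noise, tgt, 1, geom)
  expect_true(all(crop_aoi(full$pixels, default_aoi(geom)) == 200L))

  # blend arithmetic at a central pixel: (1-0.25)*100 + 0.25*200 = 125
  flat100 <- generate_noise(mean = 100, sd = 0, seed = 1)
  q <- composite_target(flat100, tgt, 0.25, geom)
  expect_equal(q$pixels[175, 150], 125)

  # locality: pixels outside the central region untouched at any opacity
  for (op in c(0.2, 0.5, 1)) {
    comp <- composite_target(noise, tgt, op, geom)
    outside <- comp$pixels
    aoi <- default_aoi(geom)
    rows <- (aoi$y_offset + 1):(aoi$y_offset + aoi$height)
    cols <- (aoi$x_offset + 1):(aoi$x_offset + aoi$width)
    outside[rows, cols] <- noise$pixels[rows, cols]
    expect_identical(outside, noise$pixels)
  }
  expect_error(composite_target(noise, tgt, 1.5), "opacity")
  expect_error(composite_target(noise, matrix(0L, 5, 5), 0.5, geom),
               "target image")
})

test_that("framing draws the ellipse aperture and cross exactly once", {
  geom <- stim_geometry()
  stim <- composite_target(generate_noise(mean = 128, sd = 0, seed = 1),
                           NULL, 0, geom)
  framed <- apply_frame_and_cross(stim, geom)
  expect_true(framed$framed)

  # corners lie outside the ellipse -> background black
  expect_equal(framed$pixels[1, 1], 0)
  expect_equal(framed$pixels[350, 300], 0)
  # canvas center lies on the cross -> cross color (black)
  expect_equal(framed$pixels[175, 150], 0)
  # a point inside the aperture away from the cross keeps its luminance
  expect_equal(framed$pixels[100, 150], 128)

  # cross mask pixel count: 2 * size * thickness - thickness^2
  expect_equal(sum(cross_mask(geom)), 2 * 12 * 2 - 4)

  expect_error(apply_frame_and_cross(framed, geom), "already framed")
})

test_that("target banks are distinct, deterministic and top-heavy", {
  for (cat in c("human_face", "chimpanzee_face", "letter")) {
    bank <- make_target_bank(cat, 20, seed = 42)
    expect_length(bank, 20)
    expect_equal(length(unique(lapply(bank, function(t) t$pixels))), 20)
    again <- make_target_bank(cat, 20, seed = 42)
    expect_identical(lapply(bank, `[[`, "pixels"),
                     lapply(again, `[[`, "pixels"))
    expect_true(all(vapply(bank, function(t)
      all(dim(t$pixels) == c(220, 200)), logical(1))))
  }
  # face banks: two dark eye blobs above one mouth, so the upper half of
  # the mean image is darker than the lower half
  for (cat in c("human_face", "chimpanzee_face")) {
    m <- bank_mean(make_target_bank(cat, 20, seed = 42))
    h <- nrow(m)
    expect_lt(mean(m[1:(h %/% 2), ]), mean(m[(h %/% 2 + 1):h, ]))
  }
  expect_error(make_target_bank("starfish", 20, seed = 1), "unknown")
})

test_that("stimuli round-trip bit-exactly through 8-bit grayscale PNG", {
  path <- withr::local_tempfile(fileext = ".png")
  noise <- generate_noise(30, 34, seed = 5)
  write_stimulus_png(noise, path)
  expect_identical(read_stimulus_png(path), noise$pixels)
})

test_that("AOI cropping uses the centered half-open convention", {
  aoi <- default_aoi(stim_geometry())
  expect_equal(c(aoi$x_offset, aoi$y_offset), c(50, 65))
  plane <- matrix(seq_len(350 * 300), 350, 300)
  sub <- crop_aoi(plane, aoi)
  expect_equal(dim(sub), c(220, 200))
  expect_equal(sub[1, 1], plane[66, 51])
  expect_equal(sub[220, 200], plane[285, 250])
  expect_error(crop_aoi(plane, aoi_spec(200, 65, 200, 220)), "outside")
})
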