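test_that("border extraction reduces filled shapes to outlines", {
  sq <- matrix(0L, 20, 20); sq[6:15, 6:15] <- 1L
  b <- extract_border(raster_trace(sq))
  expect_equal(sum(b$pixels), 36L)          # perimeter of a 10x10 block

  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_identical(extract_border(raster_trace(one))$pixels, one)

  # a 1-px curve is its own border
  g <- generate_curve("koch", iterations = 3, raster_px = 81)
  expect_identical(extract_border(g$trace)$pixels, g$trace$pixels)
})

test_that("border extraction matches the pixelwise neighbourhood oracle", {
  for (seed in 1:5) {
    tr <- rand_trace(seed, 24, 30, p = 0.4)
    for (conn in c(8, 4)) {
      expect_identical(extract_border(tr, connectivity = conn)$pixels,
                       oracle_border(tr, connectivity = conn))
    }
  }
})

test_that("count_boxes covers aligned patterns exactly", {
  one <- matrix(0L, 10, 10); one[4, 7] <- 1L
  tr1 <- raster_trace(one)
  for (s in c(1, 3, 8, 50)) expect_equal(count_boxes(tr1, s), 1L)

  line <- matrix(0L, 4, 64); line[2, ] <- 1L
  expect_equal(count_boxes(raster_trace(line), 8), 8L)
  expect_error(count_boxes(raster_trace(line), 8, origin = c(8, 0)),
               "origin")
})

test_that("count_boxes equals exhaustive cell enumeration", {
  for (seed in 1:6) {
    tr <- rand_trace(seed, 40, 40, p = 0.05)
    for (s in c(2L, 3L, 5L)) {
      expect_equal(count_boxes(tr, s), oracle_count_boxes(tr, s))
      org <- c(seed %% s, (seed + 1) %% s)
      expect_equal(count_boxes(tr, s, org), oracle_count_boxes(tr, s, org))
    }
  }
})

test_that("box-count series on an aligned line follows exact division", {
  line <- matrix(0L, 4, 64); line[2, ] <- 1L
  ser <- box_count_series(raster_trace(line), sizes = c(2, 4, 8, 16, 32, 64))
  expect_equal(ser$counts, c(32, 16, 8, 4, 2, 1))
  expect_equal(length(box_count_series(raster_trace(line))$sizes), 9L)
})

test_that("counts are non-increasing in box size and dyadically bounded", {
  for (seed in 1:4) {
    tr <- rand_trace(seed, 64, 64, p = 0.1)
    ser <- box_count_series(tr, sizes = c(2, 4, 8, 16, 32, 64))
    expect_true(all(diff(ser$counts) <= 0))
    # dyadic refinement: halving the box size at most quadruples counts
    n <- ser$counts
    expect_true(all(n[-length(n)] <= 4 * n[-1]))
  }
})

test_that("border extraction changes the series of a filled region", {
  sq <- matrix(0L, 64, 64); sq[5:60, 5:60] <- 1L
  tr <- raster_trace(sq)
  with_border <- box_count_series(extract_border(tr))
  without <- box_count_series(tr)
  expect_true(any(with_border$counts != without$counts))
  expect_true(all(with_border$counts <= without$counts))
})

test_that("dimension fitting recovers exact power laws", {
  s <- c(2, 4, 8, 16)
  mk <- function(counts) structure(
    list(sizes = s, counts = counts, grid_origin = c(0L, 0L)),
    class = "boxcount_series")
  suppressWarnings({   # lm flags the exact fit as "essentially perfect"
    expect_equal(fit_dimension(mk(1024 / s))$D, 1, tolerance = 1e-12)
    expect_equal(fit_dimension(mk(4096 / s^2))$D, 2, tolerance = 1e-12)
  })
  expect_warning(f0 <- fit_dimension(mk(rep(7, 4))), "degenerate")
  expect_equal(f0$D, 0)
  expect_error(fit_dimension(mk(c(8, 4, 0, 0))), ">= 3 sizes")
})

test_that("dimension fit equals the normal-equations oracle", {
  set.seed(9)
  for (rep in 1:10) {
    sizes <- sort(sample(2:64, 6))
    counts <- round(exp(7 - 1.3 * log(sizes) + rnorm(6, 0, 0.1)))
    counts <- pmax(counts, 1)
    ser <- structure(list(sizes = sizes, counts = counts,
                          grid_origin = c(0L, 0L)),
                     class = "boxcount_series")
    fit <- suppressWarnings(fit_dimension(ser))
    oracle <- oracle_ols(log(sizes), log(counts))
    expect_equal(fit$D, -unname(oracle["slope"]), tolerance = 1e-12)
    expect_equal(fit$intercept, unname(oracle["intercept"]),
                 tolerance = 1e-12)
  }
})

test_that("D is invariant under grid-aligned translation and rotation", {
  g <- generate_curve("koch", iterations = 5, raster_px = 512)
  base <- estimate_D(g$trace)$D
  # translation by 192 px = a whole multiple of every default box size
  shifted <- matrix(0L, 512 + 192, 512 + 192)
  shifted[193:704, 193:704] <- g$trace$pixels
  expect_equal(estimate_D(raster_trace(shifted))$D, base, tolerance = 0.02)
  # 90-degree rotation, dyadic ladder on the square image
  dyadic <- c(2, 4, 8, 16, 32, 64)
  d0 <- estimate_D(g$trace, sizes = dyadic)$D
  rot <- raster_trace(t(g$trace$pixels)[512:1, ])
  expect_equal(estimate_D(rot, sizes = dyadic)$D, d0, tolerance = 0.02)
})

test_that("D is stable when the same curve is rasterized at 2x resolution", {
  d1 <- estimate_D(generate_curve("koch", 6, 729)$trace)$D
  d2 <- estimate_D(generate_curve("koch", 6, 1458)$trace)$D
  expect_lt(abs(d1 - d2), 0.05)
})

test_that("estimate_D hits the line and plane limits", {
  line <- generate_curve("line", raster_px = 512, angle = 45)
  expect_true(estimate_D(line$trace)$D > 0.95 &&
              estimate_D(line$trace)$D < 1.08)
  filled <- generate_curve("filled_box", raster_px = 512)
  d <- suppressWarnings(estimate_D(filled$trace, border = FALSE)$D)
  expect_true(d > 1.9 && d < 2.05)
})

test_that("batch estimation skips unreadable files softly", {
  dir <- withr::local_tempdir()
  for (k in c("koch", "line")) {
    g <- generate_curve(k, iterations = 3, raster_px = 128)
    write_trace(g$trace, file.path(dir, paste0(k, ".png")))
  }
  writeLines("not an image", file.path(dir, "broken.png"))
  out <- suppressWarnings(estimate_D_dir(dir))
  expect_equal(nrow(out), 2L)
  expect_setequal(out$specimen_id, c("koch", "line"))
})
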