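# Percentile clipping, mixed-pixel classification, resolution score.

make_image <- function(values, valid = NULL) {
  structure(list(values = values,
                 valid = if (is.null(valid))
                   matrix(TRUE, nrow(values), ncol(values)) else valid,
                 mz_center = 0, mz_tol = 0, reducer = "sum"),
            class = "ion_image")
}

test_that("clip_channel clamps to percentiles computed by a sort oracle", {
  vals <- matrix(1:100, 10, 10)
  img <- make_image(vals)
  mask <- tissue_mask(matrix(TRUE, 10, 10))
  cl <- clip_channel(img, mask, 3, 97)
  # independent oracle: linear interpolation between order statistics
  sort_pctl <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p / 100 + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  expect_equal(min(cl$values), sort_pctl(1:100, 3))
  expect_equal(max(cl$values), sort_pctl(1:100, 97))
  # interior values are untouched
  inside <- vals > sort_pctl(1:100, 3) & vals < sort_pctl(1:100, 97)
  expect_equal(cl$values[inside], vals[inside])
  # random data against the same oracle
  for (i in 1:10) {
    set.seed(i)
    v <- matrix(rlnorm(64), 8, 8)
    m8 <- tissue_mask(matrix(runif(64) > 0.3, 8, 8))
    cc <- clip_channel(make_image(v), m8, 3, 97)
    expect_equal(min(cc$values[m8$grid]), sort_pctl(v[m8$grid], 3),
                 tolerance = 1e-12)
    expect_equal(max(cc$values[m8$grid]), sort_pctl(v[m8$grid], 97),
                 tolerance = 1e-12)
    # off-tissue pixels untouched
    expect_equal(cc$values[!m8$grid], v[!m8$grid])
  }
})

test_that("clip_channel handles degenerate inputs as specified", {
  mask1 <- tissue_mask(matrix(c(TRUE, rep(FALSE, 8)), 3, 3))
  expect_error(clip_channel(make_image(matrix(1:9, 3, 3)), mask1),
               "fewer than 2")
  const <- make_image(matrix(5, 3, 3))
  maskT <- tissue_mask(matrix(TRUE, 3, 3))
  expect_warning(cl <- clip_channel(const, maskT), "constant")
  expect_true(all(cl$values == 5))
  expect_error(clip_channel(const, maskT, 97, 3), "low_pct")
})

test_that("pixel classification follows the ratio rule exactly", {
  mask <- tissue_mask(matrix(TRUE, 1, 2))
  red <- make_image(matrix(c(1, 1), 1, 2))
  green <- make_image(matrix(c(1, 0.5), 1, 2))
  res <- classify_pixels(red, green, mask, 0.7)
  expect_identical(as.vector(res$labels), c(3L, 1L))  # yellow then red
  expect_equal(res$score_percent, 50)
  # identical channels: every pixel yellow, score 100
  both <- make_image(matrix(runif(36) + 1, 6, 6))
  res100 <- classify_pixels(both, both, tissue_mask(matrix(TRUE, 6, 6)))
  expect_equal(res100$score_percent, 100)
  expect_true(all(res100$labels == 3L))
  expect_error(classify_pixels(red, make_image(matrix(1, 2, 2)), mask),
               "dimensions")
  expect_error(classify_pixels(red, green, mask, ratio = 0), "ratio")
})

test_that("classification agrees with a brute-force per-pixel oracle", {
  for (i in 1:20) {
    set.seed(100 + i)
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    a <- matrix(rlnorm(nr * nc), nr, nc)
    b <- matrix(rlnorm(nr * nc), nr, nc)
    on <- matrix(runif(nr * nc) > 0.2, nr, nc)
    ratio <- runif(1, 0.3, 1)
    res <- classify_pixels(make_image(a), make_image(b), tissue_mask(on),
                           ratio)
    # independent single-pass reference
    ref <- matrix(0L, nr, nc)
    ny <- nr_ <- ng <- 0
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (!on[r, cc]) next
      x <- a[r, cc]; y <- b[r, cc]
      if (min(x, y) >= ratio * max(x, y)) { ref[r, cc] <- 3L; ny <- ny + 1 }
      else if (x > y) { ref[r, cc] <- 1L; nr_ <- nr_ + 1 }
      else { ref[r, cc] <- 2L; ng <- ng + 1 }
    }
    expect_identical(res$labels, ref)
    expect_equal(res$score_percent, 100 * ny / (ny + nr_ + ng))
  }
})

test_that("the score is invariant to channel swap and positive scaling", {
  set.seed(12)
  a <- make_image(matrix(rlnorm(49), 7, 7))
  b <- make_image(matrix(rlnorm(49), 7, 7))
  mask <- tissue_mask(matrix(TRUE, 7, 7))
  clip <- function(img) clip_channel(img, mask, rescale = TRUE)
  s1 <- classify_pixels(clip(a), clip(b), mask)$score_percent
  s2 <- classify_pixels(clip(b), clip(a), mask)$score_percent
  expect_equal(s1, s2)
  for (c_ in c(5, 100, 1e6)) {
    ac <- make_image(c_ * a$values)
    expect_equal(classify_pixels(clip(ac), clip(b), mask)$score_percent, s1)
  }
  # the clamp-only reading is deliberately NOT scale invariant: comparing
  # raw clamped magnitudes of unrelated ions degenerates under rescaling
  clamp <- function(img) clip_channel(img, mask)
  s_raw <- classify_pixels(clamp(a), clamp(b), mask)$score_percent
  a_big <- make_image(1e4 * a$values)
  s_big <- classify_pixels(clamp(a_big), clamp(b), mask)$score_percent
  expect_false(isTRUE(all.equal(s_raw, s_big)))
})

test_that("excluded pixels are exactly the off-mask or unmeasured ones", {
  set.seed(4)
  valid <- matrix(runif(25) > 0.2, 5, 5)
  on <- matrix(runif(25) > 0.3, 5, 5)
  a <- make_image(matrix(rlnorm(25), 5, 5), valid)
  b <- make_image(matrix(rlnorm(25), 5, 5), valid)
  res <- classify_pixels(a, b, tissue_mask(on))
  expect_identical(res$labels == 0L, !(on & valid))
})

test_that("the full score pipeline carries parameters and respects flags", {
  ph <- generate_phantom(test_spec(seed = 8))
  res <- spatial_resolution_score(ph$dataset, ph$truth$mask)
  expect_true(res$score_percent >= 0 && res$score_percent <= 100)
  expect_equal(res$params$red_mz, 944.6)
  expect_equal(res$params$ratio, 0.7)
  # the same m/z in both channels makes every classified pixel yellow
  same <- spatial_resolution_score(ph$dataset, ph$truth$mask,
                                   red_mz = 944.6, green_mz = 944.6)
  expect_equal(same$score_percent, 100)
  # alternative clipping interpretation stays within bounds
  r2 <- spatial_resolution_score(ph$dataset, ph$truth$mask,
                                 rescale_after_clip = TRUE)
  expect_true(r2$score_percent >= 0 && r2$score_percent <= 100)
  # a signal floor can only exclude pixels, never invent yellow ones
  r3 <- spatial_resolution_score(ph$dataset, ph$truth$mask,
                                 min_signal_fraction = 0.05)
  expect_lte(r3$counts[["YELLOW"]], res$counts[["YELLOW"]] +
               res$counts[["RED"]] + res$counts[["GREEN"]])
})
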