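# one-pixel chromaticity frame helper
px <- function(r, g, b) chrom_frame(matrix(r), matrix(g), matrix(b),
                                    matrix(TRUE))

test_that("the r-b and r-g conditions keep boundary pixels (non-strict)", {
  expect_true(apply_rb_condition(px(0.6, 0.2, 0.2), 2.8)[1, 1])
  expect_false(apply_rb_condition(px(0.5, 0.3, 0.2), 2.8)[1, 1])
  expect_true(apply_rb_condition(px(0.56, 0.24, 0.2), 2.8)[1, 1])  # on the line

  p <- px(0.6, 0.25, 0.15)
  expect_true(apply_rg_condition(p, 2.0, matrix(TRUE))[1, 1])
  expect_false(apply_rg_condition(px(0.4, 0.25, 0.35), 2.0, matrix(TRUE))[1, 1])
  # sequential gating: not in prior -> never kept
  expect_false(apply_rg_condition(p, 2.0, matrix(FALSE))[1, 1])

  expect_error(apply_rb_condition(p, -1), "positive")
  expect_error(apply_rg_condition(p, 0, matrix(TRUE)), "positive")
})

test_that("extract_roi equals the brute-force conjunction and is monotone", {
  set.seed(31)
  for (rep in 1:25) {
    ch <- rand_chrom(32, 32)
    m <- runif(1, 1.5, 4)
    n <- runif(1, 1, 3)
    roi <- extract_roi(ch, roi_params(m, n))
    expect_identical(roi, oracle_roi(ch, m, n))
    expect_true(all(roi <= ch$valid))  # ROI within validity
    # monotone shrinkage in both slopes
    expect_true(all(extract_roi(ch, roi_params(m + 0.5, n)) <= roi))
    expect_true(all(extract_roi(ch, roi_params(m, n + 0.5)) <= roi))
    # order independence: rg first then rb gives the same set
    alt <- apply_rg_condition(ch, n, ch$valid) & apply_rb_condition(ch, m)
    expect_identical(roi, alt)
  }
})

test_that("degenerate chromaticities behave as expected", {
  expect_false(extract_roi(px(1 / 3, 1 / 3, 1 / 3))[1, 1])  # uniform gray
  expect_true(extract_roi(px(1, 0, 0), roi_params(10, 10))[1, 1])  # pure red
})

test_that("pixel accuracy matches its definition and symmetries", {
  set.seed(32)
  pred <- rand_mask(10, 10); truth <- rand_mask(10, 10)
  valid <- rand_mask(10, 10, 0.9)
  pa <- pixel_accuracy(pred, truth, valid)
  expect_equal(pa$n_true_bleeding, sum(pred & truth & valid))
  expect_equal(pa$accuracy,
               (pa$n_true_bleeding + pa$n_true_nonbleeding) / sum(valid))
  # perfect and inverted predictions
  expect_equal(pixel_accuracy(truth, truth, valid)$accuracy, 1)
  expect_equal(pixel_accuracy(!truth, truth, valid)$accuracy, 0)
  # symmetric under simultaneous complement
  expect_equal(pixel_accuracy(!pred, !truth, valid)$accuracy, pa$accuracy)
  expect_error(pixel_accuracy(pred, truth, matrix(FALSE, 10, 10)), "valid")
})

test_that("pixel accuracy reproduces the worked count example", {
  # 100 valid pixels, 80 true bleeding + 10 true nonbleeding -> 0.9
  valid <- matrix(TRUE, 10, 10)
  truth <- matrix(c(rep(TRUE, 85), rep(FALSE, 15)), 10, 10)
  pred <- truth
  pred[81:85] <- FALSE      # 5 bleeding pixels missed -> 80 true bleeding
  pred[86:90] <- TRUE       # 5 false bleeding -> 10 true nonbleeding
  pa <- pixel_accuracy(pred, truth, valid)
  expect_equal(pa$n_true_bleeding, 80)
  expect_equal(pa$n_true_nonbleeding, 10)
  expect_equal(pa$accuracy, 0.9)
})

test_that("sweep_slope recovers the separating slope on a constructed frame", {
  # bleeding pixels at r/b = 3.0 (pass m = 2.8, fail 3.6), background at
  # r/b = 2.5 (pass 2.0, fail 2.8): only m = 2.8 classifies perfectly
  n <- 16
  truth <- matrix(rep(c(TRUE, FALSE), each = n * n / 2), n, n)
  r <- matrix(0.5, n, n)
  b <- ifelse(truth, 0.5 / 3.0, 0.5 / 2.5)
  g <- 1 - r - b
  ch <- chrom_frame(r, g, b, matrix(TRUE, n, n))
  sw <- sweep_slope(list(list(chrom = ch, truth = truth)), c(2.0, 2.8, 3.6),
                    stage = "rb")
  # brute-force accuracy per grid value
  for (j in 1:3) {
    acc <- mean((ch$r >= sw$table$value[j] * ch$b) == truth)
    expect_equal(sw$table$mean_accuracy[j], acc)
  }
  expect_equal(sw$argmax, 2.8)
  expect_equal(sw$table$mean_accuracy[2], 1)

  # single-value grid: argmax trivially that value, sd over one image is 0
  one <- sweep_slope(list(list(chrom = ch, truth = truth)), 2.8, stage = "rb")
  expect_equal(one$argmax, 2.8)
  expect_equal(one$table$std_accuracy, 0)
})

test_that("sweep summary statistics agree with an independent recomputation", {
  set.seed(33)
  imgs <- lapply(1:4, function(i) {
    ch <- rand_chrom(20, 20, p_invalid = 0)
    list(chrom = ch, truth = rand_mask(20, 20, 0.3))
  })
  grid <- seq(2, 3, 0.5)
  sw <- sweep_slope(imgs, grid, stage = "rg", fixed_m = 2.8)
  for (j in seq_along(grid)) {
    accs <- vapply(imgs, function(im) {
      mask <- oracle_roi(im$chrom, 2.8, grid[j])
      pixel_accuracy(mask, im$truth, im$chrom$valid)$accuracy
    }, numeric(1))
    expect_equal(sw$table$mean_accuracy[j], mean(accs), tolerance = 1e-12)
    expect_equal(sw$table$std_accuracy[j], sd(accs), tolerance = 1e-12)
  }
  expect_error(sweep_slope(imgs, numeric(0)), "empty grid")
  expect_error(sweep_slope(list(), grid), "empty image set")
  expect_error(sweep_slope(imgs, grid, stage = "rg"), "fixed_m")
})

test_that("joint sweep finds a perfect cell and breaks ties toward small slopes", {
  # only the r-b plane separates (both classes share r/g = 2.2); every n that
  # keeps the bleeding pixels is optimal, so ties resolve to the smallest n
  n <- 16
  truth <- matrix(rep(c(TRUE, FALSE), each = n * n / 2), n, n)
  r <- matrix(0.5, n, n)
  b <- ifelse(truth, 0.5 / 3.0, 0.5 / 2.5)
  g <- matrix(0.5 / 2.2, n, n)
  # not a simplex frame; rescale each pixel to sum 1 (ratios are preserved)
  s <- r + g + b
  ch <- chrom_frame(r / s, g / s, b / s, matrix(TRUE, n, n))
  js <- sweep_slope_joint(list(list(chrom = ch, truth = truth)),
                          c(2.0, 2.8, 3.6), c(1.5, 2.0, 2.5))
  expect_equal(unname(js$argmax), c(2.8, 1.5))
  expect_equal(max(js$mean_accuracy), 1)
})
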