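test_that("knn_predict matches the exhaustive oracle, including ties", {
  set.seed(51)
  for (rep in 1:60) {
    n <- sample(4:20, 1)
    d <- sample(2:8, 1)
    # integer coordinates on a tiny lattice provoke duplicate distances,
    # even k provokes vote ties
    x <- matrix(sample(0:3, n * d, TRUE), n, d)
    y <- sample(c("bleeding", "nonbleeding"), n, TRUE)
    k <- sample(1:min(6, n), 1)
    q <- sample(0:3, d, TRUE)
    expect_identical(unname(knn_predict(x, y, q, k)), oracle_knn(x, y, q, k))
  }
})

test_that("knn_predict agrees with class::knn on tie-free instances", {
  set.seed(52)
  for (rep in 1:20) {
    n <- 30; d <- 4
    x <- matrix(rnorm(n * d), n, d)
    y <- factor(sample(c("bleeding", "nonbleeding"), n, TRUE))
    q <- matrix(rnorm(5 * d), 5, d)
    ref <- as.character(class::knn(x, q, y, k = 3))
    expect_identical(unname(knn_predict(x, y, q, k = 3)),
                     factor(ref, levels = levels(y)))
  }
})

test_that("knn_predict honours the documented base cases and guards", {
  x <- rbind(c(0, 0), c(5, 5), c(9, 0))
  y <- c("bleeding", "nonbleeding", "bleeding")
  expect_equal(knn_predict(x, y, c(5, 5), k = 1), "nonbleeding")
  # majority of 3: two bleeding beat one nonbleeding
  x2 <- rbind(c(0, 0), c(1, 0), c(3, 0), c(50, 50))
  y2 <- c("bleeding", "bleeding", "nonbleeding", "nonbleeding")
  expect_equal(knn_predict(x2, y2, c(0.4, 0), k = 3), "bleeding")
  expect_error(knn_predict(x[0, ], character(0), c(1, 2), 1), "empty training")
  expect_error(knn_predict(x, y, c(1, 2), k = 4), "k must lie")
  expect_error(knn_predict(x, y, c(1, 2, 3), k = 1), "query length")
})

test_that("knn_predict is invariant to rigid translation and self-consistent", {
  set.seed(53)
  x <- matrix(rnorm(40), 20, 2)
  y <- sample(c("bleeding", "nonbleeding"), 20, TRUE)
  q <- matrix(rnorm(10), 5, 2)
  shift <- c(13.7, -4.2)
  expect_identical(
    knn_predict(x, y, q, 5),
    knn_predict(sweep(x, 2, shift, "+"), y, sweep(q, 2, shift, "+"), 5)
  )
  # k = 1 on distinct points recovers each training label
  expect_identical(knn_predict(x, y, x, 1), y)
})

test_that("cross_validate predicts each sample once and pools counts", {
  set.seed(54)
  # two well-separated clusters: perfect tenfold CV accuracy
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(60, 30), 30))
  y <- rep(c("bleeding", "nonbleeding"), c(20, 30))
  cv <- cross_validate(x, y, folds = 10, k = 5, seed = 7)
  expect_equal(cv$metrics$accuracy, 1)
  expect_equal(cv$metrics$sensitivity, 1)
  expect_equal(cv$metrics$specificity, 1)
  with(cv$counts, expect_equal(t_b + f_nb + t_nb + f_b, 50))
  # stratification: every fold holds both classes
  expect_true(all(tapply(y, cv$fold, function(l) length(unique(l))) == 2))
  # determinism in the seed
  cv2 <- cross_validate(x, y, folds = 10, k = 5, seed = 7)
  expect_identical(cv$predictions, cv2$predictions)

  expect_error(cross_validate(x, y, folds = 51), "folds")
  expect_error(cross_validate(x[1:10, ], y[1:10], folds = 2, k = 6),
               "fewer than k")
})

test_that("folds = n reproduces leave-one-out predictions exactly", {
  set.seed(55)
  x <- matrix(rnorm(20), 10, 2)
  y <- sample(c("bleeding", "nonbleeding"), 10, TRUE)
  cv <- cross_validate(x, y, folds = 10, k = 3)
  loo <- vapply(1:10, function(i)
    oracle_knn(x[-i, , drop = FALSE], y[-i], x[i, ], 3), character(1))
  expect_identical(cv$predictions, loo)
})

test_that("frame metrics follow their definitions, including undefined cases", {
  m <- frame_metrics(confusion_counts(
    rep(c("bleeding", "nonbleeding", "nonbleeding", "bleeding"),
        c(95, 5, 98, 2)),
    rep(c("bleeding", "nonbleeding"), c(100, 100))
  ))
  expect_equal(m$sensitivity, 0.95)
  expect_equal(m$specificity, 0.98)
  expect_equal(m$accuracy, 0.965)

  all_good <- frame_metrics(confusion_counts(c("bleeding", "nonbleeding"),
                                             c("bleeding", "nonbleeding")))
  expect_equal(unlist(all_good), c(sensitivity = 1, specificity = 1, accuracy = 1))

  # no bleeding frames at all: sensitivity undefined, not an error
  none <- frame_metrics(confusion_counts(rep("nonbleeding", 4),
                                         rep("nonbleeding", 4)))
  expect_true(is.na(none$sensitivity))
  expect_equal(none$specificity, 1)
})

test_that("accuracy decomposes exactly into class-weighted sens/spec", {
  set.seed(56)
  for (rep in 1:20) {
    cnt <- structure(as.list(sample(1:50, 4)), class = "confusion_counts")
    names(cnt) <- c("t_b", "f_nb", "t_nb", "f_b")
    m <- frame_metrics(cnt)
    P <- cnt$t_b + cnt$f_nb
    N <- cnt$t_nb + cnt$f_b
    expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
  }
})
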