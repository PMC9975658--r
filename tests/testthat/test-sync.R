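test_that("PLV identities hold", {
  expect_equal(plv(c(0, 0), c(0, pi)), 0, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    th <- runif(50, -pi, pi)
    c0 <- runif(1, -10, 10)
    expect_equal(plv(th, th), 1, tolerance = 1e-12)
    expect_equal(plv(th, th + c0), 1, tolerance = 1e-12)
    th2 <- runif(50, -pi, pi)
    v <- plv(th, th2)
    expect_equal(v, plv(th2, th), tolerance = 1e-12)
    expect_true(v >= 0 && v <= 1)
  }
  expect_error(plv(c(0, 1), c(0, 1, 2)),
               class = "speechsync_invalid_input")
  expect_error(plv(0.5, 0.2), class = "speechsync_invalid_input")
})

test_that("window tiling matches the hop arithmetic", {
  th <- seq(0, 2 * pi * 4.5 * 80, length.out = 8000)
  w <- windowed_plv(th, th + 0.3, sample_rate = 100)
  expect_equal(nrow(w$windows), 26) # floor((8000-500)/300)+1
  expect_true(all(abs(w$windows$plv - 1) < 1e-12))
  expect_equal(w$trial_plv, 1, tolerance = 1e-12)

  w1 <- windowed_plv(th[1:500], th[1:500], sample_rate = 100)
  expect_equal(nrow(w1$windows), 1)
  expect_equal(w1$trial_plv, w1$windows$plv)

  expect_error(windowed_plv(th[1:499], th[1:499], sample_rate = 100),
               class = "speechsync_invalid_input")
})

test_that("participant PLV is the unweighted trial mean", {
  expect_equal(participant_plv(0.5), 0.5)
  expect_equal(participant_plv(c(0.4, 0.6)), 0.5)
  expect_equal(participant_plv(rep(0.37, 8)), 0.37)
  expect_error(participant_plv(numeric(0)),
               class = "speechsync_invalid_input")
})

test_that("k-means split matches the exhaustive 1-D oracle", {
  cl <- classify_synchronizers(c(0.30, 0.35, 0.40, 0.70, 0.75, 0.80))
  expect_equal(as.character(tidy(cl)$label),
               c("LOW", "LOW", "LOW", "HIGH", "HIGH", "HIGH"))
  expect_equal(unname(cl$centers), c(0.35, 0.75), tolerance = 1e-12)

  two <- classify_synchronizers(c(0.1, 0.9))
  expect_equal(sort(as.character(tidy(two)$label)), c("HIGH", "LOW"))

  expect_error(classify_synchronizers(rep(0.5, 4)),
               class = "speechsync_degenerate_clustering")

  set.seed(42)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    x <- round(runif(n), 3)
    if (length(unique(x)) < 2) next
    cl <- classify_synchronizers(x, seed = i)
    oracle <- kmeans_1d_oracle(x)
    expect_equal(as.character(tidy(cl)$label), oracle$labels)
    expect_equal(cl$tot_withinss, oracle$ss, tolerance = 1e-9)
  }
})

test_that("classification is deterministic given a seed", {
  co <- make_plv_cohort(seed = 8)
  a <- classify_synchronizers(co[c("participant", "plv")], seed = 1)
  b <- classify_synchronizers(co[c("participant", "plv")], seed = 1)
  expect_identical(tidy(a), tidy(b))
})

test_that("expected PLV rises monotonically with coupling concentration", {
  kappas <- c(0.5, 1, 2, 4)
  means <- vapply(kappas, function(k) {
    mean(vapply(1:25, function(i) {
      cp <- make_coupled_phases(kappa = k, duration = 40, seed = 300 + i)
      plv(cp$theta1, cp$theta2)
    }, numeric(1)))
  }, numeric(1))
  # allow Monte-Carlo slack well below the spacing of the Bessel ratios
  expect_true(all(diff(means) > 0.02))
})
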