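# GFP retention index, empty-vector normalization, error propagation and
# the synthetic sort generator.

test_that("identity cases: equal arms give retention 1 and zero loss", {
  set.seed(1)
  f <- rlnorm(200, log(200), 0.3)
  rec <- data.frame(worm_id = 1:400, fluorescence = c(f, f),
                    condition = rep(c("uninjured", "injured"), each = 200),
                    treatment = "EV", repeat_id = rep(1:2, 100))
  r <- gfp_index(sort_batch(rec), "EV")
  expect_equal(r$retention, 1, tolerance = 1e-12)
  expect_equal(r$percent_loss, 0, tolerance = 1e-10)
  expect_equal(r$normalized_index, 1, tolerance = 1e-12)
})

test_that("noise-free attenuation 0.579 yields a 42.1% loss", {
  set.seed(2)
  f <- rlnorm(300, log(150), 0.25)
  rec <- data.frame(worm_id = 1:600, fluorescence = c(f, 0.579 * f),
                    condition = rep(c("uninjured", "injured"), each = 300),
                    treatment = "EV", repeat_id = rep(1:3, 200))
  r <- gfp_index(sort_batch(rec), "EV")
  expect_equal(r$percent_loss, 42.1, tolerance = 1e-9)
  # any treatment whose retention equals the EV retention has index 1
  rec2 <- rec; rec2$treatment <- "cox-5b"
  r2 <- gfp_index(sort_batch(rbind(rec, rec2)), "cox-5b")
  expect_equal(r2$normalized_index, 1, tolerance = 1e-12)
})

test_that("error propagation matches the quadrature formula by hand", {
  # single repeat, zero error
  expect_equal(propagate_error(0, 0.4)$total, 0)
  # two repeats with equal errors e: within = sqrt(2) * e / (1 - EV)
  e <- 0.03; cc <- 0.42
  r <- propagate_error(c(e, e), cc)
  expect_equal(r$within, sqrt(2) * e / (1 - cc), tolerance = 1e-12)
  expect_equal(r$total, r$within)
  # three-repeat fixture evaluated by hand, with a between-repeat term
  dX <- c(0.02, 0.05, 0.01); cc <- 0.3; bet <- 0.04
  r <- propagate_error(dX, cc, bet)
  expect_equal(r$within, sqrt(sum((dX / 0.7)^2)), tolerance = 1e-12)
  expect_equal(r$total, sqrt(sum((dX / 0.7)^2) + 0.04^2), tolerance = 1e-12)
  # order independence
  expect_equal(propagate_error(rev(dX), cc, bet)$total, r$total)
  # single-variable reduction
  expect_equal(propagate_error(0.05, cc)$total, 0.05 / 0.7, tolerance = 1e-12)
  # degenerate EV constant
  expect_error(propagate_error(0.01, 1), "ev_constant")
  expect_error(propagate_error(-0.01, 0.4), "errors")
})

test_that("generator is reproducible, validated, and recovers its parameters", {
  b1 <- simulate_sort(seed = 33)
  b2 <- simulate_sort(seed = 33)
  expect_identical(b1, b2)
  expect_false(identical(b1$fluorescence,
                         simulate_sort(seed = 34)$fluorescence))
  expect_equal(nrow(b1), 1181)
  expect_true(all(table(b1$repeat_id, b1$condition) >= 295))
  expect_error(simulate_sort(n_worms = 3, n_repeats = 2), "at least")
  expect_error(simulate_sort(attenuation = 0), "attenuation")
  # retention near the generating attenuation (3 SEM), n = 1200
  b <- simulate_sort(n_worms = 1200, attenuation = 0.7, cv = 0.3,
                     n_repeats = 2, seed = 5)
  r <- gfp_index(b, "EV")
  sem <- r$total_error
  expect_lt(abs(r$retention - 0.7), 3 * max(sem, 1e-3))
  # null case: attenuation 1 -> loss within 3 SEM of 0
  b0 <- simulate_sort(n_worms = 1200, attenuation = 1, cv = 0.3,
                      n_repeats = 2, seed = 6)
  r0 <- gfp_index(b0, "EV")
  expect_lt(abs(r0$percent_loss), 300 * max(r0$total_error, 1e-3))
})

test_that("the loss estimator is unbiased over many generator seeds", {
  est <- vapply(1:200, function(s) {
    b <- simulate_sort(n_worms = 1200, attenuation = 0.579, cv = 0.3,
                       n_repeats = 2, seed = s)
    gfp_index(b, "EV")$percent_loss
  }, numeric(1))
  expect_lt(abs(mean(est) - 42.1), 0.5)
})

test_that("the index is invariant under fluorescence rescaling", {
  b <- simulate_sort(n_worms = 800, attenuation = 0.6, cv = 0.3,
                     n_repeats = 2, seed = 9)
  r1 <- gfp_index(b, "EV")
  b2 <- b; b2$fluorescence <- 7.3 * b2$fluorescence
  r2 <- gfp_index(b2, "EV")
  expect_equal(r1$retention, r2$retention, tolerance = 1e-12)
  expect_equal(r1$normalized_index, r2$normalized_index, tolerance = 1e-12)
  expect_equal(r1$total_error, r2$total_error, tolerance = 1e-12)
})

test_that("batch validation names the offending treatment and repeat", {
  rec <- data.frame(worm_id = 1:10, fluorescence = rlnorm(10, 5, 0.2),
                    condition = "injured", treatment = "cox-5b",
                    repeat_id = 1)
  expect_error(sort_batch(rec), "cox-5b.*repeat 1|repeat 1.*cox-5b")
  rec$fluorescence[1] <- -2
  expect_error(sort_batch(rec), "fluorescence")
  b <- simulate_sort(n_worms = 100, seed = 3)
  expect_error(gfp_index(b, "cox-5b"), "not present")
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  write.csv(b, f, row.names = FALSE)
  expect_equal(read_sort_batch(f)$fluorescence, b$fluorescence,
               tolerance = 1e-12)
  unlink(f)
})
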