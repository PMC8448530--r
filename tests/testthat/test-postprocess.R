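# Tensor invariants and peak extraction.

rot2 <- function(theta) matrix(c(cos(theta), sin(theta), -sin(theta),
                                 cos(theta)), 2, 2)

test_that("von Mises matches its closed forms and is rotation invariant", {
  expect_equal(von_mises(c(5e3, 0, 0)), 5e3)            # uniaxial
  expect_equal(von_mises(c(0, 0, 2e3)), sqrt(3) * 2e3)  # pure shear
  expect_equal(von_mises(c(7e3, 7e3, 0), szz = 7e3), 0) # hydrostatic
  expect_equal(von_mises(c(1e3, 2e3, 0), nu = 0.5),
               von_mises(c(1e3, 2e3, 0), szz = 1.5e3))
  set.seed(11)
  for (i in 1:20) {
    s <- c(rnorm(2, sd = 1e4), rnorm(1, sd = 5e3))
    S <- matrix(c(s[1], s[3], s[3], s[2]), 2, 2)
    th <- runif(1, 0, 2 * pi)
    Sr <- rot2(th) %*% S %*% t(rot2(th))
    expect_equal(von_mises(Sr, szz = 1234), von_mises(S, szz = 1234),
                 tolerance = 1e-9)
    expect_gte(von_mises(S), 0)
  }
})

test_that("max principal strain matches brute-force eigenvalues and shifts", {
  expect_equal(max_principal(c(0.05, 0, 0)), 0.05)       # uniaxial
  expect_equal(max_principal(c(0, 0, 0.01)), 0.01)       # pure shear +/- gamma/2
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(3, sd = 0.1)
    A <- matrix(c(a[1], a[3], a[3], a[2]), 2, 2)
    expect_equal(max_principal(A), max(eigen(A, symmetric = TRUE)$values),
                 tolerance = 1e-12)
    th <- runif(1, 0, 2 * pi)
    expect_equal(max_principal(rot2(th) %*% A %*% t(rot2(th))),
                 max_principal(A), tolerance = 1e-12)
    lam <- rnorm(1, sd = 0.05)   # isotropic shift moves the eigenvalue by lam
    expect_equal(max_principal(A + lam * diag(2)), max_principal(A) + lam,
                 tolerance = 1e-12)
  }
})

test_that("first_peak returns the earliest qualifying local maximum", {
  t <- seq(0, 10, by = 0.1)
  # two bumps: small early (0.4) at t=2, large late (1.0) at t=7
  y <- 0.4 * exp(-(t - 2)^2) + 1.0 * exp(-(t - 7)^2 / 2)
  # brute-force oracle: scan all interior local maxima above threshold
  scan_oracle <- function(t, y, frac) {
    i <- 2:(length(y) - 1)
    loc <- i[y[i] >= y[i - 1] & y[i] >= y[i + 1]]
    loc <- loc[y[loc] >= frac * max(y)]
    c(t[loc[1]], y[loc[1]])
  }
  p <- first_peak(t, y, threshold_frac = 0.05)
  expect_equal(c(p$time, p$value), scan_oracle(t, y, 0.05))
  expect_equal(p$flag, "ok")
  expect_equal(p$time, 2, tolerance = 0.11)  # early bump qualifies at 5%
  # at a 50% threshold only the late bump qualifies
  p2 <- first_peak(t, y, threshold_frac = 0.5)
  expect_equal(c(p2$time, p2$value), scan_oracle(t, y, 0.5))
  expect_equal(p2$time, 7, tolerance = 0.11)
  # monotone increasing trace: terminal point, flagged
  p3 <- first_peak(t, t^2)
  expect_equal(p3$time, 10)
  expect_equal(p3$flag, "boundary_peak")
  # flat zero trace
  p4 <- first_peak(t, rep(0, length(t)))
  expect_equal(c(p4$time, p4$value), c(0, 0))
  expect_equal(p4$flag, "flat")
  expect_error(first_peak(numeric(0), numeric(0)), "empty")
})

test_that("peak_table is a pure function of traces and orders arrivals", {
  t <- seq(0, 5, by = 0.05)
  mk <- function(nm, t0, amp) data.frame(
    time_ms = t, monitor = nm,
    von_mises_kPa = amp * pmax(0, sin(pmax(0, t - t0))),
    max_principal_strain = 0.1 * amp * pmax(0, sin(pmax(0, t - t0))),
    max_principal_stress_kPa = amp * pmax(0, sin(pmax(0, t - t0))))
  tr <- rbind(mk("a", 0.5, 10), mk("b", 1.0, 8), mk("c", 2.0, 12))
  class(tr) <- c("monitor_traces", "data.frame")
  pk <- peak_table(tr)
  expect_equal(pk$monitor[order(pk$arrival_order)], c("a", "b", "c"))
  expect_equal(pk$max_stress_kPa, c(10, 8, 12), tolerance = 1e-3)
  # bitwise reproducible from a CSV round trip
  f <- tempfile(fileext = ".csv")
  write_traces(tr, f)
  pk2 <- peak_table(read_traces(f))
  expect_equal(pk, pk2, tolerance = 1e-12)
  unlink(f)
})
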