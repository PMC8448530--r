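# Tensor invariants, monitor-trace containers and peak extraction.

#' von Mises effective stress
#'
#' Second-deviatoric-invariant effective stress of a symmetric 2D stress
#' state plus an out-of-plane normal component.  In plane strain the
#' out-of-plane stress is `nu * (sxx + syy)` for an elastic material and the
#' constitutive value for a viscoelastic one; pass it via `szz` or let it be
#' derived from `nu`.
#'
#' @param sigma in-plane stress: length-3 vector `c(sxx, syy, sxy)` or a
#'   symmetric 2x2 matrix.
#' @param szz out-of-plane normal stress (default 0 unless `nu` is given).
#' @param nu if supplied (and `szz` is not), `szz = nu * (sxx + syy)`.
#' @return effective stress, same units as the input.
#' @export
von_mises <- function(sigma, szz = NULL, nu = NULL) {
  if (is.matrix(sigma)) {
    if (any(dim(sigma) != c(2, 2)) || abs(sigma[1, 2] - sigma[2, 1]) >
        1e-9 * max(1, max(abs(sigma))))
      stop("sigma must be a symmetric 2x2 matrix")
    sigma <- c(sigma[1, 1], sigma[2, 2], sigma[1, 2])
  }
  if (is.null(szz)) szz <- if (is.null(nu)) 0 else nu * (sigma[1] + sigma[2])
  sqrt(0.5 * ((sigma[1] - sigma[2])^2 + (sigma[2] - szz)^2 +
              (szz - sigma[1])^2) + 3 * sigma[3]^2)
}

#' Maximum principal value of a symmetric in-plane tensor
#'
#' Larger eigenvalue of the in-plane 2x2 tensor (for strain in plane strain
#' the out-of-plane normal strain is zero and not compared).
#'
#' @param a length-3 vector `c(axx, ayy, axy)` (tensor shear component) or a
#'   symmetric 2x2 matrix.
#' @export
max_principal <- function(a) {
  if (is.matrix(a)) {
    if (any(dim(a) != c(2, 2)) ||
        abs(a[1, 2] - a[2, 1]) > 1e-9 * max(1, max(abs(a))))
      stop("input must be a symmetric 2x2 matrix")
    a <- c(a[1, 1], a[2, 2], a[1, 2])
  }
  0.5 * (a[1] + a[2]) + sqrt(0.25 * (a[1] - a[2])^2 + a[3]^2)
}

#' First qualifying peak of a trace
#'
#' Earliest local maximum whose value reaches `threshold_frac` times the
#' global maximum; ties are broken by earliest time.  A trace that is still
#' rising at its end yields the terminal point flagged `"boundary_peak"`; an
#' all-zero trace yields `(0, 0)` flagged `"flat"`.
#'
#' @param times sample times (strictly increasing).
#' @param values sampled values (same length).
#' @param threshold_frac qualification threshold as a fraction of the global
#'   maximum, default 0.05.
#' @return list with `time`, `value` and `flag` (`"ok"`, `"boundary_peak"`,
#'   or `"flat"`).
#' @export
first_peak <- function(times, values, threshold_frac = 0.05) {
  n <- length(values)
  if (n == 0 || length(times) != n) stop("empty or mismatched trace")
  if (all(values == 0)) return(list(time = 0, value = 0, flag = "flat"))
  gmax <- max(values)
  thr <- threshold_frac * gmax
  cand <- integer(0)
  if (n >= 3) {
    i <- 2:(n - 1)
    loc <- values[i] >= values[i - 1] & values[i] >= values[i + 1] &
      (values[i] > values[i - 1] | values[i] > values[i + 1])
    cand <- i[loc]
  }
  boundary <- FALSE
  if (n >= 2 && values[n] > values[n - 1]) {
    cand <- c(cand, n)
  }
  cand <- cand[values[cand] >= thr]
  if (length(cand) == 0) {
    # monotone non-increasing tail or single sample: take the global max
    k <- which.max(values)
    flag <- if (k == n || k == 1) "boundary_peak" else "ok"
    return(list(time = times[k], value = values[k], flag = flag))
  }
  k <- cand[1]
  list(time = times[k], value = values[k],
       flag = if (k == n) "boundary_peak" else "ok")
}

#' Monitor traces container
#'
#' Long-format data.frame of monitor time histories with the reporting units
#' used throughout (time ms, stress kPa, strain dimensionless).
#'
#' @param times time vector, s.
#' @param mon_vm,mon_e1,mon_s1 monitor x time matrices from [run_explicit()]
#'   (Pa / dimensionless / Pa).
#' @return data.frame of class `monitor_traces` with columns `time_ms`,
#'   `monitor`, `von_mises_kPa`, `max_principal_strain`,
#'   `max_principal_stress_kPa`.
#' @export
monitor_traces <- function(times, mon_vm, mon_e1, mon_s1) {
  mons <- rownames(mon_vm)
  out <- do.call(rbind, lapply(seq_along(mons), function(i) {
    data.frame(time_ms = times * 1e3, monitor = mons[i],
               von_mises_kPa = mon_vm[i, ] * 1e-3,
               max_principal_strain = mon_e1[i, ],
               max_principal_stress_kPa = mon_s1[i, ] * 1e-3,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("monitor_traces", "data.frame")
  out
}

#' Peak table over all monitors
#'
#' One row per monitor: first qualifying peak of the effective-stress and
#' principal-strain traces, global maxima, the 5%-of-maximum arrival time,
#' and the arrival-order index (by first stress peak).
#'
#' @param traces a `monitor_traces` data.frame (or a `simulation_result`).
#' @param threshold_frac peak qualification threshold, see [first_peak()].
#' @return data.frame, one row per monitor.
#' @export
peak_table <- function(traces, threshold_frac = 0.05) {
  if (inherits(traces, "simulation_result")) traces <- traces$traces
  stopifnot(inherits(traces, "monitor_traces") || is.data.frame(traces))
  mons <- unique(traces$monitor)
  rows <- lapply(mons, function(mn) {
    tr <- traces[traces$monitor == mn, ]
    ps <- first_peak(tr$time_ms, tr$von_mises_kPa, threshold_frac)
    pe <- first_peak(tr$time_ms, tr$max_principal_strain, threshold_frac)
    smax <- max(tr$von_mises_kPa)
    arr <- if (smax > 0)
      tr$time_ms[which(tr$von_mises_kPa >= threshold_frac * smax)[1]]
    else NA_real_
    data.frame(monitor = mn,
               t_first_stress_ms = ps$time, first_stress_kPa = ps$value,
               stress_flag = ps$flag,
               t_first_strain_ms = pe$time, first_strain = pe$value,
               strain_flag = pe$flag,
               max_stress_kPa = smax,
               max_strain = max(tr$max_principal_strain),
               max_principal_stress_kPa = max(tr$max_principal_stress_kPa),
               t_arrival_ms = arr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$arrival_order <- rank(out$t_first_stress_ms, ties.method = "first")
  rownames(out) <- NULL
  out
}

#' Write / read monitor traces as CSV
#'
#' @param traces a `monitor_traces` data.frame.
#' @param path file path.
#' @export
write_traces <- function(traces, path) {
  write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("monitor_traces", "data.frame")
  out
}

#' Plot monitor traces
#'
#' Time histories of effective stress and maximum principal strain per
#' monitor (base graphics, two stacked panels).
#'
#' @param x a `monitor_traces` data.frame.
#' @param ... unused.
#' @export
plot.monitor_traces <- function(x, ...) {
  mons <- unique(x$monitor)
  cols <- grDevices::hcl.colors(max(3, length(mons)), "Dark 3")[seq_along(mons)]
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(NA, xlim = range(x$time_ms), ylim = range(x$von_mises_kPa),
       xlab = "time (ms)", ylab = "von Mises stress (kPa)")
  for (i in seq_along(mons)) {
    tr <- x[x$monitor == mons[i], ]
    graphics::lines(tr$time_ms, tr$von_mises_kPa, col = cols[i])
  }
  graphics::legend("topright", legend = mons, col = cols, lty = 1, cex = 0.7)
  plot(NA, xlim = range(x$time_ms), ylim = range(x$max_principal_strain),
       xlab = "time (ms)", ylab = "max principal strain (-)")
  for (i in seq_along(mons)) {
    tr <- x[x$monitor == mons[i], ]
    graphics::lines(tr$time_ms, tr$max_principal_strain, col = cols[i])
  }
  invisible(x)
}
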