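#' @export
plot.ot_trace <- function(x, downsample_to = 5000, ...) {
  n <- length(x$time)
  idx <- if (n > downsample_to) {
    unique(round(seq(1, n, length.out = downsample_to)))
  } else seq_len(n)
  plot(x$time[idx], x$force[idx], type = "l", xlab = "time (s)",
       ylab = "force (pN)", ...)
  if (!is.null(x$truth_bound)) {
    b <- x$truth_bound[idx]
    graphics::points(x$time[idx][b], x$force[idx][b], col = "steelblue",
                     pch = ".", cex = 2)
  }
  invisible(x)
}

#' @export
plot.state_assignment <- function(x, trace, ...) {
  plot(trace, col = "grey70", ...)
  graphics::lines(trace$time, x$levels$mean[x$path], col = "firebrick")
  graphics::abline(h = x$levels$mean, lty = 3, col = "grey40")
  invisible(x)
}

#' @export
plot.binding_rate_fit <- function(x, ...) {
  plot(x$points$force, x$points$k_off, log = "y", xlab = "force (pN)",
       ylab = expression(k[off] ~ (s^-1)), pch = 19, ...)
  if (!is.null(x$fit)) {
    f <- seq(0, max(x$points$force) * 1.05, length.out = 100)
    graphics::lines(f, predict(x, f), lty = 2)
  }
  invisible(x)
}

#' @export
plot.hill_fit <- function(x, concs = NULL, fractions = NULL, ...) {
  cgrid <- 10^seq(log10(max(x$kd / 100, 1e-3)), log10(x$kd * 100),
                  length.out = 200)
  plot(cgrid, predict(x, cgrid), type = "l", log = "x",
       xlab = "concentration (nM)", ylab = "fraction bound", ...)
  if (!is.null(concs)) graphics::points(concs, fractions, pch = 19)
  graphics::abline(v = x$kd, lty = 3)
  invisible(x)
}

#' @export
plot.melt_fit <- function(x, temps = NULL, signal = NULL, ...) {
  tgrid <- seq(min(x$derivative$temperature),
               max(x$derivative$temperature), length.out = 300)
  plot(tgrid, predict(x, tgrid), type = "l",
       xlab = expression(temperature ~ (degree * C)), ylab = "signal", ...)
  if (!is.null(temps)) graphics::points(temps, signal, pch = 1,
                                        col = "grey50")
  graphics::abline(v = c(x$tm1, x$tm2), lty = 3)
  invisible(x)
}

#' @export
plot.contour_gain_fit <- function(x, ...) {
  graphics::hist(x$gains, breaks = "FD", xlab = "contour-length gain (nm)",
                 main = sprintf("mean %.2f +/- %.2f nm", x$mean_gain,
                                x$sd_gain), ...)
  graphics::abline(v = x$mean_gain, lty = 2)
  invisible(x)
}
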