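#' Hill fit of a binding titration
#'
#' Least-squares fit of
#' \code{f(c) = f_min + (f_max - f_min) * c^n / (kd^n + c^n)} with
#' multi-start over K_D decades spanning the concentration range.
#'
#' @param concs concentrations, nM.
#' @param fraction_bound observed fraction bound.
#' @param fix_n optionally fix the Hill coefficient (e.g. 1).
#' @return object of class \code{hill_fit} with \code{kd} (nM),
#'   \code{hill_n}, \code{f_min}, \code{f_max}, per-parameter \code{ci}
#'   (95%, covariance-based), and \code{out_of_range} flag when the fitted
#'   K_D lies outside \code{[min(c>0)/10, 10*max(c)]}.
#' @examples
#' t <- simulate_titration(kd = 307, noise_sd = 0)
#' hill_fit(t$conc, t$fraction_bound)
#' @export
hill_fit <- function(concs, fraction_bound, fix_n = NULL) {
  stopifnot(length(concs) == length(fraction_bound))
  if (length(concs) < 5) stop("need at least 5 titration points")
  d <- data.frame(c = concs, f = fraction_bound)
  cpos <- concs[concs > 0]
  kd_grid <- 10^seq(log10(min(cpos) / 10), log10(max(cpos) * 10),
                    length.out = 9)
  best <- NULL
  for (kd0 in kd_grid) {
    st <- list(f_min = max(min(d$f), 0), f_max = min(max(d$f), 1.05),
               kd = kd0)
    if (is.null(fix_n)) st$n <- 1
    fml <- if (is.null(fix_n)) {
      f ~ f_min + (f_max - f_min) * c^n / (kd^n + c^n)
    } else {
      stats::as.formula(sprintf(
        "f ~ f_min + (f_max - f_min) * c^%g / (kd^%g + c^%g)",
        fix_n, fix_n, fix_n))
    }
    lower <- if (is.null(fix_n)) c(0, 0, 1e-6, 0.1) else c(0, 0, 1e-6)
    upper <- if (is.null(fix_n)) c(1, 1.05, Inf, 10) else c(1, 1.05, Inf)
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = d, start = st, lower = lower,
                        upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || stats::deviance(fit) < stats::deviance(best))) {
      best <- fit
    }
  }
  if (is.null(best)) stop("Hill fit failed from every start")
  cf <- stats::coef(best)
  se <- tryCatch(sqrt(diag(stats::vcov(best))), error = function(e)
    rep(NA_real_, length(cf)))
  ci <- cbind(cf - 1.96 * se, cf + 1.96 * se)
  colnames(ci) <- c("low", "high")
  kd <- unname(cf["kd"])
  oor <- kd < min(cpos) / 10 || kd > max(cpos) * 10
  if (oor) warning("fitted K_D ", signif(kd, 3),
                   " nM lies outside the concentration range: ",
                   "no transition in range")
  structure(list(kd = kd,
                 hill_n = if (is.null(fix_n)) unname(cf["n"]) else fix_n,
                 f_min = unname(cf["f_min"]), f_max = unname(cf["f_max"]),
                 ci = ci, out_of_range = oor, nls = best),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: K_D = %.4g nM, n = %.3g, f_min = %.3g, f_max = %.3g%s\n",
    x$kd, x$hill_n, x$f_min, x$f_max,
    if (x$out_of_range) "  [K_D outside titration range]" else ""))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(kd = object$kd, hill_n = object$hill_n, f_min = object$f_min,
    f_max = object$f_max)
}

#' @export
predict.hill_fit <- function(object, conc, ...) {
  with(object, f_min + (f_max - f_min) * conc^hill_n /
         (kd^hill_n + conc^hill_n))
}

#' Smoothed derivative of a melting curve
#'
#' Savitzky-Golay local-polynomial smoothing of dS/dT; the extrema of the
#' derivative locate the melting transitions and seed [melt_fit()].
#'
#' @param temps temperature grid, deg C (uniform).
#' @param signal melting signal.
#' @param window Savitzky-Golay window length (odd number of points).
#' @param degree polynomial degree.
#' @return list with \code{temperature}, \code{dS_dT} (smoothed) and
#'   \code{extrema} (temperatures of local minima of dS/dT, strongest
#'   first; transitions are descending so minima mark midpoints).
#' @export
melt_derivative <- function(temps, signal, window = 9, degree = 3) {
  stopifnot(length(temps) == length(signal))
  dT <- diff(temps)
  if (max(dT) - min(dT) > 1e-6 * mean(dT)) stop("temperature grid must be uniform")
  window <- min(window, length(temps) - (length(temps) + 1) %% 2)
  if (window %% 2 == 0) window <- window - 1
  ds <- signal::sgolayfilt(signal, p = degree, n = window, m = 1) / mean(dT)
  inner <- 2:(length(ds) - 1)
  is_min <- ds[inner] < ds[inner - 1] & ds[inner] <= ds[inner + 1]
  ext <- inner[is_min]
  ext <- ext[order(ds[ext])]  # most negative (strongest transition) first
  list(temperature = temps, dS_dT = ds, extrema = temps[ext])
}

#' Double-Boltzmann fit of a melting curve
#'
#' Fits the sum of two descending Boltzmann sigmoids plus a baseline,
#' initialized from the two strongest derivative extrema; the melting
#' temperatures are the sigmoid midpoints. If the data support only one
#' transition (second amplitude degenerate or fewer than two derivative
#' extrema), the fit falls back to a single Boltzmann and flags it.
#'
#' @param temps temperature grid, deg C (at least 20 points spanning at
#'   least 40 deg C).
#' @param signal melting signal.
#' @param window passed to [melt_derivative()].
#' @return object of class \code{melt_fit} with \code{tm1}, \code{tm2},
#'   \code{widths}, \code{amplitudes}, \code{baseline}, \code{ci} (95% on
#'   tm1/tm2), \code{single_transition} flag and \code{derivative}.
#' @export
melt_fit <- function(temps, signal, window = 9) {
  if (length(temps) < 20 || diff(range(temps)) < 40) {
    stop("need at least 20 points spanning at least 40 deg C")
  }
  der <- melt_derivative(temps, signal, window = window)
  ext <- der$extrema
  d <- data.frame(T = temps, s = signal)
  amp_tot <- max(signal) - min(signal)
  single_fit <- function() {
    tm0 <- if (length(ext)) ext[1] else stats::median(temps)
    minpack.lm::nlsLM(
      s ~ b + A1 / (1 + exp((T - tm1) / w1)), data = d,
      start = list(b = min(signal), A1 = amp_tot, tm1 = tm0, w1 = 2),
      lower = c(-Inf, 0, min(temps), 0.1),
      upper = c(Inf, Inf, max(temps), 30),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  }
  fit2 <- NULL
  if (length(ext) >= 2) {
    tms <- sort(ext[1:2])
    fit2 <- tryCatch(minpack.lm::nlsLM(
      s ~ b + A1 / (1 + exp((T - tm1) / w1)) +
        A2 / (1 + exp((T - tm2) / w2)),
      data = d,
      start = list(b = min(signal), A1 = amp_tot / 3,
                   A2 = 2 * amp_tot / 3, tm1 = tms[1], tm2 = tms[2],
                   w1 = 2, w2 = 2),
      lower = c(-Inf, 0, 0, min(temps), min(temps), 0.1, 0.1),
      upper = c(Inf, Inf, Inf, max(temps), max(temps), 30, 30),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
  }
  degenerate <- is.null(fit2)
  if (!degenerate) {
    cf <- stats::coef(fit2)
    if (cf["A2"] < 0.02 * amp_tot || cf["A1"] < 0.02 * amp_tot ||
        abs(cf["tm2"] - cf["tm1"]) < 1) {
      degenerate <- TRUE
    }
  }
  if (degenerate) {
    f1 <- single_fit()
    cf <- stats::coef(f1)
    se <- sqrt(diag(stats::vcov(f1)))
    return(structure(list(
      tm1 = unname(cf["tm1"]), tm2 = NA_real_,
      widths = unname(cf["w1"]), amplitudes = unname(cf["A1"]),
      baseline = unname(cf["b"]),
      ci = rbind(tm1 = cf["tm1"] + c(-1.96, 1.96) * se["tm1"]),
      single_transition = TRUE, derivative = der, nls = f1),
      class = "melt_fit"))
  }
  cf <- stats::coef(fit2)
  if (cf["tm1"] > cf["tm2"]) {  # enforce tm1 < tm2
    cf <- cf[c("b", "A2", "A1", "tm2", "tm1", "w2", "w1")]
    names(cf) <- c("b", "A1", "A2", "tm1", "tm2", "w1", "w2")
  }
  se <- tryCatch(sqrt(diag(stats::vcov(fit2))), error = function(e)
    stats::setNames(rep(NA_real_, 7), names(stats::coef(fit2))))
  structure(list(
    tm1 = unname(cf["tm1"]), tm2 = unname(cf["tm2"]),
    widths = unname(cf[c("w1", "w2")]),
    amplitudes = unname(cf[c("A1", "A2")]),
    baseline = unname(cf["b"]),
    ci = rbind(tm1 = cf["tm1"] + c(-1.96, 1.96) * se["tm1"],
               tm2 = cf["tm2"] + c(-1.96, 1.96) * se["tm2"]),
    single_transition = FALSE, derivative = der, nls = fit2),
    class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  if (x$single_transition) {
    cat(sprintf("Melting fit (single Boltzmann): Tm = %.2f C\n", x$tm1))
  } else {
    cat(sprintf(
      "Melting fit (double Boltzmann): Tm1 = %.2f C, Tm2 = %.2f C\n",
      x$tm1, x$tm2))
  }
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(tm1 = object$tm1, tm2 = object$tm2)
}

#' @export
predict.melt_fit <- function(object, temps, ...) {
  if (object$single_transition) {
    object$baseline + object$amplitudes /
      (1 + exp((temps - object$tm1) / object$widths))
  } else {
    double_boltzmann(temps, object$tm1, object$tm2,
                     object$amplitudes[1], object$amplitudes[2],
                     object$widths[1], object$widths[2], object$baseline)
  }
}

#' Hydrogen-bond scalar coupling from HNN-COSY intensities
#'
#' Quantifies the through-hydrogen-bond h2J(N,N) coupling of a base pair
#' from the cross (acceptor) to diagonal (donor) peak intensity ratio:
#' \code{|J| = atan(sqrt(|I_Na / I_Nd|)) / (2 * pi * delta)}, the standard
#' quantitative HNN-COSY inversion of \code{I_Na/I_Nd = -tan^2(2 pi J
#' delta)} (the acceptor peak is opposite in sign to the donor peak), with
#' \code{2*delta} the COSY transfer time. As the magnitude ratio grows the
#' coupling saturates at \code{1/(4*delta)}.
#'
#' @param donor_intensity donor (Nd) diagonal-peak intensities.
#' @param acceptor_intensity acceptor (Na) cross-peak intensities.
#' @param delta transfer half-delay, s (default 0.015, i.e. 30 ms transfer
#'   time).
#' @return data.frame of class \code{coupling_result} with \code{j_hz},
#'   \code{intensity_ratio} and \code{saturated} flag.
#' @examples
#' hnn_cosy_coupling(-1, 1, delta = 0.015)  # 8.33 Hz
#' @export
hnn_cosy_coupling <- function(donor_intensity, acceptor_intensity,
                              delta = 0.015) {
  stopifnot(delta > 0)
  if (any(donor_intensity == 0)) stop("donor intensity must be nonzero")
  ratio <- abs(acceptor_intensity / donor_intensity)
  j <- atan(sqrt(ratio)) / (2 * pi * delta)
  out <- data.frame(j_hz = j, intensity_ratio = ratio,
                    donor_intensity = donor_intensity,
                    acceptor_intensity = acceptor_intensity,
                    delta = delta,
                    saturated = !is.finite(ratio))
  out$j_hz[out$saturated] <- 1 / (4 * delta)
  class(out) <- c("coupling_result", "data.frame")
  out
}

#' Per-base-pair coupling changes between apo and complexed RNA
#'
#' Joins apo and complex coupling tables on a base-pair key and labels
#' each pair stabilized (coupling increased beyond \code{threshold}),
#' destabilized, or unchanged; keys present in only one table are
#' reported as not quantifiable.
#'
#' @param apo,complex data.frames with columns \code{key} and \code{j_hz}.
#' @param threshold label threshold on \code{delta_j}, Hz.
#' @return data.frame with \code{key}, \code{j_apo}, \code{j_complex},
#'   \code{delta_j} and \code{label}.
#' @export
coupling_delta <- function(apo, complex, threshold = 0.5) {
  keys <- union(apo$key, complex$key)
  out <- do.call(rbind, lapply(keys, function(k) {
    ja <- apo$j_hz[match(k, apo$key)]
    jc <- complex$j_hz[match(k, complex$key)]
    dj <- jc - ja
    lab <- if (is.na(dj)) "not_quantifiable"
    else if (dj > threshold) "stabilized"
    else if (dj < -threshold) "destabilized"
    else "unchanged"
    data.frame(key = k, j_apo = ja, j_complex = jc, delta_j = dj,
               label = lab, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
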