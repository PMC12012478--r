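#' Exponential maximum-likelihood rate from dwell durations
#'
#' MLE \code{k = 1/mean(durations)} with an exact 95% confidence interval
#' from the Gamma distribution of the summed dwell time. With a detection
#' dead time, the truncated MLE \code{k = 1/(mean - t_dead)} corrects the
#' bias of observing only dwells longer than \code{t_dead}.
#'
#' @param durations dwell durations, s (at least 5).
#' @param t_dead detection dead time, s.
#' @return object of class \code{rate_fit} with \code{rate} (1/s),
#'   \code{ci95}, \code{n_dwells}, \code{mean_dwell}, \code{model}.
#' @export
fit_exponential <- function(durations, t_dead = 0) {
  durations <- durations[is.finite(durations)]
  n <- length(durations)
  if (n < 5) stop("insufficient data: need at least 5 dwells, got ", n)
  m <- mean(durations) - t_dead
  if (m <= 0) stop("mean dwell does not exceed the dead time")
  k <- 1 / m
  # sum of n exponentials ~ Gamma(n, k): CI on k from the pivotal quantity
  ci <- stats::qgamma(c(0.025, 0.975), shape = n) / (n * m)
  structure(list(rate = k, ci95 = ci, n_dwells = n,
                 mean_dwell = m + t_dead, t_dead = t_dead,
                 model = "single"),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  if (identical(x$model, "single")) {
    cat(sprintf("Exponential rate: %.4g 1/s (95%% CI %.4g-%.4g, n = %d)\n",
                x$rate, x$ci95[1], x$ci95[2], x$n_dwells))
  } else {
    cat(sprintf(
      "Exponential mixture: k1 = %.4g, k2 = %.4g 1/s (w1 = %.2f, n = %d)\n",
      x$components$rate[1], x$components$rate[2],
      x$components$weight[1], x$n_dwells))
  }
  invisible(x)
}

#' @export
coef.rate_fit <- function(object, ...) {
  if (identical(object$model, "single")) c(rate = object$rate)
  else c(k1 = object$components$rate[1], k2 = object$components$rate[2],
         w1 = object$components$weight[1])
}

#' Test dwell durations for a multi-exponential distribution
#'
#' Fits one- and two-component exponential mixtures (EM for the mixture)
#' and selects by BIC; the mixture is preferred only when
#' \code{BIC(single) - BIC(mixture) > 6}, a conservative evidence
#' threshold. Multi-exponential lifetimes indicate that an apparent force
#' level hides more than one underlying state.
#'
#' @param durations dwell durations, s (at least 50).
#' @param delta_bic_required BIC margin required to prefer the mixture.
#' @return a \code{rate_fit} with \code{model} "single" or "mixture";
#'   mixtures carry \code{components} (rates, weights) and both BICs.
#' @export
detect_multiexponential <- function(durations, delta_bic_required = 6) {
  durations <- durations[is.finite(durations) & durations > 0]
  n <- length(durations)
  if (n < 50) stop("need at least 50 dwells for mixture detection, got ", n)
  k1 <- 1 / mean(durations)
  ll1 <- sum(stats::dexp(durations, k1, log = TRUE))
  bic1 <- -2 * ll1 + log(n)
  # 2-component EM, initialized by splitting at the median
  lo <- durations[durations <= stats::median(durations)]
  hi <- durations[durations > stats::median(durations)]
  ka <- 1 / mean(lo); kb <- 1 / mean(hi); w <- 0.5
  ll2 <- -Inf
  for (it in 1:500) {
    da <- w * stats::dexp(durations, ka)
    db <- (1 - w) * stats::dexp(durations, kb)
    r <- da / (da + db)
    w <- mean(r)
    ka <- sum(r) / sum(r * durations)
    kb <- sum(1 - r) / sum((1 - r) * durations)
    ll_new <- sum(log(da + db))
    if (is.finite(ll2) && abs(ll_new - ll2) < 1e-10 * abs(ll2)) break
    ll2 <- ll_new
  }
  bic2 <- -2 * ll2 + 3 * log(n)
  if (bic1 - bic2 > delta_bic_required) {
    ord <- order(c(ka, kb))
    structure(list(rate = c(ka, kb)[ord][1], n_dwells = n,
                   ci95 = c(NA_real_, NA_real_),
                   model = "mixture",
                   components = data.frame(
                     rate = c(ka, kb)[ord],
                     weight = c(w, 1 - w)[ord]),
                   bic_single = bic1, bic_mixture = bic2),
              class = "rate_fit")
  } else {
    f <- fit_exponential(durations)
    f$bic_single <- bic1
    f$bic_mixture <- bic2
    f
  }
}

#' Transition rates between two conformational states
#'
#' Estimates \code{k_a->b} as the number of observed a->b transitions
#' divided by the total time spent in a (and vice versa), optionally
#' restricted to protein-bound or unbound phases. Confidence intervals are
#' exact Poisson intervals on the transition counts.
#'
#' @param dwells a \code{dwell_table}, optionally with a \code{phase}
#'   column from [segment_bound_phases()].
#' @param state_a,state_b state indices.
#' @param phase_filter "all", "bound" or "unbound".
#' @return data.frame with one row per direction: \code{from}, \code{to},
#'   \code{rate}, \code{n_transitions}, \code{time_in_from},
#'   \code{ci_low}, \code{ci_high}.
#' @export
conformational_rates <- function(dwells, state_a, state_b,
                                 phase_filter = c("all", "bound",
                                                  "unbound")) {
  phase_filter <- match.arg(phase_filter)
  seg_id <- rep(1, nrow(dwells))
  if (phase_filter != "all") {
    if (is.null(dwells$phase)) stop("dwells carry no phase labels")
    keep <- dwells$phase == phase_filter
    # transitions are only counted within contiguous kept segments
    seg_id <- cumsum(c(TRUE, diff(keep) != 0))[keep]
    dwells <- dwells[keep, , drop = FALSE]
  }
  if (!state_a %in% dwells$state || !state_b %in% dwells$state) {
    stop("both states must be present in the filtered dwells")
  }
  one_dir <- function(a, b) {
    n_tr <- 0L
    fr <- dwells$state
    same_seg <- seg_id[-length(seg_id)] == seg_id[-1]
    if (nrow(dwells) > 1) {
      n_tr <- sum(fr[-length(fr)] == a & fr[-1] == b & same_seg)
    }
    t_a <- sum(dwells$duration[fr == a])
    rate <- n_tr / t_a
    ci <- c(if (n_tr > 0) stats::qgamma(0.025, n_tr) / t_a else 0,
            stats::qgamma(0.975, n_tr + 1) / t_a)
    data.frame(from = a, to = b, rate = rate, n_transitions = n_tr,
               time_in_from = t_a, ci_low = ci[1], ci_high = ci[2])
  }
  rbind(one_dir(state_a, state_b), one_dir(state_b, state_a))
}

#' Protein off-rates versus force, with zero-force extrapolation
#'
#' One rate point per group (typically one passive-mode step/trace):
#' \code{k_off = (n-1)/(n*(mean bound lifetime - t_dead))} - the
#' dead-time-truncated exponential MLE with the exact Gamma small-sample
#' bias correction (\code{E[1/mean] = k*n/(n-1)}) - plotted against the
#' mean bound-state force, then a weighted least-squares fit of
#' \code{k_off(F) = k_ind + k0 * exp(F * dx / kT)} - a force-independent
#' plus a Bell force-dependent contribution. The zero-force off-rate is
#' \code{k_ind + k0}. Weights are inverse-variance from the per-group event
#' counts (\code{var(k) ~ k^2/n}).
#'
#' @param bound_events data.frame with columns \code{group},
#'   \code{duration} (s) and \code{force} (pN) - one row per bound event.
#' @param t_dead detection dead time (the minimum bound duration used in
#'   segmentation), s.
#' @param kT thermal energy, pN.nm.
#' @param pure_bell set \code{TRUE} to force \code{k_ind = 0}.
#' @param min_events groups with fewer bound events than this are dropped
#'   from the force fit (their lifetimes are too noisy to weight sanely).
#' @return object of class \code{binding_rate_fit} with \code{points}
#'   (per-group force, rate, n), \code{fit} (k_ind, k0, dx),
#'   \code{k_off_zero_force} and its \code{ci95}; when fewer than 3 force
#'   points are available the fit is refused and only points are returned.
#' @export
protein_off_rates <- function(bound_events, t_dead = 0, kT = kT_25C_pNnm,
                              pure_bell = FALSE, min_events = 3) {
  stopifnot(all(c("group", "duration", "force") %in% names(bound_events)))
  pts <- do.call(rbind, lapply(split(bound_events, bound_events$group),
                               function(d) {
    m <- mean(d$duration) - t_dead
    n <- nrow(d)
    bias_corr <- if (n > 1) (n - 1) / n else 1
    data.frame(group = d$group[1], force = mean(d$force),
               k_off = bias_corr / max(m, 1e-9), n = n)
  }))
  rownames(pts) <- NULL
  degenerate <- pts$n < min_events | pts$k_off >= 1e8
  if (any(degenerate)) {
    warning(sum(degenerate), " group(s) dropped from the force fit ",
            "(fewer than ", min_events, " events or degenerate lifetime)")
    pts <- pts[!degenerate, , drop = FALSE]
  }
  out <- list(points = pts, fit = NULL, k_off_zero_force = NA_real_,
              ci95 = c(NA_real_, NA_real_), kT = kT)
  if (nrow(pts) < 3) {
    warning("fewer than 3 force points: off-rate force fit refused")
    class(out) <- "binding_rate_fit"
    return(out)
  }
  w <- pts$n / pts$k_off^2
  fits <- list()
  for (dx0 in c(0.2, 0.5, 1, 2, 4)) {
    st <- if (pure_bell) {
      list(k0 = max(min(pts$k_off) / exp(min(pts$force) * dx0 / kT), 1e-8),
           dx = dx0)
    } else {
      list(k_ind = 0.5 * min(pts$k_off),
           k0 = max(0.5 * min(pts$k_off) /
                      exp(min(pts$force) * dx0 / kT), 1e-10),
           dx = dx0)
    }
    f <- tryCatch({
      if (pure_bell) {
        minpack.lm::nlsLM(k_off ~ k0 * exp(force * dx / kT),
                          data = cbind(pts, kT = kT), start = st,
                          weights = w,
                          lower = c(0, 0), upper = c(Inf, 20),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(k_off ~ k_ind + k0 * exp(force * dx / kT),
                          data = cbind(pts, kT = kT), start = st,
                          weights = w,
                          lower = c(0, 0, 0), upper = c(Inf, Inf, 20),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }
  fit_kind <- if (pure_bell) "bell" else "two_contribution"
  if (!length(fits) && !pure_bell) {
    # fall back to the pure-Bell form (one parameter fewer)
    for (dx0 in c(0.2, 0.5, 1, 2, 4)) {
      f <- tryCatch(minpack.lm::nlsLM(
        k_off ~ k0 * exp(force * dx / kT), data = cbind(pts, kT = kT),
        start = list(k0 = max(min(pts$k_off) /
                                exp(min(pts$force) * dx0 / kT), 1e-8),
                     dx = dx0),
        weights = w, lower = c(0, 0), upper = c(Inf, 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f)) fits[[length(fits) + 1]] <- f
    }
    if (length(fits)) fit_kind <- "bell"
  }
  if (!length(fits)) {
    # last resort: force-independent weighted mean (dx = 0)
    warning("off-rate force fit did not converge; ",
            "using the force-independent weighted mean")
    kbar <- sum(w * pts$k_off) / sum(w)
    se <- sqrt(sum(w^2 * pts$k_off^2 / pts$n)) / sum(w)
    out$fit <- list(k_ind = kbar, k0 = 0, dx = 0)
    out$fit_kind <- "constant"
    out$k_off_zero_force <- kbar
    out$se_zero_force <- se
    out$ci95 <- kbar + c(-1.96, 1.96) * se
    class(out) <- "binding_rate_fit"
    return(out)
  }
  best <- fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]
  cf <- stats::coef(best)
  if (length(cf) == 2) cf <- c(k_ind = 0, cf)
  k0f <- unname(cf["k_ind"] + cf["k0"])
  # delta-method CI on k_off(0) = k_ind + k0
  se <- tryCatch({
    V <- stats::vcov(best)
    g <- if (length(stats::coef(best)) == 2) c(1, 0) else c(1, 1, 0)
    sqrt(drop(t(g) %*% V %*% g))
  }, error = function(e) NA_real_)
  out$fit <- as.list(cf)
  out$fit_kind <- fit_kind
  out$nls <- best
  out$k_off_zero_force <- k0f
  out$se_zero_force <- se
  out$ci95 <- k0f + c(-1.96, 1.96) * se
  class(out) <- "binding_rate_fit"
  out
}

#' @export
print.binding_rate_fit <- function(x, ...) {
  cat("Protein off-rate vs force\n")
  print(round(x$points, 4), row.names = FALSE)
  if (!is.null(x$fit)) {
    cat(sprintf(
      "  fit: k_ind = %.4g, k0 = %.4g 1/s, dx = %.3g nm\n",
      x$fit$k_ind, x$fit$k0, x$fit$dx))
    cat(sprintf("  k_off(F=0) = %.4g 1/s (95%% CI %.4g-%.4g)\n",
                x$k_off_zero_force, x$ci95[1], x$ci95[2]))
  }
  invisible(x)
}

#' @export
coef.binding_rate_fit <- function(object, ...) unlist(object$fit)

#' @export
predict.binding_rate_fit <- function(object, force, ...) {
  cf <- object$fit
  cf$k_ind + cf$k0 * exp(force * cf$dx / object$kT)
}

#' Protein on-rates corrected for the folding distribution
#'
#' The observed binding rate at a force is \code{k_obs = 1/(mean unbound
#' phase duration)}; because the protein binds only the folded, competent
#' conformation, the chemically meaningful rate is
#' \code{k_bind = k_obs / (occupancy * p_detect)}, where \code{occupancy}
#' is the fraction of unbound time spent in the competent state and
#' \code{p_detect} corrects for bound events shorter than the detection
#' threshold (\code{p_detect = exp(-k_off * t_dead)} when an off-rate is
#' supplied). A force-independent (constant) weighted fit across groups
#' gives the binding rate, and division by the protein concentration the
#' per-molar association rate.
#'
#' @param unbound_events data.frame with columns \code{group},
#'   \code{duration} (s), \code{force} (pN) and \code{occupancy} (fraction
#'   of unbound time in the competent state for that group) - one row per
#'   unbound phase. An optional logical \code{complete} column marks
#'   phases that ended in a binding event (censored first/last phases get
#'   \code{FALSE}); the observed rate is the exposure estimator
#'   \code{k_obs = n_complete / total unbound time}, which is unbiased
#'   under censoring.
#' @param protein_conc protein concentration, M.
#' @param t_dead bound-event detection threshold, s (for the missed-event
#'   correction).
#' @param k_off_of_force optional function \code{force -> k_off} used for
#'   the missed-event correction.
#' @param t_flank expected unbound time absorbed into each detected bound
#'   phase, s. A bound phase is delimited by state dwells, so it contains
#'   the pre-binding and post-unbinding portions of the flanking
#'   competent-state dwells; by memorylessness each contributes one mean
#'   unbound competent-state dwell, so \code{t_flank = 2 * (mean unbound
#'   competent-state dwell)} restores the exposure they remove.
#' @return object of class \code{on_rate_fit} with \code{points},
#'   \code{k_bind} (weighted mean, 1/s), \code{k_on} (1/M/s) and
#'   \code{ci95} on \code{k_on}.
#' @export
protein_on_rates <- function(unbound_events, protein_conc, t_dead = 0,
                             k_off_of_force = NULL, t_flank = 0) {
  stopifnot(all(c("group", "duration", "force", "occupancy") %in%
                  names(unbound_events)))
  if (any(unbound_events$occupancy <= 0)) {
    stop("competent-state occupancy must be positive")
  }
  if (is.null(unbound_events$complete)) unbound_events$complete <- TRUE
  pts <- do.call(rbind, lapply(split(unbound_events, unbound_events$group),
                               function(d) {
    k_obs <- sum(d$complete) / (sum(d$duration) +
                                sum(d$complete) * t_flank)
    occ <- mean(d$occupancy)
    p_det <- if (!is.null(k_off_of_force) && t_dead > 0) {
      exp(-k_off_of_force(mean(d$force)) * t_dead)
    } else 1
    data.frame(group = d$group[1], force = mean(d$force), k_obs = k_obs,
               occupancy = occ, p_detect = p_det,
               k_bind = k_obs / (occ * p_det), n = sum(d$complete))
  }))
  rownames(pts) <- NULL
  # pooled Poisson MLE: events over competent-state-corrected exposure
  exposure <- vapply(split(unbound_events, unbound_events$group),
                     function(d) {
    occ <- mean(d$occupancy)
    p_det <- if (!is.null(k_off_of_force) && t_dead > 0) {
      exp(-k_off_of_force(mean(d$force)) * t_dead)
    } else 1
    (sum(d$duration) + sum(d$complete) * t_flank) * occ * p_det
  }, numeric(1))
  n_tot <- sum(pts$n)
  k_bind <- n_tot / sum(exposure)
  se <- sqrt(n_tot) / sum(exposure)
  k_on <- k_bind / protein_conc
  structure(list(points = pts, k_bind = k_bind, se_bind = se,
                 k_on = k_on,
                 ci95 = (k_bind + c(-1.96, 1.96) * se) / protein_conc,
                 protein_conc = protein_conc),
            class = "on_rate_fit")
}

#' @export
print.on_rate_fit <- function(x, ...) {
  cat("Protein on-rate (force-independent constant fit)\n")
  print(round(x$points, 4), row.names = FALSE)
  cat(sprintf("  k_bind = %.4g 1/s at %.3g M -> k_on = %.4g 1/M/s\n",
              x$k_bind, x$protein_conc, x$k_on))
  invisible(x)
}

#' Zero-force equilibrium dissociation constant
#'
#' \code{K_D = k_off(F=0) / k_on}, with the relative uncertainties of both
#' rates propagated in quadrature.
#'
#' @param off_fit a \code{binding_rate_fit} from [protein_off_rates()].
#' @param on_fit an \code{on_rate_fit} from [protein_on_rates()].
#' @return list with \code{kd} (M), \code{ci95} and the two rates.
#' @export
compute_kd <- function(off_fit, on_fit) {
  if (is.na(off_fit$k_off_zero_force)) {
    stop("off-rate fit not available")
  }
  kd <- off_fit$k_off_zero_force / on_fit$k_on
  rel_off <- off_fit$se_zero_force / off_fit$k_off_zero_force
  rel_on <- on_fit$se_bind / on_fit$k_bind
  rel <- sqrt(sum(c(rel_off, rel_on)^2, na.rm = TRUE))
  structure(list(kd = kd, ci95 = kd * c(max(1 - 1.96 * rel, 0),
                                        1 + 1.96 * rel),
                 k_off_zero_force = off_fit$k_off_zero_force,
                 k_on = on_fit$k_on),
            class = "kd_result")
}

#' @export
print.kd_result <- function(x, ...) {
  cat(sprintf(
    "K_D(F=0) = %.4g M (%.3g nM), 95%% CI %.3g-%.3g nM\n  k_off(0) = %.4g 1/s, k_on = %.4g 1/M/s\n",
    x$kd, x$kd * 1e9, x$ci95[1] * 1e9, x$ci95[2] * 1e9,
    x$k_off_zero_force, x$k_on))
  invisible(x)
}
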