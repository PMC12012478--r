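#' Full zero-force K_D recovery experiment
#'
#' Runs the complete single-molecule binding pipeline for one condition:
#' simulate passive-mode traces with protein binding at several trap
#' separations (one per target force), assign states by HMM, extract
#' dwells, segment bound/unbound phases by the stabilized-state criterion,
#' estimate per-trace off-rates and pooled on-rates with dead-time,
#' flanking-dwell and missed-event corrections, fit the off-rate force
#' dependence, and combine into the zero-force dissociation constant.
#'
#' @param kd_nM ground-truth zero-force K_D handed to
#'   [roq_binding_scheme()], nM.
#' @param k_on,protein_conc association rate (1/M/s) and concentration (M)
#'   of the condition.
#' @param forces target bound-state forces, pN (one trap separation each).
#' @param n_traces passive-mode traces (steps) per force.
#' @param events_per_trace expected bound events per trace; sets the
#'   simulated duration from the condition's own rates.
#' @param min_duration bound-phase detection threshold, s (also the dead
#'   time of the corrections).
#' @param noise_sd force noise, pN.
#' @param sampling_hz,downsample_factor acquisition emulation.
#' @param seed RNG seed; each trace uses an offset sub-seed.
#' @param model an [elastic_model()].
#' @return list with \code{kd} (a \code{kd_result}), \code{off}
#'   (\code{binding_rate_fit}), \code{on} (\code{on_rate_fit}),
#'   \code{bound_events}, \code{n_events}, \code{scheme}.
#' @export
kd_recovery_experiment <- function(kd_nM, k_on = 2e7, protein_conc = 30e-9,
                                   forces = c(4, 8, 12), n_traces = 2,
                                   events_per_trace = 5.5,
                                   min_duration = 0.5, noise_sd = 0.35,
                                   sampling_hz = 3000,
                                   downsample_factor = 3L, seed = 1,
                                   model = elastic_model()) {
  scheme <- roq_binding_scheme(kd_nM, k_on = k_on,
                               protein_conc = protein_conc,
                               k_unfold = 20, k_fold = 80)
  k_off0 <- kd_nM * 1e-9 * k_on
  b <- scheme$binding
  bound <- NULL
  unbound <- NULL
  flanks <- numeric(0)
  g <- 0
  for (i in seq_along(forces)) {
    f_target <- forces[i]
    D <- construct_extension(f_target, model, 0, 1) +
      f_target / model$trap_stiffness
    koffF <- b$k_off_force_independent +
      b$k_off0 * exp(f_target * b$dx_off / model$kT)
    duration <- events_per_trace *
      (1 / koffF + 1 / (protein_conc * k_on * 0.8))
    for (j in seq_len(n_traces)) {
      g <- g + 1
      tr <- simulate_binding_trace(scheme, model, D, duration,
                                   noise_sd = noise_sd,
                                   seed = seed * 1000 + g,
                                   sampling_hz = sampling_hz,
                                   downsample_factor = downsample_factor)
      a <- fit_hmm(tr, n_states = 2)
      dw <- extract_dwells(a, tr, min_dwell = 3)
      dw <- segment_bound_phases(dw, list(state = 1,
                                          min_duration = min_duration))
      ph <- attr(dw, "phases")
      bd <- dw[dw$phase == "bound" & dw$state == 1, , drop = FALSE]
      if (nrow(bd) < 2) next
      bound <- rbind(bound, data.frame(group = g, duration = bd$duration,
                                       force = bd$mean_force))
      iu <- which(ph$type == "unbound")
      if (length(iu)) {
        unbound <- rbind(unbound, data.frame(
          group = g, duration = ph$duration[iu],
          force = mean(bd$mean_force),
          occupancy = sum(dw$duration[dw$phase == "unbound" &
                                        dw$state == 1]) /
            sum(dw$duration[dw$phase == "unbound"]),
          complete = iu < nrow(ph)))
      }
      flanks <- c(flanks, 2 * mean(dw$duration[dw$phase == "unbound" &
                                                 dw$state == 1]))
    }
  }
  if (is.null(bound) || is.null(unbound)) {
    stop("no usable bound/unbound phases detected in any trace")
  }
  off <- suppressWarnings(protein_off_rates(bound, t_dead = min_duration,
                                            kT = model$kT))
  kfun <- if (!is.null(off$fit)) function(f) stats::predict(off, f)
  on_fit <- protein_on_rates(unbound, protein_conc = protein_conc,
                             t_dead = min_duration, k_off_of_force = kfun,
                             t_flank = mean(flanks, na.rm = TRUE))
  list(kd = compute_kd(off, on_fit), off = off, on = on_fit,
       bound_events = bound, n_events = nrow(bound), scheme = scheme)
}

#' Protein-induced population-shift experiment
#'
#' Runs the full pipeline behind a bound/unbound free-energy comparison: a
#' passive-mode trace of the I1/I3/U network with conformational-selection
#' binding is simulated, HMM-assigned (3 states), segmented into bound and
#' unbound phases by the stabilized-I3 criterion, and the population ratio
#' I1:I3 of the two phases is converted to the protein-induced
#' destabilization of the more-folded state I1 by [delta_delta_G()].
#'
#' @param ddG_kcal ground-truth destabilization written into the fixture:
#'   while bound, I3 -> I1 refolding is slowed by
#'   \code{exp(ddG_kcal / 0.592)}.
#' @param protein_conc protein concentration, M. The default (2 nM) puts
#'   roughly half the trace in each phase, which maximizes the number of
#'   I1 excursions observed per simulated second in both phases.
#' @param duration simulated time, s.
#' @param min_duration bound-anchor threshold on I3 dwells, s.
#' @param n_boot bootstrap resamples for the confidence interval.
#' @param seed RNG seed.
#' @return list with \code{ddG} (from [delta_delta_G()]), the
#'   ground truth, the dwell table and the assignment.
#' @export
ddG_recovery_experiment <- function(ddG_kcal = 1.3, protein_conc = 2e-9,
                                    duration = 1200,
                                    min_duration = 1.2, n_boot = 1000,
                                    seed = 1) {
  p <- otfold_preset("ADE_extROQ_binding")
  p$scheme$binding$slowed_while_bound$factor <- exp(ddG_kcal / 0.592)
  p$scheme$binding$protein_conc <- protein_conc
  tr <- simulate_binding_trace(p$scheme, p$model, p$trap_separation,
                               duration, noise_sd = p$noise_sd,
                               seed = seed,
                               sampling_hz = p$sampling_hz,
                               downsample_factor = p$downsample_factor)
  a <- fit_hmm(tr, n_states = 3)
  dw <- extract_dwells(a, tr, min_dwell = 3)
  # levels descending: 1 = I1 (most folded), 2 = I3, 3 = U
  dw <- segment_bound_phases(dw, list(state = 2,
                                      min_duration = min_duration,
                                      allowed_states = 1))
  dd <- delta_delta_G(dw[dw$phase == "bound", ],
                      dw[dw$phase == "unbound", ],
                      state_hi = 1, state_lo = 2, kT = p$model$kT,
                      n_boot = n_boot, seed = seed)
  list(ddG = dd, truth_kcal = ddG_kcal, dwells = dw, assignment = a)
}
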