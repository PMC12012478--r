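#' Free-energy difference between two states at the measurement force
#'
#' Boltzmann inversion of the total occupancy times:
#' \code{dG = -kT * ln(T_j / T_i)}, reported in kcal/mol. Occupancy time,
#' not dwell counts, defines populations (robust to missed events).
#' Positive means state j is higher in free energy than state i at the
#' trap position.
#'
#' @param dwells a \code{dwell_table}.
#' @param state_i,state_j state indices (i is the reference, typically the
#'   more folded state).
#' @param kT thermal energy, pN.nm.
#' @return list with \code{dG_kcal}, the occupancy times and an
#'   \code{infinite} flag when one state has zero occupancy.
#' @export
population_dG <- function(dwells, state_i, state_j, kT = kT_25C_pNnm) {
  t_i <- sum(dwells$duration[dwells$state == state_i])
  t_j <- sum(dwells$duration[dwells$state == state_j])
  if (t_i == 0 && t_j == 0) stop("neither state is occupied")
  dg <- -kT * log(t_j / t_i)
  list(dG_kcal = pNnm_to_kcalmol(dg), t_i = t_i, t_j = t_j,
       infinite = !is.finite(dg))
}

#' Extrapolate a free-energy difference to zero force
#'
#' Removes the mechanical free energy stored in the stretched construct
#' from a population free-energy difference measured at the trap position:
#' \code{dG0 = dG_at_force - (G_mech(j) - G_mech(i))}, where
#' \code{G_mech(s)} is the stretching free energy of the released ssRNA at
#' the state's force, plus that of the handles, plus the trap potential
#' \code{F^2/(2 k_trap)}. Positive dG0 means the more unfolded state j is
#' higher in folding free energy.
#'
#' @param dG_at_force population free-energy difference i -> j, kcal/mol.
#' @param model an [elastic_model()].
#' @param n_nt_i,n_nt_j released nucleotides in states i and j.
#' @param F_i,F_j per-state equilibrium forces (from the assignment
#'   levels), pN.
#' @param trap_separation optional trap separation, nm; when given, the
#'   measured forces are checked against the passive-force prediction and
#'   a deviation above 1 pN raises a warning.
#' @return zero-force free-energy difference, kcal/mol.
#' @export
zero_force_dG <- function(dG_at_force, model, n_nt_i, n_nt_j, F_i, F_j,
                          trap_separation = NULL) {
  if (!is.null(trap_separation)) {
    for (s in list(c(n_nt_i, F_i), c(n_nt_j, F_j))) {
      pred <- passive_force(trap_separation, model, s[1])
      if (abs(pred - s[2]) > 1) {
        warning(sprintf(
          "measured force %.2f pN deviates > 1 pN from the passive-force prediction %.2f pN",
          s[2], pred))
      }
    }
  }
  g_i <- state_mechanical_energy(F_i, model, n_nt_i)
  g_j <- state_mechanical_energy(F_j, model, n_nt_j)
  dG_at_force - pNnm_to_kcalmol(g_j - g_i)
}

#' Pairwise state free energies from an assigned passive-mode trace
#'
#' Convenience wrapper: population free energies for every state pair from
#' the dwell table, extrapolated to zero force with the per-state levels.
#'
#' @param dwells a \code{dwell_table}.
#' @param assignment the \code{state_assignment} providing force levels.
#' @param model an [elastic_model()].
#' @param n_nt_of_state integer vector mapping state index to released
#'   nucleotides.
#' @param reference_state index of the reference state (default 1, most
#'   folded).
#' @return data.frame of class \code{energy_result}: one row per pair with
#'   \code{dG_at_force_kcal} and \code{dG_zero_force_kcal}.
#' @export
state_free_energies <- function(dwells, assignment, model, n_nt_of_state,
                                reference_state = 1) {
  K <- assignment$n_states
  stopifnot(length(n_nt_of_state) == K)
  lev <- assignment$levels$mean
  pairs <- utils::combn(K, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    pd <- population_dG(dwells, i, j, kT = model$kT)
    data.frame(state_i = i, state_j = j,
               dG_at_force_kcal = pd$dG_kcal,
               dG_zero_force_kcal = zero_force_dG(
                 pd$dG_kcal, model, n_nt_of_state[i], n_nt_of_state[j],
                 lev[i], lev[j]))
  }))
  attr(out, "reference_state") <- reference_state
  attr(out, "kT_used") <- model$kT
  class(out) <- c("energy_result", "data.frame")
  out
}

#' Protein-induced population shift between two states
#'
#' Compares the population ratio of a more-folded state to a less-folded
#' state between unbound and bound phases:
#' \code{ddG = kT * ln[(T_hi/T_lo)_unbound / (T_hi/T_lo)_bound]}.
#' Positive means the protein destabilizes the more-folded state. The
#' confidence interval is a seeded bootstrap over dwells within each
#' phase. Bound and unbound populations should come from the same trap
#' separation; a mean force differing by more than 0.5 pN between phases
#' raises a warning (the force shift itself biases the comparison).
#'
#' @param dwells_bound,dwells_unbound \code{dwell_table}s (or subsets of
#'   one table) for the two phases.
#' @param state_hi index of the more folded state.
#' @param state_lo index of the less folded state.
#' @param kT thermal energy, pN.nm.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{ddG_kcal}, \code{ci95} and the two ratios.
#' @export
delta_delta_G <- function(dwells_bound, dwells_unbound, state_hi, state_lo,
                          kT = kT_25C_pNnm, n_boot = 1000, seed = 1) {
  for (ph in list(bound = dwells_bound, unbound = dwells_unbound)) {
    if (!state_hi %in% ph$state || !state_lo %in% ph$state) {
      stop("state ", if (!state_hi %in% ph$state) state_hi else state_lo,
           " missing from the ",
           if (identical(ph, dwells_bound)) "bound" else "unbound",
           " phase")
    }
  }
  fb <- mean(dwells_bound$mean_force[dwells_bound$state %in%
                                       c(state_hi, state_lo)])
  fu <- mean(dwells_unbound$mean_force[dwells_unbound$state %in%
                                         c(state_hi, state_lo)])
  if (is.finite(fb) && is.finite(fu) && abs(fb - fu) > 0.5) {
    warning(sprintf(
      "mean phase forces differ by %.2f pN; populations are compared at different loads",
      abs(fb - fu)))
  }
  ratio <- function(d) {
    sum(d$duration[d$state == state_hi]) /
      sum(d$duration[d$state == state_lo])
  }
  r_b <- ratio(dwells_bound); r_u <- ratio(dwells_unbound)
  ddg <- pNnm_to_kcalmol(kT * log(r_u / r_b))
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    rb <- ratio(dwells_bound[sample.int(nrow(dwells_bound),
                                        replace = TRUE), ])
    ru <- ratio(dwells_unbound[sample.int(nrow(dwells_unbound),
                                          replace = TRUE), ])
    pNnm_to_kcalmol(kT * log(ru / rb))
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  list(ddG_kcal = ddg,
       ci95 = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
       ratio_bound = r_b, ratio_unbound = r_u, n_boot_valid = length(boot))
}
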