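#' Built-in synthetic fixtures
#'
#' Ready-made study conditions used throughout the package's tests and
#' examples. Each preset bundles a kinetic scheme, the elastic model, the
#' trap separation and the noise level of the emulated measurement:
#'
#' \describe{
#'   \item{CDE_two_state}{a 15-nt triloop hairpin hopping between folded
#'     and unfolded with Bell force-dependent rates; its equilibrium force
#'     sits near 11.5 pN. Suited to constant-velocity cycles and two-state
#'     passive traces.}
#'   \item{ADE_six_state}{the six-state folding network of a 52-nt
#'     hairpin: F, I1, I2, I3 on the unzipping pathway, U unfolded, and an
#'     off-pathway misfold M reachable only from I2. Transition rates are
#'     built by [equilibrium_scheme()] so the occupancies at the reference
#'     trap separation are exactly Boltzmann in the injected free
#'     energies - the end-to-end oracle for the energetics pipeline.}
#'   \item{ADE_extROQ_binding}{a reduced I1/I3/U network with a
#'     conformational-selection binding channel emulating extROQ at 10 nM:
#'     binding from folded I3 only, unfolding I3 -> U blocked and
#'     refolding I3 -> I1 slowed 9-fold while bound (a 1.3 kcal/mol
#'     destabilization of I1).}
#' }
#'
#' @param name preset name.
#' @return list with \code{scheme}, \code{model}, \code{trap_separation}
#'   (nm), \code{noise_sd} (pN), \code{sampling_hz},
#'   \code{downsample_factor}, and for the six-state preset
#'   \code{n_nt_of_state} plus the injected \code{dG0_kcal}.
#' @export
otfold_preset <- function(name = c("CDE_two_state", "ADE_six_state",
                                   "ADE_extROQ_binding")) {
  name <- match.arg(name)
  model <- elastic_model()
  switch(name,
    CDE_two_state = {
      states <- data.frame(name = c("F", "U"),
                           n_unfolded_nt = c(0, 15),
                           dG0_kcal = c(0, 9.5))
      transitions <- data.frame(
        from = c("F", "U"), to = c("U", "F"),
        k0 = c(1e-7, 3.6e7), dx = c(6, 6), sign = c(1, -1))
      sep <- construct_extension(11.5, model, 0, 1) + 11.5 / model$trap_stiffness
      list(scheme = kinetic_scheme(states, transitions), model = model,
           trap_separation = sep, noise_sd = 0.35,
           sampling_hz = 1500, downsample_factor = 3L)
    },
    ADE_six_state = {
      # six levels at the reference trap separation; the misfold M releases
      # 7 nt, off every sequential-unzipping boundary (14/26/38/52), and
      # its force level falls between F and I1
      states <- data.frame(
        name = c("F", "I1", "I2", "I3", "M", "U"),
        n_unfolded_nt = c(0, 14, 26, 38, 7, 52),
        dG0_kcal = 0,
        n_closed_stems = c(1, 1, 1, 1, 1, 0))
      sep <- construct_extension(13, model, 0, 1) + 13 / model$trap_stiffness
      # injected truth: total-energy stagger (kcal/mol, relative to F) at
      # the reference separation; dG0 follows from the mechanical energies
      stagger <- c(F = 0, I1 = -0.2, I2 = 0.1, I3 = -0.1, M = 0.5,
                   U = 0.2)
      sc0 <- kinetic_scheme(states, data.frame(
        from = character(0), to = character(0), k0 = numeric(0),
        dx = numeric(0), sign = numeric(0)))
      gm <- vapply(seq_len(nrow(states)), function(i) {
        f <- passive_force(sep, model, states$n_unfolded_nt[i],
                           states$n_closed_stems[i])
        state_mechanical_energy(f, model, states$n_unfolded_nt[i])
      }, numeric(1))
      states$dG0_kcal <- pNnm_to_kcalmol(gm[1] - gm) + stagger
      edges <- data.frame(from = c("F", "I1", "I2", "I3", "I2"),
                          to = c("I1", "I2", "I3", "U", "M"),
                          k_base = c(12, 12, 12, 12, 6))
      sch <- equilibrium_scheme(states, edges, model, sep)
      list(scheme = sch, model = model, trap_separation = sep,
           noise_sd = 0.15, sampling_hz = 1500, downsample_factor = 3L,
           n_nt_of_state = stats::setNames(states$n_unfolded_nt,
                                           states$name),
           dG0_kcal = stats::setNames(states$dG0_kcal, states$name))
    },
    ADE_extROQ_binding = {
      states <- data.frame(name = c("I1", "I3", "U"),
                           n_unfolded_nt = c(0, 24, 42),
                           dG0_kcal = c(0, 5, 9),
                           n_closed_stems = c(1, 1, 0))
      transitions <- data.frame(
        from = c("I1", "I3", "I3", "U"),
        to = c("I3", "I1", "U", "I3"),
        k0 = c(2, 1, 5, 20), dx = 0, sign = 0)
      binding <- list(
        k_on = 2e7, protein_conc = 10e-9,
        k_off0 = 0, dx_off = 0, k_off_force_independent = 0.02,
        competent_state = "I3",
        blocked_while_bound = "I3->U",
        slowed_while_bound = data.frame(from = "I3", to = "I1",
                                        factor = exp(1.3 / 0.592)))
      sep <- construct_extension(11, model, 0, 1) + 11 / model$trap_stiffness
      list(scheme = kinetic_scheme(states, transitions, binding),
           model = model, trap_separation = sep, noise_sd = 0.35,
           sampling_hz = 1500, downsample_factor = 3L)
    })
}

#' Two-state binding scheme with an injected zero-force K_D
#'
#' Builds the study condition for a zero-force K_D recovery experiment: a
#' folded, binding-competent state I3 and the unfolded state U with fast
#' force-independent hopping, plus a conformational-selection binding
#' channel whose zero-force off-rate is \code{kd * k_on}. The off-rate
#' carries a force-independent and a Bell force-dependent contribution:
#' \code{k_off(F) = k_ind_frac*k_off(0) + (1-k_ind_frac)*k_off(0) *
#' exp(F*dx_off/kT)} (so \code{k_off(0)} is exact by construction).
#'
#' @param kd_nM ground-truth zero-force dissociation constant, nM.
#' @param k_on association rate, 1/M/s.
#' @param protein_conc protein concentration, M.
#' @param dx_off unbinding transition-state distance, nm.
#' @param k_ind_frac force-independent fraction of the zero-force
#'   off-rate.
#' @param k_unfold,k_fold unbound I3 <-> U hopping rates, 1/s.
#' @return a [kinetic_scheme()].
#' @export
roq_binding_scheme <- function(kd_nM, k_on = 2e7, protein_conc = 30e-9,
                               dx_off = 0.5, k_ind_frac = 0.7,
                               k_unfold = 15, k_fold = 60) {
  k_off0 <- kd_nM * 1e-9 * k_on
  states <- data.frame(name = c("I3", "U"),
                       n_unfolded_nt = c(0, 50),
                       dG0_kcal = c(0, 4),
                       n_closed_stems = c(1, 0))
  transitions <- data.frame(from = c("I3", "U"), to = c("U", "I3"),
                            k0 = c(k_unfold, k_fold), dx = 0, sign = 0)
  binding <- list(
    k_on = k_on, protein_conc = protein_conc,
    k_off0 = (1 - k_ind_frac) * k_off0, dx_off = dx_off,
    k_off_force_independent = k_ind_frac * k_off0,
    competent_state = "I3",
    blocked_while_bound = "I3->U",
    slowed_while_bound = NULL)
  kinetic_scheme(states, transitions, binding)
}

#' Secondary structures of the built-in fixtures
#'
#' \code{cde_hairpin()} is a 15-nt triloop hairpin (6-bp stem);
#' \code{ade_hairpin()} is a 52-nt hairpin with four helices separated by
#' single-nucleotide interior bulges, whose sequential-unzipping
#' boundaries release 14, 26, 38 and 52 nucleotides - the intermediates of
#' the six-state fixture. Both are synthetic fixture structures.
#'
#' @return a [secondary_structure()].
#' @export
cde_hairpin <- function() {
  secondary_structure("GGCAGCUUAGCUGCC", "((((((...))))))",
                      name = "CDE_fixture")
}

#' @rdname cde_hairpin
#' @export
ade_hairpin <- function() {
  seq52 <- paste0("GGCAGC", "A", "GCUGC", "A", "GGCAC", "U", "GCGC",
                  "UUCGAA", "GCGC", "A", "GUGCC", "U", "GCAGC", "A",
                  "GCUGCC")
  db52 <- paste0("((((((", ".", "(((((", ".", "(((((", ".", "((((",
                 "......", "))))", ".", ")))))", ".", ")))))", ".",
                 "))))))")
  secondary_structure(seq52, db52, name = "ADE_fixture",
                      numbering_offset = 52)
}
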