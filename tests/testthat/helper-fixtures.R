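# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data.

# simple symmetric two-state scheme with constant rates
two_state_scheme <- function(k12 = 10, k21 = 10, n_unf = 30,
                             dG0 = 5) {
  kinetic_scheme(
    data.frame(name = c("A", "B"), n_unfolded_nt = c(0, n_unf),
               dG0_kcal = c(0, dG0)),
    data.frame(from = c("A", "B"), to = c("B", "A"),
               k0 = c(k12, k21), dx = 0, sign = 0))
}

# trap separation that puts the folded state of `scheme` at `force`
separation_for_force <- function(force, model, n_unfolded_nt = 0,
                                 n_closed_stems = 1) {
  construct_extension(force, model, n_unfolded_nt, n_closed_stems) +
    force / model$trap_stiffness
}

# state-name order of the six-state ADE preset sorted by force level
# (what fit_hmm index i corresponds to)
ade_level_names <- c("F", "M", "I1", "I2", "I3", "U")
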