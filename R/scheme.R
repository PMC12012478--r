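#' Kinetic scheme of folding states and transitions
#'
#' Describes a Markov folding network: a set of conformational states (each
#' with its number of released ssRNA nucleotides and folding free energy
#' relative to the fully folded state) and force-dependent transition rates
#' in the Bell form \code{k(F) = k0 * exp(sign * F * dx / kT)}. An optional
#' binding block adds a protein channel with conformational-selection
#' binding: the protein binds only from the competent (folded) state, and
#' while bound a declared set of transitions is blocked or slowed.
#'
#' @param states data.frame with columns \code{name}, \code{n_unfolded_nt},
#'   \code{dG0_kcal} (folding free energy at zero force relative to the
#'   fully folded state, kcal/mol) and optionally \code{n_closed_stems}
#'   (defaults to 1 except for the state with the most released
#'   nucleotides, which gets 0).
#' @param transitions data.frame with columns \code{from}, \code{to},
#'   \code{k0} (rate at zero force, 1/s), \code{dx} (transition-state
#'   distance, nm) and \code{sign} (+1 force-accelerated, -1
#'   force-decelerated, 0 force-independent).
#' @param binding optional list with elements \code{k_on} (1/M/s),
#'   \code{protein_conc} (M), \code{k_off0} (1/s), \code{dx_off} (nm),
#'   \code{k_off_force_independent} (1/s), \code{competent_state},
#'   \code{blocked_while_bound} (character "A->B"), and
#'   \code{slowed_while_bound} (data.frame \code{from}, \code{to},
#'   \code{factor}).
#' @return An object of class \code{kinetic_scheme}.
#' @export
kinetic_scheme <- function(states, transitions, binding = NULL) {
  states <- as.data.frame(states, stringsAsFactors = FALSE)
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "n_unfolded_nt", "dG0_kcal") %in% names(states)),
            all(c("from", "to", "k0", "dx", "sign") %in% names(transitions)))
  if (anyDuplicated(states$name)) stop("state names must be unique")
  if (min(states$n_unfolded_nt) != 0) {
    stop("the fully folded state must have n_unfolded_nt = 0")
  }
  if (any(transitions$k0 < 0)) stop("rates must be >= 0")
  bad <- setdiff(c(transitions$from, transitions$to), states$name)
  if (length(bad)) stop("unknown states in transitions: ",
                        paste(bad, collapse = ", "))
  if (is.null(states$n_closed_stems)) {
    states$n_closed_stems <- ifelse(
      states$n_unfolded_nt == max(states$n_unfolded_nt), 0L, 1L)
  }
  if (!is.null(binding)) {
    req <- c("k_on", "protein_conc", "k_off0", "dx_off",
             "k_off_force_independent", "competent_state")
    miss <- setdiff(req, names(binding))
    if (length(miss)) stop("binding block missing: ",
                           paste(miss, collapse = ", "))
    if (!binding$competent_state %in% states$name) {
      stop("competent_state '", binding$competent_state, "' not a state")
    }
    if (is.null(binding$blocked_while_bound)) binding$blocked_while_bound <-
        character(0)
    if (is.null(binding$slowed_while_bound)) binding$slowed_while_bound <-
        data.frame(from = character(0), to = character(0),
                   factor = numeric(0))
  }
  structure(list(states = states, transitions = transitions,
                 binding = binding),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme:", nrow(x$states), "states,",
      nrow(x$transitions), "transitions",
      if (!is.null(x$binding)) "+ protein binding channel" else "", "\n")
  print(x$states, row.names = FALSE)
  invisible(x)
}

#' Bell-model transition rate at a force
#'
#' @param k0 zero-force rate, 1/s.
#' @param dx transition-state distance, nm.
#' @param sign +1 (force-accelerated), -1 (force-decelerated) or 0.
#' @param force force, pN.
#' @param kT thermal energy, pN.nm.
#' @return rate, 1/s.
#' @export
bell_rate <- function(k0, dx, sign, force, kT = kT_25C_pNnm) {
  k0 * exp(sign * force * dx / kT)
}

# Per-state passive-mode force levels for a scheme at one trap separation.
scheme_state_forces <- function(scheme, model, trap_separation) {
  st <- scheme$states
  stats::setNames(vapply(seq_len(nrow(st)), function(i) {
    passive_force(trap_separation, model, st$n_unfolded_nt[i],
                  st$n_closed_stems[i])
  }, numeric(1)), st$name)
}

# Total system energy (folding + mechanical, pN.nm) of each state at its
# passive-mode force level.
scheme_state_energies <- function(scheme, model, trap_separation) {
  st <- scheme$states
  f <- scheme_state_forces(scheme, model, trap_separation)
  kcalmol_to_pNnm(st$dG0_kcal) + vapply(seq_len(nrow(st)), function(i) {
    state_mechanical_energy(f[i], model, st$n_unfolded_nt[i])
  }, numeric(1))
}

#' Detailed-balance transition rates for an equilibrium fixture
#'
#' Builds force-independent (constant) transition rates on a given edge set
#' so that the stationary distribution at a specific trap separation is
#' exactly Boltzmann in the total system energy (folding free energy plus
#' mechanical energy of ssRNA, handles and traps). Metropolis rates are
#' used: \code{k_ij = k_base * exp(-max(0, E_j - E_i)/kT)}. This makes the
#' simulator's occupancies an analytic oracle for the energetics pipeline.
#'
#' @param states state table as in [kinetic_scheme()].
#' @param edges data.frame with columns \code{from}, \code{to} (undirected;
#'   both directions are generated) and optionally \code{k_base} per edge.
#' @param model an [elastic_model()].
#' @param trap_separation trap separation the fixture will be simulated at, nm.
#' @param k_base attempt rate, 1/s.
#' @param binding optional binding block, passed through.
#' @return a [kinetic_scheme()] with constant rates.
#' @export
equilibrium_scheme <- function(states, edges, model, trap_separation,
                               k_base = 50, binding = NULL) {
  sc0 <- kinetic_scheme(states, data.frame(
    from = character(0), to = character(0), k0 = numeric(0),
    dx = numeric(0), sign = numeric(0)), binding = NULL)
  E <- scheme_state_energies(sc0, model, trap_separation)
  names(E) <- sc0$states$name
  kb <- if (is.null(edges$k_base)) rep(k_base, nrow(edges)) else edges$k_base
  tr <- do.call(rbind, lapply(seq_len(nrow(edges)), function(i) {
    a <- edges$from[i]; b <- edges$to[i]
    dE <- (E[b] - E[a]) / model$kT
    data.frame(from = c(a, b), to = c(b, a),
               k0 = kb[i] * exp(-pmax(0, c(dE, -dE))),
               dx = 0, sign = 0)
  }))
  kinetic_scheme(sc0$states, tr, binding = binding)
}

# Rate matrix (1/s) of the scheme evaluated at per-state forces; rates for
# a transition use the force of the departure state (the dwell force).
scheme_rate_matrix <- function(scheme, forces, kT = kT_25C_pNnm) {
  st <- scheme$states$name
  K <- length(st)
  Q <- matrix(0, K, K, dimnames = list(st, st))
  tr <- scheme$transitions
  for (i in seq_len(nrow(tr))) {
    a <- tr$from[i]; b <- tr$to[i]
    Q[a, b] <- Q[a, b] + bell_rate(tr$k0[i], tr$dx[i], tr$sign[i],
                                   forces[match(a, st)], kT)
  }
  Q
}

# Augment a scheme with a bound copy of every state (conformational
# selection: binding only from the competent state; unbinding from any
# bound state at k_off(F); blocked/slowed edges apply while bound).
augment_binding_scheme <- function(scheme, forces, kT = kT_25C_pNnm) {
  b <- scheme$binding
  if (is.null(b)) stop("scheme has no binding block")
  st <- scheme$states$name
  K <- length(st)
  Qu <- scheme_rate_matrix(scheme, forces, kT)
  Qb <- Qu
  for (e in b$blocked_while_bound) {
    ab <- strsplit(e, "->", fixed = TRUE)[[1]]
    Qb[trimws(ab[1]), trimws(ab[2])] <- 0
  }
  sw <- b$slowed_while_bound
  if (NROW(sw)) {
    for (i in seq_len(nrow(sw))) {
      Qb[sw$from[i], sw$to[i]] <- Qb[sw$from[i], sw$to[i]] / sw$factor[i]
    }
  }
  Q <- matrix(0, 2 * K, 2 * K,
              dimnames = list(c(st, paste0(st, ":bound")),
                              c(st, paste0(st, ":bound"))))
  Q[1:K, 1:K] <- Qu
  Q[K + 1:K, K + 1:K] <- Qb
  ci <- match(b$competent_state, st)
  Q[ci, K + ci] <- b$k_on * b$protein_conc
  koff <- b$k_off_force_independent + b$k_off0 *
    exp(forces * b$dx_off / kT)
  for (i in 1:K) Q[K + i, i] <- koff[i]
  Q
}
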