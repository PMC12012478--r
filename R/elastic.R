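#' Mechanical model of the dual-trap dumbbell construct
#'
#' Collects every elasticity parameter of the assay: the two optical traps
#' (collapsed into one effective stiffness \code{k_eff = k1*k2/(k1+k2)}),
#' the dsDNA handles, the released ssRNA, and the end-to-end offset spanned
#' by a closed hairpin stem.
#'
#' Defaults follow conventional values for this assay type: ssRNA contour
#' 0.65 nm/nt and persistence 1.0 nm, folded stem offset 2.0 nm (so a 15-nt
#' hairpin release yields a 7.75 nm contour-length gain), dsDNA handles of
#' 600 nm total contour with 40 nm persistence and 1000 pN stretch modulus,
#' and an effective trap stiffness of 0.15 pN/nm (per-trap stiffnesses of
#' 0.25--0.40 pN/nm in series). Handle defaults are fixture conventions, not
#' measured claims; all are overridable.
#'
#' @param kT thermal energy, pN.nm (default 4.114, i.e. 25 C).
#' @param trap_stiffness effective combined trap stiffness, pN/nm.
#' @param handle_contour total dsDNA handle contour length, nm.
#' @param handle_persistence dsDNA persistence length, nm.
#' @param handle_stretch_modulus dsDNA stretch modulus, pN (\code{Inf}
#'   disables the enthalpic term).
#' @param ss_contour_per_nt ssRNA contour length per nucleotide, nm.
#' @param ss_persistence ssRNA persistence length, nm.
#' @param folded_offset end-to-end distance spanned by one closed stem, nm.
#' @param allow_unusual_stiffness set \code{TRUE} to permit an effective
#'   stiffness outside the 0.01--10 pN/nm band.
#'
#' @return An object of class \code{elastic_model}.
#' @examples
#' m <- elastic_model()
#' passive_force(330, m, n_unfolded_nt = 0)
#' @export
elastic_model <- function(kT = kT_25C_pNnm,
                          trap_stiffness = 0.15,
                          handle_contour = 600,
                          handle_persistence = 40,
                          handle_stretch_modulus = 1000,
                          ss_contour_per_nt = 0.65,
                          ss_persistence = 1.0,
                          folded_offset = 2.0,
                          allow_unusual_stiffness = FALSE) {
  stopifnot(kT > 0, handle_contour > 0, handle_persistence > 0,
            handle_stretch_modulus > 0, ss_contour_per_nt > 0,
            ss_persistence > 0, folded_offset >= 0, trap_stiffness > 0)
  if (!allow_unusual_stiffness &&
      (trap_stiffness < 0.01 || trap_stiffness > 10)) {
    stop("trap_stiffness ", trap_stiffness,
         " pN/nm is outside the expected 0.01-10 pN/nm band; ",
         "set allow_unusual_stiffness = TRUE to override")
  }
  structure(list(kT = kT, trap_stiffness = trap_stiffness,
                 handle_contour = handle_contour,
                 handle_persistence = handle_persistence,
                 handle_stretch_modulus = handle_stretch_modulus,
                 ss_contour_per_nt = ss_contour_per_nt,
                 ss_persistence = ss_persistence,
                 folded_offset = folded_offset),
            class = "elastic_model")
}

#' @export
print.elastic_model <- function(x, ...) {
  cat("Dumbbell elastic model\n")
  cat(sprintf("  kT: %.3f pN.nm   effective trap stiffness: %.3f pN/nm\n",
              x$kT, x$trap_stiffness))
  cat(sprintf("  handles: L = %g nm, p = %g nm, K = %g pN\n",
              x$handle_contour, x$handle_persistence,
              x$handle_stretch_modulus))
  cat(sprintf("  ssRNA: %g nm/nt, p = %g nm; folded stem offset %g nm\n",
              x$ss_contour_per_nt, x$ss_persistence, x$folded_offset))
  invisible(x)
}

# Relative extension z solving the Marko-Siggia relation at scaled force
# fs = F*p/kT. Root of 4u^3 + (4*fs - 3)u^2 - 1 = 0 in u = 1 - z, located
# in (0, 1]; vectorized bisection (monotone sign change guaranteed).
ms_rel_extension <- function(f_scaled) {
  fs <- pmax(f_scaled, 0)
  lo <- rep(1e-12, length(fs))
  hi <- rep(1, length(fs))
  g <- function(u) 4 * u^3 + (4 * fs - 3) * u^2 - 1
  # g(0+) = -1 < 0; g(1) = 4*fs >= 0; bisect on the first sign change from
  # the high end (g has at most one root in (0,1] for fs >= 0)
  for (i in 1:48) {
    mid <- 0.5 * (lo + hi)
    pos <- g(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  z <- 1 - 0.5 * (lo + hi)
  z[f_scaled <= 0] <- 0
  z
}

#' Worm-like chain force at a relative extension
#'
#' Marko--Siggia interpolation
#' \code{F = (kT/p) * (1/(4(1-z)^2) - 1/4 + z)} with \code{z = x/L}.
#'
#' @param rel_extension relative extension \code{z} in \code{[0, 1)}.
#' @param persistence persistence length, nm.
#' @param kT thermal energy, pN.nm.
#' @return force, pN (vectorized).
#' @examples
#' wlc_force(0.5, persistence = 1, kT = 4.114)  # 5.1425 pN
#' @export
wlc_force <- function(rel_extension, persistence, kT = kT_25C_pNnm) {
  z <- rel_extension
  if (any(z < 0) || any(z >= 1)) {
    stop("rel_extension must lie in [0, 1): the WLC is finitely extensible")
  }
  (kT / persistence) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}

#' Worm-like chain extension at a force
#'
#' Numeric inverse of [wlc_force()]; with a finite stretch modulus the
#' extensible-WLC correction \code{L*F/K} is added (series enthalpic
#' stretching), the standard treatment for dsDNA handles.
#'
#' @param force force, pN (vectorized, must be >= 0).
#' @param contour contour length L, nm.
#' @param persistence persistence length, nm.
#' @param kT thermal energy, pN.nm.
#' @param stretch_modulus enthalpic stretch modulus K, pN (\code{Inf} for the
#'   inextensible WLC).
#' @return extension, nm.
#' @export
wlc_extension <- function(force, contour, persistence, kT = kT_25C_pNnm,
                          stretch_modulus = Inf) {
  if (any(force < 0)) stop("force must be >= 0")
  z <- ms_rel_extension(force * persistence / kT)
  ext <- contour * z
  if (is.finite(stretch_modulus)) ext <- ext + contour * force / stretch_modulus
  ext
}

# Extension of every series element at force F for a construct with
# n_unfolded_nt released ssRNA nucleotides and n_closed_stems closed stems
# (each spanning folded_offset nm as a rigid element).
construct_extension_parts <- function(force, model, n_unfolded_nt,
                                      n_closed_stems) {
  xh <- wlc_extension(force, model$handle_contour, model$handle_persistence,
                      model$kT, model$handle_stretch_modulus)
  Lss <- n_unfolded_nt * model$ss_contour_per_nt
  xss <- if (Lss > 0) {
    wlc_extension(force, Lss, model$ss_persistence, model$kT)
  } else rep(0, length(force))
  list(handles = xh, ss = xss,
       folded = rep(n_closed_stems * model$folded_offset, length(force)))
}

#' Total construct extension at a force
#'
#' Series sum of dsDNA handle extension, released-ssRNA extension and the
#' rigid span of any still-closed stem. Each fully closed stem contributes
#' one \code{folded_offset}; opening it replaces the offset by the ssRNA
#' contour of the released nucleotides.
#'
#' @param force force, pN (vectorized).
#' @param model an [elastic_model()].
#' @param n_unfolded_nt number of released ssRNA nucleotides.
#' @param n_closed_stems number of fully closed stems still spanning the
#'   tether (default 1 when any structure remains, 0 when fully unfolded).
#' @return total extension, nm.
#' @export
construct_extension <- function(force, model, n_unfolded_nt,
                                n_closed_stems = 1) {
  stopifnot(n_unfolded_nt >= 0, n_closed_stems >= 0)
  p <- construct_extension_parts(force, model, n_unfolded_nt, n_closed_stems)
  p$handles + p$ss + p$folded
}

#' Passive-mode force at fixed trap separation
#'
#' Solves the force balance \code{F = k_trap * (D - x_total(F))} of the
#' dumbbell at trap separation \code{D}. In passive mode each folding state
#' sets its own force level: unfolding releases contour, the beads relax
#' into the traps and the force drops.
#'
#' @param trap_separation trap separation D, nm (vectorized).
#' @param model an [elastic_model()].
#' @param n_unfolded_nt released ssRNA nucleotides in the current state.
#' @param n_closed_stems closed stems in the current state.
#' @param f_max upper bracket for the root solve, pN.
#' @return force, pN.
#' @export
passive_force <- function(trap_separation, model, n_unfolded_nt,
                          n_closed_stems = 1, f_max = 120) {
  D <- trap_separation
  k <- model$trap_stiffness
  resid <- function(f) {
    f - k * (D - construct_extension(f, model, n_unfolded_nt, n_closed_stems))
  }
  r0 <- resid(rep(0, length(D)))
  rmax <- resid(rep(f_max, length(D)))
  if (any(r0 > 0)) {
    stop("trap separation below the zero-force construct length: no tension")
  }
  if (any(rmax < 0)) {
    stop("no force-balance root below ", f_max,
         " pN; check trap separation and model")
  }
  lo <- rep(0, length(D))
  hi <- rep(f_max, length(D))
  for (i in 1:48) {
    mid <- 0.5 * (lo + hi)
    pos <- resid(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  0.5 * (lo + hi)
}

# Passive force for an arbitrary extra ssRNA contour (nm) instead of a
# nucleotide count; used by the contour-gain inversion and WLC branch fits.
# A negative ss_contour is accepted as a signed (odd-extended) nuisance so
# least-squares branch fits are unbiased when the true value sits at zero.
passive_force_contour <- function(trap_separation, model, ss_contour,
                                  n_closed_stems = 1, f_max = 120) {
  D <- trap_separation
  k <- model$trap_stiffness
  resid <- function(f) {
    xh <- wlc_extension(f, model$handle_contour, model$handle_persistence,
                        model$kT, model$handle_stretch_modulus)
    xss <- if (ss_contour != 0) {
      sign(ss_contour) *
        wlc_extension(f, abs(ss_contour), model$ss_persistence, model$kT)
    } else 0
    f - k * (D - xh - xss - n_closed_stems * model$folded_offset)
  }
  lo <- rep(0, length(D))
  hi <- rep(f_max, length(D))
  if (any(resid(lo) > 0)) stop("trap separation below slack length")
  if (any(resid(hi) < 0)) stop("no root below f_max")
  for (i in 1:48) {
    mid <- 0.5 * (lo + hi)
    pos <- resid(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  0.5 * (lo + hi)
}

#' Contour-length gain from a passive-mode force jump
#'
#' Inverts the dumbbell force balance in the ssRNA-contour argument: given
#' the force before (\code{force_high}) and after (\code{force_low}) an
#' unfolding transition at fixed trap separation, finds the ssRNA
#' contour-length gain that explains the force drop.
#'
#' @param force_high force of the more folded state, pN.
#' @param force_low force of the less folded state, pN.
#' @param trap_separation trap separation, nm.
#' @param model an [elastic_model()].
#' @param opens_last_stem \code{TRUE} if the transition opens the final
#'   closed stem (its rigid offset is replaced by ssRNA contour).
#' @return contour-length gain, nm (net of the folded offset when
#'   \code{opens_last_stem}).
#' @export
contour_gain_from_force_jump <- function(force_high, force_low,
                                         trap_separation, model,
                                         opens_last_stem = FALSE) {
  if (force_high < force_low) {
    stop("force_high must be >= force_low (unfolding drops the force)")
  }
  if (force_low <= 0) stop("forces must be positive")
  if (force_high == force_low) return(0)
  D <- trap_separation
  # ssRNA contour consistent with the high force (state before the jump)
  base <- stats::uniroot(function(L) {
    passive_force_contour(D, model, L, n_closed_stems = 1) - force_high
  }, c(0, 2000), tol = 1e-9)$root
  ncs_after <- if (opens_last_stem) 0 else 1
  f_after <- function(dL) {
    passive_force_contour(D, model, base + model$folded_offset *
                            opens_last_stem + dL, ncs_after) - force_low
  }
  if (f_after(0) < 0) {
    stop("forces inconsistent: no positive contour gain reproduces force_low")
  }
  stats::uniroot(f_after, c(0, 2000), tol = 1e-9)$root
}

#' Nucleotides released for a given contour-length gain
#'
#' Converts a measured contour-length gain into the number of released
#' nucleotides, \code{n = (dL + folded_offset*[closes_hairpin]) /
#' ss_contour_per_nt}, rounded to the nearest integer. When the transition
#' opens (or closes) a complete hairpin, the rigid stem offset that the
#' ssRNA replaces is added back before dividing.
#'
#' @param delta_contour measured contour-length gain, nm.
#' @param model an [elastic_model()].
#' @param closes_hairpin does the transition open/close a complete hairpin?
#' @return list with \code{n_nt} (integer) and \code{n_exact} (unrounded).
#' @examples
#' nt_from_contour_gain(7.75, elastic_model(), closes_hairpin = TRUE)$n_nt  # 15
#' @export
nt_from_contour_gain <- function(delta_contour, model,
                                 closes_hairpin = FALSE) {
  stopifnot(delta_contour > 0)
  n_exact <- (delta_contour + model$folded_offset * closes_hairpin) /
    model$ss_contour_per_nt
  list(n_nt = as.integer(round(n_exact)), n_exact = n_exact)
}

#' Expected contour-length gain for n released nucleotides
#'
#' Inverse of [nt_from_contour_gain()]: the ssRNA contour of \code{n_nt}
#' nucleotides minus the folded-stem offset if a complete hairpin opens.
#'
#' @inheritParams nt_from_contour_gain
#' @param n_nt number of released nucleotides.
#' @return expected contour-length gain, nm.
#' @export
expected_contour_gain <- function(n_nt, model, closes_hairpin = FALSE) {
  n_nt * model$ss_contour_per_nt - model$folded_offset * closes_hairpin
}

#' Free energy stored in a stretched worm-like chain
#'
#' The reversible work \code{integral of F dx} from zero extension to the
#' extension at \code{force}, computed as \code{F*x(F) - integral of x dF}
#' (the second term by adaptive quadrature of [wlc_extension()]).
#'
#' @inheritParams wlc_extension
#' @return stretching free energy, pN.nm (vectorized over \code{force}).
#' @export
stretch_free_energy <- function(force, contour, persistence,
                                kT = kT_25C_pNnm, stretch_modulus = Inf) {
  if (any(force < 0)) stop("force must be >= 0")
  vapply(force, function(f) {
    if (f == 0) return(0)
    xi <- stats::integrate(function(ff) {
      wlc_extension(ff, contour, persistence, kT, stretch_modulus)
    }, 0, f, rel.tol = 1e-9)$value
    f * wlc_extension(f, contour, persistence, kT, stretch_modulus) - xi
  }, numeric(1))
}

# Mechanical free energy of the whole dumbbell in a given state at its
# passive-mode force: stretched ssRNA + stretched handles + trap potential.
state_mechanical_energy <- function(force, model, n_unfolded_nt) {
  g_h <- stretch_free_energy(force, model$handle_contour,
                             model$handle_persistence, model$kT,
                             model$handle_stretch_modulus)
  Lss <- n_unfolded_nt * model$ss_contour_per_nt
  g_ss <- if (Lss > 0) {
    stretch_free_energy(force, Lss, model$ss_persistence, model$kT)
  } else 0
  g_h + g_ss + force^2 / (2 * model$trap_stiffness)
}
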