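#' Simulate a continuous-time Markov state path
#'
#' Exact Gillespie simulation of the folding network at fixed per-state
#' forces: each dwell is exponential with the total exit rate of the
#' current state, and the successor is drawn proportionally to the
#' individual rates.
#'
#' @param scheme a [kinetic_scheme()] (without binding; see
#'   [simulate_binding_trace()] for the bound channel) or a rate matrix.
#' @param force_of_state named numeric vector of per-state forces, pN (one
#'   per state; ignored if \code{scheme} is already a rate matrix).
#' @param duration total simulated time, s.
#' @param seed integer RNG seed.
#' @param initial_state starting state name, or \code{NULL} to draw from
#'   the stationary distribution.
#' @return data.frame with columns \code{state}, \code{t_start},
#'   \code{duration}; dwells tile \code{[0, duration]}.
#' @export
simulate_state_path <- function(scheme, force_of_state = NULL, duration,
                                seed = 1, initial_state = NULL) {
  stopifnot(duration > 0)
  Q <- if (is.matrix(scheme)) scheme else {
    f <- force_of_state
    if (is.null(names(f))) {
      if (length(f) != nrow(scheme$states)) {
        stop("force_of_state must have one force per state")
      }
      names(f) <- scheme$states$name
    }
    scheme_rate_matrix(scheme, f[scheme$states$name], kT = kT_25C_pNnm)
  }
  st <- rownames(Q)
  set.seed(seed)
  exit <- rowSums(Q)
  cur <- if (is.null(initial_state)) {
    sample(seq_along(st), 1, prob = ctmc_stationary(Q))
  } else match(initial_state, st)
  if (is.na(cur)) stop("unknown initial_state")
  t <- 0
  states <- integer(0); starts <- numeric(0); durs <- numeric(0)
  repeat {
    if (exit[cur] <= 0) {
      warning("absorbing state '", st[cur], "' reached; dwell runs to end")
      dw <- duration - t
    } else {
      dw <- stats::rexp(1, exit[cur])
    }
    dw <- min(dw, duration - t)
    states <- c(states, cur); starts <- c(starts, t); durs <- c(durs, dw)
    t <- t + dw
    if (t >= duration) break
    cur <- sample.int(length(st), 1, prob = Q[cur, ])
  }
  data.frame(state = st[states], t_start = starts, duration = durs,
             stringsAsFactors = FALSE)
}

# Stationary distribution of a CTMC rate matrix (rows = from). Solves
# pi Q = 0 with sum(pi) = 1; falls back to uniform for a single state.
ctmc_stationary <- function(Q) {
  K <- nrow(Q)
  if (K == 1) return(1)
  G <- Q
  diag(G) <- -rowSums(Q)
  A <- rbind(t(G), rep(1, K))
  b <- c(rep(0, K), 1)
  pi <- stats::coef(stats::lm.fit(A, b))
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

# Per-sample state index from a dwell path on a uniform grid (state at the
# sample instant). Dwells shorter than a sample may vanish here but remain
# in the dwell table.
path_to_samples <- function(path, time) {
  idx <- findInterval(time, path$t_start)
  idx[idx < 1] <- 1
  path$state[idx]
}

#' Simulate a passive-mode force trace
#'
#' Runs the folding network at fixed trap separation, maps each state to
#' its passive-mode force level (more folded states sit at higher force),
#' samples onto the stored (downsampled) time grid and adds i.i.d. Gaussian
#' measurement noise. Truth labels and the exact dwell path are kept.
#'
#' @param scheme a [kinetic_scheme()] without binding block usage (any
#'   binding block is ignored here; see [simulate_binding_trace()]).
#' @param model an [elastic_model()].
#' @param trap_separation trap separation, nm.
#' @param duration simulated time, s.
#' @param noise_sd Gaussian force noise after downsampling, pN.
#' @param seed RNG seed.
#' @param sampling_hz raw sampling rate, Hz.
#' @param downsample_factor integer downsampling factor (boxcar).
#' @param initial_state optional starting state.
#' @return an [ot_trace()] with truth labels.
#' @export
simulate_passive_trace <- function(scheme, model, trap_separation, duration,
                                   noise_sd = 0.35, seed = 1,
                                   sampling_hz = 78125,
                                   downsample_factor = 3L,
                                   initial_state = NULL) {
  f <- scheme_state_forces(scheme, model, trap_separation)
  names(f) <- scheme$states$name
  sep <- diff(sort(f))
  if (length(sep) && any(sep < noise_sd / 2)) {
    warning("some state force levels are closer than noise_sd/2 (",
            paste(sprintf("%.3f", sep[sep < noise_sd / 2]), collapse = ", "),
            " pN): states may be indistinguishable")
  }
  path <- simulate_state_path(scheme, f, duration, seed = seed,
                              initial_state = initial_state)
  dt <- downsample_factor / sampling_hz
  time <- seq(0, duration - dt, by = dt)
  stname <- path_to_samples(path, time)
  force <- unname(f[stname]) + stats::rnorm(length(time), 0, noise_sd)
  ot_trace(time, force, sampling_hz = sampling_hz,
           downsample_factor = downsample_factor, mode = "passive",
           trap_separation = trap_separation, model = model,
           truth_state = stname, truth_dwells = path)
}

#' Simulate a passive-mode trace with protein binding
#'
#' Extends [simulate_passive_trace()] with a conformational-selection
#' binding channel: the protein binds only from the competent (folded)
#' state at \code{k_on * protein_conc}; while bound, the declared
#' transitions are blocked or slowed and unbinding occurs at
#' \code{k_off(F) = k_off_force_independent + k_off0 * exp(F*dx_off/kT)}
#' evaluated at the current state's force.
#'
#' @inheritParams simulate_passive_trace
#' @return an [ot_trace()] with \code{truth_state} and \code{truth_bound}.
#' @export
simulate_binding_trace <- function(scheme, model, trap_separation, duration,
                                   noise_sd = 0.35, seed = 1,
                                   sampling_hz = 78125,
                                   downsample_factor = 3L,
                                   initial_state = NULL) {
  if (is.null(scheme$binding)) stop("scheme has no binding block")
  if (scheme$binding$protein_conc == 0) {
    return(simulate_passive_trace(scheme, model, trap_separation, duration,
                                  noise_sd, seed, sampling_hz,
                                  downsample_factor, initial_state))
  }
  f <- scheme_state_forces(scheme, model, trap_separation)
  names(f) <- scheme$states$name
  Q <- augment_binding_scheme(scheme, f, kT = model$kT)
  path <- simulate_state_path(Q, duration = duration, seed = seed,
                              initial_state = initial_state)
  bound <- grepl(":bound$", path$state)
  conf <- sub(":bound$", "", path$state)
  dt <- downsample_factor / sampling_hz
  time <- seq(0, duration - dt, by = dt)
  idx <- findInterval(time, path$t_start)
  idx[idx < 1] <- 1
  force <- unname(f[conf[idx]]) + stats::rnorm(length(time), 0, noise_sd)
  truth <- data.frame(state = conf, t_start = path$t_start,
                      duration = path$duration, bound = bound,
                      stringsAsFactors = FALSE)
  ot_trace(time, force, sampling_hz = sampling_hz,
           downsample_factor = downsample_factor, mode = "passive",
           trap_separation = trap_separation, model = model,
           truth_state = conf[idx], truth_bound = bound[idx],
           truth_dwells = truth)
}

#' Simulate constant-velocity stretch-relax cycles
#'
#' Ramps the trap separation linearly between the separations that put the
#' fully folded construct at the low and high ends of \code{f_range}, while
#' the molecule hops between states with Bell force-dependent rates
#' evaluated along the ramp. Each cycle yields a stretch and a relax
#' branch.
#'
#' @inheritParams simulate_passive_trace
#' @param velocity trap velocity, nm/s.
#' @param f_range force range of the ramp (for the folded state), pN.
#' @param n_cycles number of stretch-relax cycles.
#' @return list of [ot_trace()] objects (one per branch) with a
#'   \code{branch} attribute "stretch"/"relax" and \code{cycle} index.
#' @export
simulate_pulling_cycles <- function(scheme, model, velocity = 100,
                                    f_range = c(3, 20), n_cycles = 5,
                                    seed = 1, noise_sd = 0.35,
                                    sampling_hz = 1500,
                                    downsample_factor = 3L) {
  stopifnot(velocity > 0, n_cycles >= 1)
  set.seed(seed)
  st <- scheme$states
  folded <- which.min(st$n_unfolded_nt)
  # trap separations bracketing the requested force range for the folded state
  D_of_force <- function(fr) {
    x <- construct_extension(fr, model, st$n_unfolded_nt[folded],
                             st$n_closed_stems[folded])
    x + fr / model$trap_stiffness
  }
  D_lo <- D_of_force(f_range[1]); D_hi <- D_of_force(f_range[2])
  dt <- downsample_factor / sampling_hz
  n_per <- max(2, ceiling((D_hi - D_lo) / velocity / dt))
  # per-state force level curves on a D grid, interpolated per sample
  Dgrid <- seq(D_lo, D_hi, length.out = 400)
  level_fun <- lapply(seq_len(nrow(st)), function(i) {
    stats::approxfun(Dgrid, passive_force(Dgrid, model,
                                          st$n_unfolded_nt[i],
                                          st$n_closed_stems[i]))
  })
  names(level_fun) <- st$name
  out <- list()
  cur <- st$name[folded]
  for (cyc in seq_len(n_cycles)) {
    for (branch in c("stretch", "relax")) {
      D <- if (branch == "stretch") {
        seq(D_lo, D_hi, length.out = n_per)
      } else seq(D_hi, D_lo, length.out = n_per)
      force <- numeric(n_per); stname <- character(n_per)
      for (i in seq_len(n_per)) {
        Fi <- level_fun[[cur]](D[i])
        # at most one transition per sample step; rates frozen within step
        tr <- scheme$transitions[scheme$transitions$from == cur, ,
                                 drop = FALSE]
        if (nrow(tr)) {
          k <- bell_rate(tr$k0, tr$dx, tr$sign, Fi, model$kT)
          ktot <- sum(k)
          if (ktot > 0 && stats::runif(1) < 1 - exp(-ktot * dt)) {
            cur <- tr$to[sample.int(nrow(tr), 1, prob = k)]
            Fi <- level_fun[[cur]](D[i])
          }
        }
        force[i] <- Fi
        stname[i] <- cur
      }
      force <- force + stats::rnorm(n_per, 0, noise_sd)
      tr_obj <- ot_trace(seq(0, by = dt, length.out = n_per), force,
                         sampling_hz = sampling_hz,
                         downsample_factor = downsample_factor,
                         mode = "constant_velocity", trap_separation = D,
                         model = model, truth_state = stname)
      tr_obj$branch <- branch
      tr_obj$cycle <- cyc
      out[[length(out) + 1]] <- tr_obj
    }
  }
  out
}

#' Simulate a Hill binding titration
#'
#' Fraction bound \code{f = c^n / (kd^n + c^n)} with additive Gaussian
#' noise, clipped to \code{[0, 1]}.
#'
#' @param kd dissociation constant, nM.
#' @param hill_n Hill coefficient.
#' @param concentrations protein concentrations, nM.
#' @param noise_sd Gaussian noise on fraction bound (absolute).
#' @param seed RNG seed.
#' @return data.frame \code{conc}, \code{fraction_bound}.
#' @export
simulate_titration <- function(kd, hill_n = 1,
                               concentrations = c(0, 100, 200, 400, 700,
                                                  1000, 2000, 3000, 5000,
                                                  20000),
                               noise_sd = 0.03, seed = 1) {
  stopifnot(kd > 0, hill_n > 0)
  set.seed(seed)
  f <- concentrations^hill_n / (kd^hill_n + concentrations^hill_n)
  f <- f + stats::rnorm(length(f), 0, noise_sd)
  data.frame(conc = concentrations,
             fraction_bound = pmin(pmax(f, 0), 1))
}

#' Simulate a two-transition melting curve
#'
#' Sum of two descending Boltzmann sigmoids plus a baseline with Gaussian
#' noise, the canonical model for a CD melting curve with two separable
#' transitions.
#'
#' @param tm1,tm2 midpoints of the lower and upper transition, deg C.
#' @param amplitudes signal amplitudes (A1, A2) lost across each transition.
#' @param widths transition widths, deg C.
#' @param baseline high-temperature plateau signal.
#' @param temps temperature grid, deg C.
#' @param noise_sd Gaussian noise on the signal (same units as amplitudes).
#' @param seed RNG seed.
#' @return data.frame \code{temperature}, \code{signal}.
#' @export
simulate_melting_curve <- function(tm1 = 65, tm2 = 76.7,
                                   amplitudes = c(1, 3), widths = c(3, 2.2),
                                   baseline = 0, temps = seq(5, 95, by = 1),
                                   noise_sd = 0.05, seed = 1) {
  stopifnot(tm1 < tm2, all(widths > 0))
  set.seed(seed)
  s <- double_boltzmann(temps, tm1, tm2, amplitudes[1], amplitudes[2],
                        widths[1], widths[2], baseline)
  data.frame(temperature = temps,
             signal = s + stats::rnorm(length(temps), 0, noise_sd))
}

# Two descending Boltzmann sigmoids + baseline (shared by simulator and fit).
double_boltzmann <- function(T, tm1, tm2, A1, A2, w1, w2, baseline) {
  baseline + A1 / (1 + exp((T - tm1) / w1)) + A2 / (1 + exp((T - tm2) / w2))
}
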