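#' Hidden-Markov state assignment of a passive-mode trace
#'
#' Fits a Gaussian-emission hidden Markov model to the force signal by
#' expectation-maximization (Baum-Welch) and returns the Viterbi state
#' path. In passive mode the folding state is encoded in the force level:
#' state 1 is the most folded (highest force). Emission standard deviations
#' are per-state and floored at 0.05 pN; EM stops when the relative
#' log-likelihood change falls below \code{tol} or after \code{max_iter}
#' iterations. When \code{n_states} is omitted, models with 2-8 states are
#' compared by BIC.
#'
#' @param trace an [ot_trace()] in passive mode (or a numeric force vector).
#' @param n_states number of states, or \code{NULL} for BIC selection.
#' @param init_levels optional initial force levels, pN. When omitted,
#'   EM is multi-started from k-means centers (quantile-seeded and
#'   random-seeded) and from quantile-spaced levels, and the run with the
#'   best final log-likelihood is kept - Gaussian-mixture EM on closely
#'   spaced levels has local optima that merge one level and split
#'   another.
#' @param seed RNG seed (initialization restarts and tie-breaking).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param restarts number of EM initializations (1 = k-means only,
#'   2 adds quantile spacing, 3 adds a random-seeded k-means). BIC model
#'   selection scans candidate state counts with a single light
#'   initialization and then refits the winning count at full settings.
#' @return object of class \code{state_assignment}: \code{path} (per-sample
#'   state index, 1 = most folded), \code{levels} (per-state mean/sd force,
#'   sorted descending by mean), \code{transition_counts},
#'   \code{log_likelihood}, \code{loglik_trace}, \code{n_states},
#'   \code{bic}, \code{converged}.
#' @export
fit_hmm <- function(trace, n_states = NULL, init_levels = NULL, seed = 1,
                    tol = 1e-6, max_iter = 500, restarts = 3) {
  x <- if (inherits(trace, "ot_trace")) {
    if (trace$mode != "passive") {
      stop("fit_hmm expects a passive-mode trace")
    }
    trace$force
  } else as.numeric(trace)
  if (is.null(n_states)) {
    scan <- lapply(2:8, function(K) {
      tryCatch(fit_hmm(x, n_states = K, seed = seed, tol = 1e-5,
                       max_iter = 80, restarts = 1),
               error = function(e) NULL)
    })
    scan <- Filter(Negate(is.null), scan)
    best_K <- scan[[which.min(vapply(scan, function(f) f$bic,
                                     numeric(1)))]]$n_states
    return(fit_hmm(x, n_states = best_K, seed = seed, tol = tol,
                   max_iter = max_iter, restarts = restarts))
  }
  n_states <- as.integer(n_states)
  if (n_states < 1) stop("n_states must be >= 1")
  if (n_states == 1) {
    lev <- data.frame(mean = mean(x), sd = max(stats::sd(x), 0.05))
    ll <- sum(stats::dnorm(x, lev$mean, lev$sd, log = TRUE))
    return(structure(list(
      path = rep(1L, length(x)), levels = lev,
      transition_counts = matrix(0, 1, 1), log_likelihood = ll,
      loglik_trace = ll, n_states = 1L,
      bic = -2 * ll + 2 * log(length(x)), converged = TRUE),
      class = "state_assignment"))
  }
  set.seed(seed)
  K <- n_states
  quant_mu <- sort(stats::quantile(x, probs = (seq_len(K) - 0.5) / K,
                                   names = FALSE), decreasing = TRUE)
  kmeans_mu <- function(centers) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers,
                                     iter.max = 30)),
      error = function(e) NULL)
    if (is.null(km)) NULL else sort(as.numeric(km$centers),
                                    decreasing = TRUE)
  }
  inits <- if (!is.null(init_levels)) {
    list(sort(as.numeric(init_levels), decreasing = TRUE))
  } else {
    cand <- list(kmeans_mu(rev(quant_mu)), quant_mu,
                 kmeans_mu(sample(x, K)))[seq_len(max(1, min(restarts, 3)))]
    unique(Filter(Negate(is.null), cand))
  }
  em_run <- function(mu) {
    if (length(mu) != K) stop("init_levels must have length n_states")
    if (anyDuplicated(mu)) {
      mu <- mu + stats::rnorm(K, 0, 1e-3 * max(stats::sd(x), 0.05))
    }
    sd_k <- rep(max(stats::sd(x) / K, 0.05), K)
    A <- matrix(0.05 / (K - 1), K, K); diag(A) <- 0.95
    pi0 <- rep(1 / K, K)
    ll_trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      e <- hmm_forward_backward(x, mu, sd_k, A, pi0)
      ll_trace <- c(ll_trace, e$loglik)
      g <- e$gamma
      occ <- colSums(g)
      mu <- colSums(g * x) / occ
      sd_k <- pmax(sqrt(colSums(g * (outer(x, mu, "-"))^2) / occ), 0.05)
      xi <- e$xi
      A <- xi / pmax(rowSums(xi), 1e-300)
      # guard empty rows
      A[rowSums(xi) == 0, ] <- 1 / K
      pi0 <- pmax(g[1, ], 1e-12); pi0 <- pi0 / sum(pi0)
      if (it > 1) {
        d <- abs(ll_trace[it] - ll_trace[it - 1]) /
          max(1, abs(ll_trace[it - 1]))
        if (d < tol) { converged <- TRUE; break }
      }
    }
    list(mu = mu, sd_k = sd_k, A = A, pi0 = pi0, ll_trace = ll_trace,
         converged = converged)
  }
  runs <- lapply(inits, em_run)
  best <- runs[[which.max(vapply(runs, function(r) {
    r$ll_trace[length(r$ll_trace)]
  }, numeric(1)))]]
  mu <- best$mu; sd_k <- best$sd_k; A <- best$A; pi0 <- best$pi0
  ll_trace <- best$ll_trace; converged <- best$converged
  # canonical state order: descending mean force (state 1 = most folded)
  ord <- order(mu, decreasing = TRUE)
  mu <- mu[ord]; sd_k <- sd_k[ord]
  A <- A[ord, ord, drop = FALSE]; pi0 <- pi0[ord]
  path <- hmm_viterbi(x, mu, sd_k, A, pi0)
  occ_path <- tabulate(path, nbins = K)
  if (any(occ_path < 10)) {
    warning("state(s) ", paste(which(occ_path < 10), collapse = ", "),
            " occupy < 10 samples; consider merging (reduce n_states)")
  }
  tc <- matrix(0L, K, K)
  rl <- rle(path)$values
  if (length(rl) > 1) {
    for (i in seq_len(length(rl) - 1)) {
      tc[rl[i], rl[i + 1]] <- tc[rl[i], rl[i + 1]] + 1L
    }
  }
  ll <- ll_trace[length(ll_trace)]
  n_par <- K * 2 + K * (K - 1) + (K - 1)
  structure(list(path = path,
                 levels = data.frame(mean = mu, sd = sd_k),
                 transition_counts = tc, log_likelihood = ll,
                 loglik_trace = ll_trace, n_states = K,
                 bic = -2 * ll + n_par * log(length(x)),
                 converged = converged),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  cat(sprintf("HMM state assignment: %d states, logLik %.1f%s\n",
              x$n_states, x$log_likelihood,
              if (x$converged) "" else " (not converged)"))
  lev <- x$levels
  lev$occupancy <- tabulate(x$path, x$n_states) / length(x$path)
  print(round(lev, 4))
  invisible(x)
}

#' @export
summary.state_assignment <- function(object, ...) {
  print(object)
  cat("Transition counts:\n")
  print(object$transition_counts)
  invisible(object)
}

#' @export
logLik.state_assignment <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_states * 2 +
              object$n_states * (object$n_states - 1) + object$n_states - 1,
            class = "logLik")
}
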