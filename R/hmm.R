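# Three-state movement HMM: gamma step lengths (with an explicit per-state
# point mass at zero for stationary fixes), von Mises turning angles
# (missing angles contribute likelihood 1), direct likelihood maximisation
# from many random starts, and Viterbi decoding. States are canonically
# relabelled by descending step mean: 1 = travel, 2 = forage, 3 = rest.

#' @useDynLib icerange, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# von Mises density on (-pi, pi].
dvonmises <- function(x, mu, kappa) {
  exp(kappa * cos(x - mu)) / (2 * pi * besselI(kappa, 0,
                                               expon.scaled = TRUE) *
                                exp(kappa))
}

# gamma density parameterised by mean/sd.
dgamma_mean_sd <- function(x, mean, sd) {
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  stats::dgamma(x, shape = shape, rate = rate)
}

# n x N matrix of emission densities for (step, angle) observations.
hmm_allprobs <- function(steps, angles, par) {
  n <- length(steps); N <- length(par$step_mean)
  P <- matrix(1, n, N)
  zs <- steps == 0 & !is.na(steps)
  ok <- !is.na(steps) & !zs
  for (j in seq_len(N)) {
    col <- rep(1, n)
    col[ok] <- (1 - par$zero_mass[j]) *
      dgamma_mean_sd(steps[ok], par$step_mean[j], par$step_sd[j])
    col[zs] <- par$zero_mass[j]
    ka <- !is.na(angles)
    col[ka] <- col[ka] * dvonmises(angles[ka], par$angle_mean[j],
                                   par$angle_kappa[j])
    P[, j] <- col
  }
  P
}

# --- working <-> natural parameter transforms -------------------------------

hmm_n2w <- function(par, est_zero) {
  w <- c(log(par$step_mean), log(par$step_sd), par$angle_mean,
         log(par$angle_kappa))
  tr <- par$trans
  off <- c()
  for (i in seq_len(nrow(tr)))
    off <- c(off, log(tr[i, -i] / tr[i, i]))
  w <- c(w, off, log(par$delta[-1] / par$delta[1]))
  if (est_zero) w <- c(w, stats::qlogis(pmin(pmax(par$zero_mass, 1e-6),
                                             1 - 1e-6)))
  w
}

hmm_w2n <- function(w, N, est_zero) {
  i <- 0
  take <- function(k) { v <- w[(i + 1):(i + k)]; i <<- i + k; v }
  step_mean <- exp(take(N)); step_sd <- exp(take(N))
  angle_mean <- ((take(N) + pi) %% (2 * pi)) - pi
  angle_kappa <- exp(take(N))
  trans <- diag(N)
  for (r in seq_len(N)) {
    o <- exp(take(N - 1))
    row <- numeric(N); row[-r] <- o; row[r] <- 1
    trans[r, ] <- row / sum(row)
  }
  dl <- exp(c(0, take(N - 1)))
  delta <- dl / sum(dl)
  zero_mass <- if (est_zero) stats::plogis(take(N)) else rep(0, N)
  list(step_mean = step_mean, step_sd = step_sd,
       angle_mean = angle_mean, angle_kappa = angle_kappa,
       trans = trans, delta = delta, zero_mass = zero_mass)
}

# Relabel states by descending step mean (canonical order).
hmm_relabel <- function(par) {
  o <- order(par$step_mean, decreasing = TRUE)
  list(step_mean = par$step_mean[o], step_sd = par$step_sd[o],
       angle_mean = par$angle_mean[o], angle_kappa = par$angle_kappa[o],
       trans = par$trans[o, o, drop = FALSE], delta = par$delta[o],
       zero_mass = par$zero_mass[o])
}

#' Default starting-value ranges for the movement HMM
#'
#' Uniform ranges from which random starting parameters are drawn, one row
#' per state in canonical order (travel, forage, rest). Step units are km
#' per regularised interval.
#'
#' @return List of 2-column (lo, hi) matrices `step_mean`, `step_sd`,
#'   `angle_kappa`.
#' @export
hmm_start_ranges <- function() {
  list(step_mean = cbind(lo = c(8, 1.5, 0.05), hi = c(25, 6, 1)),
       step_sd = cbind(lo = c(3, 0.8, 0.05), hi = c(15, 4, 1)),
       angle_kappa = cbind(lo = c(3, 0.2, 0.05), hi = c(20, 2, 1)))
}

#' Forward-algorithm log-likelihood of a movement HMM
#'
#' Scaled forward recursion (log space via per-step normalisation),
#' exposed for model comparison and testing.
#'
#' @param steps,angles Observation vectors (km; radians, `NA` allowed).
#' @param par Parameter list as returned by [fit_hmm()] (`$par`).
#' @return Log-likelihood.
#' @export
hmm_loglik <- function(steps, angles, par) {
  P <- hmm_allprobs(steps, angles, par)
  hmm_forward_loglik(P, par$trans, par$delta)
}

#' Fit a multi-state movement HMM by direct likelihood maximisation
#'
#' Maximises the forward-algorithm likelihood over gamma step-length and
#' von Mises turning-angle emission parameters, the transition matrix and
#' the initial distribution, using quasi-Newton optimisation on
#' transformed (log / logit / angular) parameters. The fit is repeated
#' from `n_starts` random starting points drawn within `start_ranges`, and
#' the best fit is returned with states canonically relabelled by
#' descending step mean. Zero step lengths are handled by an explicit
#' per-state point mass at zero, estimated only when zeros are present.
#'
#' @param steps Step lengths (km), `NA` allowed at track boundaries.
#' @param angles Turning angles (radians in (-pi, pi]); `NA` where
#'   undefined; likelihood contribution 1.
#' @param n_states Number of states (default 3).
#' @param n_starts Number of random restarts (default 25).
#' @param start_ranges Ranges from [hmm_start_ranges()].
#' @param seed Integer seed making the restarts reproducible.
#' @param maxit Maximum quasi-Newton iterations per start.
#' @return Object of class `ir_hmm`: `par` (natural parameters), `loglik`,
#'   `all_logliks` (one per start), `n_states`, `convergence` codes.
#' @export
fit_hmm <- function(steps, angles, n_states = 3, n_starts = 25,
                    start_ranges = hmm_start_ranges(), seed = 1L,
                    maxit = 500) {
  ok <- !is.na(steps)
  if (sum(ok) < 100) stop("fit_hmm: need at least 100 steps")
  est_zero <- any(steps[ok] == 0)
  set.seed(seed)
  lsteps <- suppressWarnings(log(steps))
  lsteps[!is.finite(lsteps)] <- 0
  cosang <- cos(angles); sinang <- sin(angles)
  nll <- function(w) {
    par <- hmm_w2n(w, n_states, est_zero)
    v <- hmm_nll_cpp(steps, lsteps, cosang, sinang,
                     par$step_mean, par$step_sd,
                     par$angle_mean, par$angle_kappa, par$trans,
                     par$delta, par$zero_mass)
    if (!is.finite(v)) 1e10 else v
  }
  runif_range <- function(m, k) stats::runif(1, m[k, "lo"], m[k, "hi"])
  best <- NULL
  lls <- rep(NA_real_, n_starts)
  conv <- rep(NA_integer_, n_starts)
  for (s in seq_len(n_starts)) {
    sm <- vapply(seq_len(n_states), function(k)
      runif_range(start_ranges$step_mean, min(k, nrow(start_ranges$step_mean))),
      numeric(1))
    ssd <- vapply(seq_len(n_states), function(k)
      runif_range(start_ranges$step_sd, min(k, nrow(start_ranges$step_sd))),
      numeric(1))
    kap <- vapply(seq_len(n_states), function(k)
      runif_range(start_ranges$angle_kappa,
                  min(k, nrow(start_ranges$angle_kappa))), numeric(1))
    tr <- matrix(0.1 / (n_states - 1), n_states, n_states)
    diag(tr) <- 0.9
    par0 <- list(step_mean = sm, step_sd = ssd,
                 angle_mean = rep(0, n_states), angle_kappa = kap,
                 trans = tr, delta = rep(1 / n_states, n_states),
                 zero_mass = rep(if (est_zero) 0.05 else 0, n_states))
    w0 <- hmm_n2w(par0, est_zero)
    fit <- tryCatch(
      stats::optim(w0, nll, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    lls[s] <- -fit$value
    conv[s] <- fit$convergence
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10)
    stop("fit_hmm: no start converged to a finite likelihood")
  par <- hmm_relabel(hmm_w2n(best$par, n_states, est_zero))
  structure(list(par = par, loglik = -best$value, all_logliks = lls,
                 n_states = n_states, convergence = conv,
                 est_zero_mass = est_zero, seed = seed),
            class = "ir_hmm")
}

#' @export
print.ir_hmm <- function(x, ...) {
  cat(sprintf("<ir_hmm: %d states, logLik %.2f (best of %d starts)>\n",
              x$n_states, x$loglik, length(x$all_logliks)))
  cat("  step mean (km):", sprintf("%.3f", x$par$step_mean), "\n")
  invisible(x)
}

#' Decode the most likely state sequence
#'
#' Viterbi maximum a posteriori path under a fitted HMM; ties are broken
#' toward the lower state index.
#'
#' @param steps,angles Observations as in [fit_hmm()].
#' @param model An `ir_hmm` fit, or a bare parameter list.
#' @return Integer state sequence (1 = largest step mean).
#' @export
decode_states <- function(steps, angles, model) {
  par <- if (inherits(model, "ir_hmm")) model$par else model
  P <- hmm_allprobs(steps, angles, par)
  as.integer(hmm_viterbi(P, par$trans, par$delta))
}

#' Extract putative foraging locations from a decoded trip
#'
#' Maps the decoded per-step states onto fixes (each fix takes the state
#' of the step leading into it; the first fix takes the first step's
#' state) and keeps the fixes decoded as foraging (state 2 under the
#' canonical travel/forage/rest labelling).
#'
#' @param trip Regular trip data frame (`timestamp`, `lon`, `lat`).
#' @param states Integer state sequence from [decode_states()] (length
#'   `nrow(trip) - 1`).
#' @return The foraging-state rows of `trip`.
#' @export
extract_foraging <- function(trip, states) {
  stopifnot(length(states) == nrow(trip) - 1)
  trip[c(states[1], states) == 2L, , drop = FALSE]
}

#' Simulate from a movement HMM
#'
#' Generates a state sequence from the Markov chain and (step, angle)
#' observations from the per-state emission distributions; used for
#' parameter-recovery checks and as a building block of the synthetic
#' track generator.
#'
#' @param n Number of observations.
#' @param par Parameter list (`step_mean`, `step_sd`, `angle_mean`,
#'   `angle_kappa`, `trans`, `delta`, `zero_mass`).
#' @param seed Integer seed.
#' @return List with `states`, `steps`, `angles`.
#' @export
simulate_hmm <- function(n, par, seed = 1L) {
  set.seed(seed)
  N <- length(par$step_mean)
  states <- integer(n)
  states[1] <- sample.int(N, 1, prob = par$delta)
  for (t in 2:n)
    states[t] <- sample.int(N, 1, prob = par$trans[states[t - 1], ])
  shape <- (par$step_mean / par$step_sd)^2
  rate <- par$step_mean / par$step_sd^2
  steps <- stats::rgamma(n, shape = shape[states], rate = rate[states])
  zm <- par$zero_mass[states]
  steps[stats::runif(n) < zm] <- 0
  angles <- rvonmises(n, par$angle_mean[states], par$angle_kappa[states])
  list(states = states, steps = steps, angles = angles)
}

# von Mises sampler (Best & Fisher rejection method).
rvonmises <- function(n, mu, kappa) {
  mu <- rep_len(mu, n); kappa <- rep_len(kappa, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- kappa[i]
    if (k < 1e-8) { out[i] <- stats::runif(1, -pi, pi); next }
    a <- 1 + sqrt(1 + 4 * k^2)
    b <- (a - sqrt(2 * a)) / (2 * k)
    r <- (1 + b^2) / (2 * b)
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- k * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
        break
      }
    }
  }
  (((out + mu) + pi) %% (2 * pi)) - pi
}

#' Step lengths and turning angles of a regular track
#'
#' Steps are geodesic distances between consecutive fixes (km); turning
#' angles are differences of successive planar headings on the projected
#' plane, in (-pi, pi], `NA` at the first two fixes and wherever a
#' duplicate position makes the heading undefined.
#'
#' @param lon,lat Coordinate vectors of a regular track.
#' @return List with `steps` (length n-1) and `angles` (length n-1,
#'   first element `NA`).
#' @export
steps_and_angles <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(list(steps = numeric(0), angles = numeric(0)))
  steps <- gc_dist_km(lon[-n], lat[-n], lon[-1], lat[-1])
  xy <- polar_xy(lon, lat)
  dx <- diff(xy[, "x"]); dy <- diff(xy[, "y"])
  head <- ifelse(dx == 0 & dy == 0, NA_real_, atan2(dx, dy))
  ang <- c(NA_real_, diff(head))
  ang <- ((ang + pi) %% (2 * pi)) - pi
  ang[is.na(head)] <- NA_real_
  list(steps = steps, angles = ang)
}
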