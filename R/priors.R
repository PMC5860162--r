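# Prior specification and the birth/death/swap/move probability schedule.

#' Prior specification for the switch model
#'
#' Defaults follow the settings used for the method's applications: a Poisson
#' prior with small mean on the number of regulators, a Gamma prior on the
#' degradation rate with mean 0.345 per hour (a ~2 h mRNA half-life) and sd
#' 0.1543, a vague scaled inverse-chi-squared prior on the noise variances,
#' and a uniform prior on the variance exponents psi_k. The regulator-set and
#' threshold priors come in a non-informative (`uniform`) and an
#' `informative` mode; the informative set prior weights each candidate
#' proportionally to the range of its smoothed profile across experiments,
#' and the informative threshold prior concentrates on levels the profile
#' traverses (see [informative_tf_weights()],
#' [informative_threshold_density()]).
#'
#' @param lambda Poisson mean for the number of regulators.
#' @param nu_max Maximum regulator-set size; default `min(N, 8)` at run time.
#' @param delta_mean,delta_sd Mean and sd of the Gamma prior on the
#'   degradation rate (per unit time of the data). The Gamma shape and rate
#'   are solved from these: shape = (mean/sd)^2, rate = mean/sd^2.
#' @param sigma_df,sigma_scale Degrees of freedom n0 and scale s0^2 of the
#'   scaled inverse-chi-squared prior on each sigma_k^2.
#' @param tf_prior `"informative"` (range-proportional weights) or
#'   `"uniform"`.
#' @param threshold_prior `"informative"` (gradient-occupation density) or
#'   `"uniform"` over each profile's range.
#' @param pi_bd Upper bound on pi_B(nu) + pi_D(nu), controlling how many
#'   trans-dimensional moves are attempted.
#' @param pi_tilde Split of the remaining probability between threshold
#'   moves (M) and regulator swaps (S).
#' @return Object of class `trs_priors`.
#' @export
trs_priors <- function(lambda = 0.15, nu_max = NULL,
                       delta_mean = 0.345, delta_sd = 0.1543,
                       sigma_df = 0.001, sigma_scale = 0.001,
                       tf_prior = c("informative", "uniform"),
                       threshold_prior = c("informative", "uniform"),
                       pi_bd = 0.5, pi_tilde = 0.5) {
  tf_prior <- match.arg(tf_prior)
  threshold_prior <- match.arg(threshold_prior)
  stopifnot(lambda > 0, delta_mean > 0, delta_sd > 0, sigma_df > 0,
            sigma_scale > 0, pi_bd > 0, pi_bd < 1, pi_tilde > 0, pi_tilde < 1)
  structure(list(lambda = lambda, nu_max = nu_max,
                 delta_mean = delta_mean, delta_sd = delta_sd,
                 delta_shape = (delta_mean / delta_sd)^2,
                 delta_rate = delta_mean / delta_sd^2,
                 sigma_df = sigma_df, sigma_scale = sigma_scale,
                 tf_prior = tf_prior, threshold_prior = threshold_prior,
                 pi_bd = pi_bd, pi_tilde = pi_tilde),
            class = "trs_priors")
}

#' Move-probability schedule
#'
#' Birth and death probabilities follow
#' `pi_B(nu) = c min(1, pi(nu+1)/pi(nu))`,
#' `pi_D(nu) = c min(1, pi(nu-1)/pi(nu))`
#' with `pi(nu)` the Poisson(lambda) prior, so that the balance equation
#' `pi(nu) pi_B(nu) = pi(nu+1) pi_D(nu+1)` holds for every `nu < nu_max`.
#' The constant c is maximized subject to
#' `pi_B(nu) + pi_D(nu) <= pi_bd` over all admissible `nu`. The remaining
#' probability is split between threshold moves (M) and swaps (S) by
#' `pi_tilde`. Birth is disabled at `nu_max`, death at `nu = 1`.
#'
#' @param priors A [trs_priors()] object (uses `lambda`, `pi_bd`,
#'   `pi_tilde`).
#' @param nu_max Maximum set size.
#' @return Data.frame with one row per `nu` in `1:nu_max` and columns
#'   `nu`, `pi_M`, `pi_S`, `pi_B`, `pi_D`, plus attribute `c`.
#' @export
move_schedule <- function(priors, nu_max) {
  stopifnot(nu_max >= 1)
  lambda <- priors$lambda
  nu <- seq_len(nu_max)
  b <- ifelse(nu < nu_max, pmin(1, lambda / (nu + 1)), 0)
  d <- ifelse(nu > 1, pmin(1, nu / lambda), 0)
  mx <- max(b + d)
  cc <- if (mx > 0) priors$pi_bd / mx else 0
  if (nu_max > 1 && cc <= 0) stop("infeasible move schedule: c would be <= 0")
  pi_B <- cc * b
  pi_D <- cc * d
  rest <- 1 - pi_B - pi_D
  out <- data.frame(nu = nu,
                    pi_M = priors$pi_tilde * rest,
                    pi_S = (1 - priors$pi_tilde) * rest,
                    pi_B = pi_B, pi_D = pi_D)
  attr(out, "c") <- cc
  out
}

#' Informative regulator-set prior weights
#'
#' A candidate whose smoothed profile spans a wider range across experiments
#' is a priori more likely to act as a switch; weights are proportional to
#' the range width and normalized to sum to 1. Profiles must be on
#' comparable measurement scales across genes (a property of the input data,
#' not enforced here). In uniform mode every candidate gets weight 1/N.
#'
#' @param data A [trs_data()] object, or a two-column matrix of per-candidate
#'   ranges (min, max).
#' @param mode `"informative"` or `"uniform"`.
#' @return Named numeric vector of weights summing to 1.
#' @export
informative_tf_weights <- function(data, mode = c("informative", "uniform")) {
  mode <- match.arg(mode)
  rng <- if (inherits(data, "trs_data")) data$range else data
  widths <- rng[, 2] - rng[, 1]
  if (mode == "uniform") {
    w <- rep(1 / length(widths), length(widths))
  } else {
    if (all(widths <= 0)) stop("all candidate profiles have zero range")
    w <- widths / sum(widths)
  }
  names(w) <- rownames(rng)
  w
}

#' Informative threshold prior density
#'
#' Transcriptional switches are a priori more likely to be caused by
#' substantial changes in the TF level. The profile (all experiments) is
#' decomposed into maximal monotone runs; a segment of a run traversing a
#' level with slope s contributes mass `|s| * span` per unit level, where
#' `span` is the total level range swept by that run. Levels crossed during
#' large, fast sweeps therefore carry high density, while small noise-scale
#' wiggles around a flat stretch — whose runs have tiny spans — carry almost
#' none. The density is discretized on a level grid over the profile's
#' range across experiments, mixed with a small uniform component for
#' robustness, and normalized to integrate to 1. For a linear ramp it
#' reduces to the uniform density over the range; for a profile that is
#' flat except for one steep jump it concentrates on the jump's span.
#'
#' @param profile A [regulator_profile()].
#' @param nbins Number of level-grid cells.
#' @param eps Uniform mixture weight (0 disables the mixture).
#' @return Object of class `threshold_density`: `breaks` (nbins+1 levels),
#'   `density` (per cell), and the range. Use [threshold_density_at()] to
#'   evaluate.
#' @export
informative_threshold_density <- function(profile, nbins = 256L, eps = 0.01) {
  rng <- profile$range
  if (rng[2] <= rng[1]) stop("degenerate profile: zero range")
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  cw <- diff(breaks)[1]
  mass <- numeric(nbins)
  for (cu in profile$curves) {
    v <- cu$values
    tt <- cu$times
    # maximal monotone runs: a new run starts where the direction flips
    dv <- diff(v)
    run_of <- integer(length(dv))
    cur <- 1L
    last_dir <- 0
    for (i in seq_along(dv)) {
      d_i <- sign(dv[i])
      if (d_i != 0 && last_dir != 0 && d_i != last_dir) cur <- cur + 1L
      if (d_i != 0) last_dir <- d_i
      run_of[i] <- cur
    }
    span <- tapply(abs(dv), run_of, sum)
    for (i in seq_along(dv)) {
      lo <- min(v[i], v[i + 1L]); hi <- max(v[i], v[i + 1L])
      dt <- tt[i + 1L] - tt[i]
      if (hi <= lo || dt <= 0) next
      wgt <- ((hi - lo) / dt) * span[[as.character(run_of[i])]]
      # mass |slope| * run span per unit level over the segment [lo, hi]
      i0 <- max(1L, min(nbins, findInterval(lo, breaks, rightmost.closed = TRUE)))
      i1 <- max(1L, min(nbins, findInterval(hi, breaks, rightmost.closed = TRUE)))
      if (i0 == i1) {
        mass[i0] <- mass[i0] + wgt * (hi - lo)
      } else {
        mass[i0] <- mass[i0] + wgt * (breaks[i0 + 1L] - lo)
        mass[i1] <- mass[i1] + wgt * (hi - breaks[i1])
        if (i1 > i0 + 1L) {
          idx <- (i0 + 1L):(i1 - 1L)
          mass[idx] <- mass[idx] + wgt * cw
        }
      }
    }
  }
  dens <- if (sum(mass) > 0) mass / (sum(mass) * cw) else rep(0, nbins)
  width <- rng[2] - rng[1]
  dens <- (1 - eps) * dens + eps / width
  structure(list(breaks = breaks, density = dens, range = rng,
                 tf_id = profile$tf_id), class = "threshold_density")
}

#' Evaluate a threshold prior density
#'
#' @param td A `threshold_density` object.
#' @param rho Levels at which to evaluate.
#' @return Density values (0 outside the range).
#' @export
threshold_density_at <- function(td, rho) {
  n <- length(td$density)
  i <- findInterval(rho, td$breaks, rightmost.closed = TRUE)
  out <- numeric(length(rho))
  ok <- i >= 1L & i <= n
  out[ok] <- td$density[i[ok]]
  out
}

# elementary symmetric polynomials e_0..e_kmax of w (normalizers of the
# informative set prior over size-nu subsets)
.esym <- function(w, kmax) {
  e <- c(1, rep(0, kmax))
  for (wi in w) {
    upper <- min(kmax + 1, length(e))
    e[2:upper] <- e[2:upper] + wi * e[1:(upper - 1)]
  }
  e
}

# log density of the scaled inverse-chi-squared(n0, s0^2) distribution
.dscinvchisq_log <- function(x, n0, s02) {
  if (any(x <= 0)) return(-Inf)
  h <- n0 / 2
  h * log(h) + h * log(s02) - lgamma(h) - (h + 1) * log(x) - h * s02 / x
}

#' Log prior density of a full parameter state
#'
#' Sums the truncated-Poisson prior on the number of regulators, the
#' regulator-set weight (range-proportional in informative mode, uniform over
#' size-nu subsets otherwise), the per-regulator threshold densities, the
#' Gamma prior on the degradation rate and the scaled inverse-chi-squared
#' priors on the noise variances (the uniform psi terms are constant).
#' Out-of-support values return `-Inf`.
#'
#' @param phi Integer indices of the current regulators.
#' @param rho Their thresholds.
#' @param delta Degradation rate.
#' @param sigma2 Noise variances (one per experiment).
#' @param priors A [trs_priors()] object.
#' @param prior_data Precomputed data-dependent pieces, from
#'   [prior_data()].
#' @return Log prior density.
#' @export
log_prior <- function(phi, rho, delta, sigma2, priors, prior_data) {
  nu <- length(phi)
  pd <- prior_data
  if (nu < 1L || nu > pd$nu_max) return(-Inf)
  if (delta <= 0 || any(sigma2 <= 0)) return(-Inf)
  # thresholds inside ranges
  lo <- pd$range[phi, 1]; hi <- pd$range[phi, 2]
  if (any(rho <= lo | rho >= hi)) return(-Inf)
  lp <- pd$log_pnu[nu]
  if (priors$tf_prior == "informative") {
    lp <- lp + sum(log(pd$weights[phi])) - log(pd$esym[nu + 1L])
  } else {
    lp <- lp - lchoose(pd$N, nu)
  }
  if (priors$threshold_prior == "informative") {
    for (j in seq_len(nu)) {
      dj <- threshold_density_at(pd$thr_dens[[phi[j]]], rho[j])
      if (dj <= 0) return(-Inf)
      lp <- lp + log(dj)
    }
  } else {
    lp <- lp - sum(log(hi - lo))
  }
  lp <- lp + dgamma(delta, shape = priors$delta_shape,
                    rate = priors$delta_rate, log = TRUE)
  lp <- lp + sum(.dscinvchisq_log(sigma2, priors$sigma_df, priors$sigma_scale))
  lp
}

#' Precompute the data-dependent pieces of the prior
#'
#' @param data A [trs_data()] object.
#' @param priors A [trs_priors()] object.
#' @return List with candidate ranges, set weights, threshold densities,
#'   the truncated-Poisson log masses and subset normalizers.
#' @export
prior_data <- function(data, priors) {
  N <- data$N
  nu_max <- if (is.null(priors$nu_max)) min(N, 8L) else min(priors$nu_max, N)
  w <- informative_tf_weights(data, mode = priors$tf_prior)
  lp_raw <- dpois(seq_len(nu_max), priors$lambda, log = TRUE)
  log_pnu <- lp_raw - log(sum(exp(lp_raw - max(lp_raw)))) - max(lp_raw)
  thr_dens <- NULL
  if (priors$threshold_prior == "informative") {
    thr_dens <- lapply(data$profiles, informative_threshold_density)
  }
  list(N = N, nu_max = nu_max, range = data$range, weights = w,
       esym = .esym(w, nu_max), log_pnu = log_pnu, thr_dens = thr_dens)
}

# analytic prior inclusion probabilities (used as an independent check of
# prior-only sampling): P(f in Phi) = sum_nu P(nu) w_f e_{nu-1}(w_{-f}) / e_nu(w)
.prior_inclusion <- function(priors, pd) {
  N <- pd$N
  pnu <- exp(pd$log_pnu)
  if (priors$tf_prior == "uniform") {
    return(setNames(rep(sum(pnu * seq_len(pd$nu_max) / N), N),
                    names(pd$weights)))
  }
  w <- pd$weights
  incl <- numeric(N)
  for (f in seq_len(N)) {
    ef <- .esym(w[-f], pd$nu_max)
    for (nu in seq_len(pd$nu_max)) {
      incl[f] <- incl[f] + pnu[nu] * w[f] * ef[nu] / pd$esym[nu + 1L]
    }
  }
  setNames(incl, names(w))
}
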