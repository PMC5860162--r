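# Reversible-jump MCMC over regulator sets, thresholds, degradation rate
# and noise parameters, with the plug-in weighted least squares likelihood.

#' MCMC configuration
#'
#' @param iterations Total iterations.
#' @param burnin Burn-in fraction in `[0, 1)` (applied by
#'   [summarize_trace()]; the trace records all iterations).
#' @param keep Target number of retained (thinned) draws.
#' @param sigma_rho Threshold-proposal sd as a fraction of each regulator's
#'   profile range (truncated-normal random walk).
#' @param delta_sd Gaussian random-walk sd for the degradation rate.
#' @param seed RNG seed; identical seeds reproduce identical traces.
#' @param psi_grid Grid size for the numerically computed full conditional
#'   of the variance exponents psi_k on `[0, 1]`.
#' @param flat_likelihood Force a constant likelihood so the chain samples
#'   the prior over (set, thresholds); a sampler diagnostic.
#' @param fix_delta Optional numeric: hold the degradation rate fixed at
#'   this value (no random-walk update); used for calibration checks.
#' @param fix_psi Optional numeric (recycled per experiment): hold the
#'   variance exponents fixed.
#' @param progress Print acceptance-rate progress every 10^4 iterations.
#' @return Object of class `trs_mcmc_config`.
#' @export
trs_mcmc_config <- function(iterations = 2e5L, burnin = 0.1, keep = 1e4L,
                            sigma_rho = 0.1, delta_sd = 0.05, seed = 1L,
                            psi_grid = 201L, flat_likelihood = FALSE,
                            fix_delta = NULL, fix_psi = NULL,
                            progress = FALSE) {
  stopifnot(iterations >= 1, burnin >= 0, burnin < 1, keep >= 1,
            sigma_rho > 0, delta_sd > 0, psi_grid >= 2)
  structure(list(iterations = as.integer(iterations), burnin = burnin,
                 keep = as.integer(keep), sigma_rho = sigma_rho,
                 delta_sd = delta_sd, seed = as.integer(seed),
                 psi_grid = as.integer(psi_grid),
                 flat_likelihood = isTRUE(flat_likelihood),
                 fix_delta = fix_delta, fix_psi = fix_psi,
                 progress = isTRUE(progress)),
            class = "trs_mcmc_config")
}

# log density of a normal truncated to (lo, hi)
.dtnorm_log <- function(x, mean, sd, lo, hi) {
  dnorm(x, mean, sd, log = TRUE) -
    log(pnorm(hi, mean, sd) - pnorm(lo, mean, sd))
}

.rtnorm <- function(mean, sd, lo, hi) {
  p <- runif(1, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  x <- qnorm(p, mean, sd)
  min(max(x, lo + 1e-12 * (hi - lo)), hi - 1e-12 * (hi - lo))
}

#' Propose a structure move
#'
#' Draws one of the four structure moves given the current regulator set:
#' M (move a threshold: truncated-normal random walk within the profile
#' range), S (swap a regulator for an excluded one, drawing the new
#' threshold uniformly on its range), B (birth: add an excluded regulator
#' with a uniform threshold), D (death: remove a regulator). Returns the
#' proposed state together with the log proposal ratio
#' `log q(current | proposed) - log q(proposed | current)` used in the
#' Metropolis-Hastings-Green acceptance ratio. Illegal draws (e.g. a swap
#' when every candidate is already included) trigger a move-type resample.
#'
#' @param phi Integer indices of the current regulators (sorted).
#' @param rho Their thresholds.
#' @param schedule Move schedule from [move_schedule()].
#' @param ranges N x 2 matrix of candidate profile ranges.
#' @param sigma_rho Threshold-proposal sd as a fraction of the range.
#' @return List with `move` (one of "M","S","B","D"), `phi`, `rho`,
#'   `log_qratio`, and `tf` (the regulator acted upon).
#' @export
propose_structure_move <- function(phi, rho, schedule, ranges,
                                   sigma_rho = 0.1) {
  N <- nrow(ranges)
  nu <- length(phi)
  probs <- c(schedule$pi_M[nu], schedule$pi_S[nu],
             schedule$pi_B[nu], schedule$pi_D[nu])
  widths <- ranges[, 2] - ranges[, 1]
  # a swap is illegal when every candidate is already included; resampling
  # the move type then renormalizes the remaining probabilities, which the
  # Green ratio must account for on both sides of a dimension jump
  zleg <- function(n) if (n >= N) 1 - schedule$pi_S[n] else 1
  cp <- cumsum(probs)
  repeat {
    u <- runif(1) * cp[4L]
    mv <- if (u < cp[1L]) 1L else if (u < cp[2L]) 2L else
      if (u < cp[3L]) 3L else 4L
    if (mv == 2L && nu >= N) next
    if (mv == 3L && nu >= N) next
    break
  }
  if (mv == 1L) {                                    # M: move a threshold
    j <- sample.int(nu, 1L)
    f <- phi[j]
    lo <- ranges[f, 1]; hi <- ranges[f, 2]
    sdp <- sigma_rho * widths[f]
    rp <- .rtnorm(rho[j], sdp, lo, hi)
    lqr <- .dtnorm_log(rho[j], rp, sdp, lo, hi) -
      .dtnorm_log(rp, rho[j], sdp, lo, hi)
    rho2 <- rho; rho2[j] <- rp
    return(list(move = "M", phi = phi, rho = rho2, log_qratio = lqr, tf = f))
  }
  if (mv == 2L) {                                    # S: swap a regulator
    j <- sample.int(nu, 1L)
    out_f <- phi[j]
    cand <- setdiff(seq_len(N), phi)
    f <- cand[sample.int(length(cand), 1L)]
    rnew <- runif(1, ranges[f, 1], ranges[f, 2])
    phi2 <- phi; rho2 <- rho
    phi2[j] <- f; rho2[j] <- rnew
    ord <- order(phi2)
    lqr <- log(widths[f]) - log(widths[out_f])
    return(list(move = "S", phi = phi2[ord], rho = rho2[ord],
                log_qratio = lqr, tf = f))
  }
  if (mv == 3L) {                                    # B: birth
    cand <- setdiff(seq_len(N), phi)
    f <- cand[sample.int(length(cand), 1L)]
    rnew <- runif(1, ranges[f, 1], ranges[f, 2])
    phi2 <- c(phi, f); rho2 <- c(rho, rnew)
    ord <- order(phi2)
    lqr <- log(schedule$pi_D[nu + 1L] / zleg(nu + 1L)) - log(nu + 1) -
      log(schedule$pi_B[nu] / zleg(nu)) + log(N - nu) + log(widths[f])
    return(list(move = "B", phi = phi2[ord], rho = rho2[ord],
                log_qratio = lqr, tf = f))
  }
  j <- sample.int(nu, 1L)                            # D: death
  f <- phi[j]
  lqr <- log(schedule$pi_B[nu - 1L] / zleg(nu - 1L)) - log(N - nu + 1) -
    log(widths[f]) - log(schedule$pi_D[nu] / zleg(nu)) + log(nu)
  list(move = "D", phi = phi[-j], rho = rho[-j], log_qratio = lqr, tf = f)
}

# conjugate draw of the noise variances: scaled-inv-chisq(n0 + n_k,
# [n0 s0^2 + weighted RSS_k] / (n0 + n_k)) per experiment
.draw_sigma2 <- function(rssw, nk, priors) {
  df <- priors$sigma_df + nk
  scl <- (priors$sigma_df * priors$sigma_scale + rssw) / df
  df * scl / rchisq(length(nk), df)
}

# normalized grid probabilities of the psi_k full conditional, holding the
# current residuals and sigma_k fixed: the likelihood as a function of psi
.psi_grid_probs <- function(r2, Epsi, sumlogw, sigma2, psi_grid) {
  srw <- drop(crossprod(r2, Epsi))
  llg <- psi_grid * sumlogw - 0.5 * srw / sigma2
  p <- exp(llg - max(llg))
  p / sum(p)
}

# fast structure fit inside the sampler; ctx carries precomputed pieces
.mfit <- function(ctx, phi, rho, delta, psi, sigma2, u, part = NULL) {
  if (is.null(part)) {
    part <- .partition(ctx$grids, ctx$P, ctx$horizon, phi, rho)
  }
  D <- .design(part, delta, ctx$times)
  fit <- .wls(D, ctx$y, u)
  rw <- fit$residuals * u            # u = w^psi, so rw^2 sums to rssw
  rssw <- vapply(ctx$idx, function(ix) sum(rw[ix]^2), 0)
  ll <- sum(.loglik_terms(rssw, ctx$nk, ctx$sumlogw, sigma2, psi))
  list(part = part, D = D, coef = fit$coef, residuals = fit$residuals,
       rssw = rssw, loglik = ll, rank_deficient = fit$rank_deficient)
}

# refit with an existing design matrix (delta and partition unchanged)
.mrefit <- function(ctx, D, part, psi, sigma2, u) {
  fit <- .wls(D, ctx$y, u)
  rw <- fit$residuals * u
  rssw <- vapply(ctx$idx, function(ix) sum(rw[ix]^2), 0)
  ll <- sum(.loglik_terms(rssw, ctx$nk, ctx$sumlogw, sigma2, psi))
  list(part = part, D = D, coef = fit$coef, residuals = fit$residuals,
       rssw = rssw, loglik = ll, rank_deficient = fit$rank_deficient)
}

#' Run the reversible-jump sampler
#'
#' Iterates the five sampling steps: (1) a structure move over the regulator
#' set and thresholds accepted by the Metropolis-Hastings-Green ratio of
#' prior, plug-in likelihood and proposal probabilities, (2) a Gaussian
#' random-walk update of the degradation rate, (3) conjugate scaled
#' inverse-chi-squared draws of the noise variances, and (4) grid-based
#' draws of the variance exponents psi_k from their numerically computed
#' full conditionals. The plug-in likelihood replaces the transcription
#' rates and initial conditions by their weighted least squares estimates
#' at every evaluation.
#'
#' @param data A [trs_data()] object.
#' @param priors A [trs_priors()] object.
#' @param config A [trs_mcmc_config()] object.
#' @return Object of class `trs_trace`: thinned draws of the regulator set,
#'   thresholds, degradation rate, transcription rates, initial conditions,
#'   noise parameters and log-likelihood, plus a run manifest with the
#'   configuration echo and acceptance rates by move type.
#' @export
run_trs <- function(data, priors = trs_priors(), config = trs_mcmc_config()) {
  stopifnot(inherits(data, "trs_data"), inherits(priors, "trs_priors"),
            inherits(config, "trs_mcmc_config"))
  t_start <- Sys.time()
  set.seed(config$seed)
  K <- data$K; N <- data$N
  pd <- prior_data(data, priors)
  nu_max <- pd$nu_max
  sched_df <- move_schedule(priors, nu_max)
  # plain-vector view of the schedule for the hot proposal path
  sched <- list(pi_M = sched_df$pi_M, pi_S = sched_df$pi_S,
                pi_B = sched_df$pi_B, pi_D = sched_df$pi_D)
  flat <- config$flat_likelihood

  times <- lapply(data$obs, `[[`, "times")
  nk <- lengths(times)
  idx <- split(seq_len(sum(nk)), rep(seq_len(K), nk))
  logw <- lapply(data$obs, function(o) log(o$w))
  psi_grid <- seq(0, 1, length.out = config$psi_grid)
  ctx <- list(grids = data$grid, P = data$P, horizon = data$horizon,
              times = times, y = unlist(lapply(data$obs, `[[`, "y")),
              nk = nk, idx = idx,
              sumlogw = vapply(logw, sum, 0),
              # per-experiment exp(2 psi log w) tables for the psi grid
              Epsi = lapply(logw, function(lw) exp(outer(2 * lw, psi_grid))))

  # initial state
  phi <- sample.int(N, 1L, prob = pd$weights)
  rho <- (data$range[phi, 1] + data$range[phi, 2]) / 2
  delta <- if (is.null(config$fix_delta)) priors$delta_mean else
    config$fix_delta
  psi <- if (is.null(config$fix_psi)) rep(0.5, K) else
    rep_len(config$fix_psi, K)
  sigma2 <- rep(1, K)
  u <- unlist(lapply(seq_len(K), function(k) exp(psi[k] * logw[[k]])))
  fit <- if (flat) NULL else .mfit(ctx, phi, rho, delta, psi, sigma2, u)
  if (!flat) {
    sigma2 <- pmax(fit$rssw / nk, 1e-8)
    fit$loglik <- sum(.loglik_terms(fit$rssw, nk, ctx$sumlogw, sigma2, psi))
  }
  ll <- if (flat) 0 else fit$loglik
  lp <- log_prior(phi, rho, delta, sigma2, priors, pd)

  iters <- config$iterations
  thin <- max(1L, iters %/% config$keep)
  n_keep <- length(seq(thin, iters, by = thin))
  rec <- list(iter = integer(n_keep), nu = integer(n_keep),
              delta = numeric(n_keep), loglik = numeric(n_keep),
              move = character(n_keep), accepted = logical(n_keep),
              sigma2 = matrix(0, n_keep, K), psi = matrix(0, n_keep, K),
              M0 = matrix(NA_real_, n_keep, K),
              phi = vector("list", n_keep), rho = vector("list", n_keep),
              tau = vector("list", n_keep))
  att <- c(M = 0, S = 0, B = 0, D = 0, delta = 0)
  acc <- c(M = 0, S = 0, B = 0, D = 0, delta = 0)
  n_err <- 0L
  ri <- 0L

  for (it in seq_len(iters)) {
    # --- step 1: structure move ---
    pr <- propose_structure_move(phi, rho, sched, data$range, config$sigma_rho)
    att[pr$move] <- att[pr$move] + 1
    accepted <- FALSE
    fit2 <- NULL
    ll2 <- 0
    ok <- TRUE
    if (!flat) {
      fit2 <- tryCatch(.mfit(ctx, pr$phi, pr$rho, delta, psi, sigma2, u),
                       error = function(e) NULL)
      if (is.null(fit2) || !is.finite(fit2$loglik)) {
        ok <- FALSE
        n_err <- n_err + if (is.null(fit2)) 1L else 0L
      } else {
        ll2 <- fit2$loglik
      }
    }
    if (ok) {
      lp2 <- log_prior(pr$phi, pr$rho, delta, sigma2, priors, pd)
      loga <- (lp2 - lp) + (ll2 - ll) + pr$log_qratio
      if (is.finite(loga) && log(runif(1)) < loga) {
        phi <- pr$phi; rho <- pr$rho
        fit <- fit2; ll <- ll2; lp <- lp2
        accepted <- TRUE
        acc[pr$move] <- acc[pr$move] + 1
      }
    }

    # --- step 2: degradation-rate random walk ---
    att["delta"] <- att["delta"] + 1
    d2 <- if (is.null(config$fix_delta)) delta + rnorm(1, 0, config$delta_sd)
      else -1                              # fixed delta: never update
    if (d2 > 0) {
      if (flat) {
        loga <- dgamma(d2, priors$delta_shape, priors$delta_rate, log = TRUE) -
          dgamma(delta, priors$delta_shape, priors$delta_rate, log = TRUE)
        if (log(runif(1)) < loga) {
          delta <- d2
          acc["delta"] <- acc["delta"] + 1
        }
      } else {
        fit2 <- .mfit(ctx, phi, rho, d2, psi, sigma2, u, part = fit$part)
        loga <- dgamma(d2, priors$delta_shape, priors$delta_rate, log = TRUE) -
          dgamma(delta, priors$delta_shape, priors$delta_rate, log = TRUE) +
          fit2$loglik - ll
        if (is.finite(loga) && log(runif(1)) < loga) {
          delta <- d2; fit <- fit2; ll <- fit$loglik
          acc["delta"] <- acc["delta"] + 1
        }
      }
    }

    # --- step 3: conjugate noise-variance draws ---
    if (!flat) {
      sigma2 <- .draw_sigma2(fit$rssw, nk, priors)
      # --- step 4: variance exponents on the grid ---
      if (is.null(config$fix_psi)) {
        half <- (psi_grid[2] - psi_grid[1]) / 2
        for (k in seq_len(K)) {
          p <- .psi_grid_probs(fit$residuals[idx[[k]]]^2, ctx$Epsi[[k]],
                               ctx$sumlogw[k], sigma2[k], psi_grid)
          ig <- findInterval(runif(1), cumsum(p)) + 1L
          ig <- min(ig, length(psi_grid))
          psi[k] <- min(1, max(0, psi_grid[ig] + runif(1, -half, half)))
        }
        u <- unlist(lapply(seq_len(K), function(k) exp(psi[k] * logw[[k]])))
        fit <- .mrefit(ctx, fit$D, fit$part, psi, sigma2, u)
      } else {
        fit$loglik <- sum(.loglik_terms(fit$rssw, nk, ctx$sumlogw,
                                        sigma2, psi))
      }
      ll <- fit$loglik
      lp <- log_prior(phi, rho, delta, sigma2, priors, pd)
    }

    # --- record ---
    if (it %% thin == 0L) {
      ri <- ri + 1L
      rec$iter[ri] <- it
      rec$nu[ri] <- length(phi)
      rec$delta[ri] <- delta
      rec$loglik[ri] <- ll
      rec$move[ri] <- pr$move
      rec$accepted[ri] <- accepted
      rec$sigma2[ri, ] <- sigma2
      rec$psi[ri, ] <- psi
      rec$phi[[ri]] <- phi
      rec$rho[[ri]] <- rho
      if (!flat) {
        rec$M0[ri, ] <- fit$coef[seq_len(K)]
        q <- fit$part$q
        tau <- fit$coef[K + seq_len(q)]
        names(tau) <- .code_labels(fit$part$states, length(phi))
        rec$tau[[ri]] <- tau
      }
    }
    if (config$progress && it %% 10000L == 0L) {
      message(sprintf("iter %d: acc M %.2f S %.2f B %.2f D %.2f delta %.2f",
                      it, acc["M"] / max(att["M"], 1),
                      acc["S"] / max(att["S"], 1),
                      acc["B"] / max(att["B"], 1),
                      acc["D"] / max(att["D"], 1),
                      acc["delta"] / max(att["delta"], 1)))
    }
  }

  manifest <- list(
    config = unclass(config), priors = unclass(priors),
    nu_max = nu_max, thin = thin, n_kept = ri,
    acceptance_rates = ifelse(att > 0, acc / att, NA_real_),
    attempts = att, fit_errors = n_err,
    runtime_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  structure(c(rec, list(candidates = data$candidates, target = data$target,
                        experiments = data$experiments, K = K,
                        manifest = manifest)),
            class = "trs_trace")
}

#' @export
print.trs_trace <- function(x, ...) {
  m <- x$manifest
  cat("Reversible-jump trace: ", m$n_kept, " retained draws (thin ", m$thin,
      ") from ", m$config$iterations, " iterations\n", sep = "")
  ar <- m$acceptance_rates
  cat("  acceptance rates:",
      paste(names(ar), sprintf("%.2f", ar), collapse = ", "), "\n")
  cat("  runtime:", sprintf("%.1f s", m$runtime_sec), "\n")
  invisible(x)
}
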