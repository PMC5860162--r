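# Model core: activation switches, state enumeration, closed-form ODE
# solution, design matrix, weighted least squares and the log-likelihood.

# ---- low-level helpers (shared by the exported surface and the MCMC) ----

# Crossing times of a piecewise-linear curve (g, v) with a level rho.
# State is 1 where v >= rho (closed on the active side); a crossing time is
# assigned to the following segment. Returns the crossing times and the
# state on [0, first crossing).
.crossings <- function(g, v, rho) {
  n <- length(v)
  s <- v >= rho
  ch <- which(s[-1L] != s[-n])
  tc <- if (length(ch)) {
    g[ch] + (rho - v[ch]) * (g[ch + 1L] - g[ch]) / (v[ch + 1L] - v[ch])
  } else {
    numeric(0)
  }
  list(times = tc, init = s[1L])
}

# Joint state partition for regulator indices phi (sorted) at thresholds rho.
# grids / P: per-experiment time grids and proxy-value matrices; horizon L.
# Returns observed state codes (sum alpha_j 2^(j-1), j indexing sorted phi),
# and per-experiment segments (l, r, sidx) with sidx into the code table.
.partition <- function(grids, P, horizon, phi, rho) {
  nu <- length(phi)
  K <- length(grids)
  seg_l <- vector("list", K)
  codes_all <- integer(0)
  segcode <- vector("list", K)
  pow <- 2^(seq_len(nu) - 1L)
  for (k in seq_len(K)) {
    g <- grids[[k]]
    n <- length(g)
    Pk <- P[[k]]
    tc_list <- vector("list", nu)
    init <- integer(nu)
    for (j in seq_len(nu)) {
      v <- Pk[, phi[j]]
      s <- v >= rho[j]
      ch <- which(s[-1L] != s[-n])
      tc_list[[j]] <- if (length(ch)) {
        g[ch] + (rho[j] - v[ch]) * (g[ch + 1L] - g[ch]) / (v[ch + 1L] - v[ch])
      } else numeric(0)
      init[j] <- as.integer(s[1L])
    }
    brks <- sort.int(unique(c(0, unlist(tc_list), horizon[k])))
    # drop numerically coincident breakpoints
    if (length(brks) > 2L) {
      keep <- c(TRUE, diff(brks) > 1e-10)
      keep[length(brks)] <- TRUE
      brks <- brks[keep]
    }
    l <- brks[-length(brks)]
    r <- brks[-1L]
    ok <- (r - l) > 1e-10
    l <- l[ok]; r <- r[ok]
    # state of TF j at segment start: initial state flipped once per crossing
    # at or before the segment start (crossings belong to the following segment)
    code <- integer(length(l))
    for (j in seq_len(nu)) {
      nflip <- findInterval(l + 1e-9, tc_list[[j]])
      code <- code + pow[j] * ((init[j] + nflip) %% 2L)
    }
    seg_l[[k]] <- list(l = l, r = r)
    segcode[[k]] <- as.integer(code)
    codes_all <- c(codes_all, code)
  }
  states <- sort.int(unique(as.integer(codes_all)))
  segs <- vector("list", K)
  for (k in seq_len(K)) {
    segs[[k]] <- list(l = seg_l[[k]]$l, r = seg_l[[k]]$r,
                      sidx = match(segcode[[k]], states))
  }
  structure(list(states = states, q = length(states), nu = nu, phi = phi,
                 segs = segs, horizon = horizon),
            class = "trs_partition")
}

# Design matrix for the linear regression form of the ODE solution:
# K initial-condition columns exp(-delta t) (per experiment) followed by q
# shared transcription-rate columns with the closed-form integral factors.
# times: list per experiment of observation times (replicates included).
.design <- function(part, delta, times) {
  K <- length(times)
  q <- part$q
  nk <- lengths(times)
  n <- sum(nk)
  D <- matrix(0, n, K + q)
  off <- 0L
  for (k in seq_len(K)) {
    t <- times[[k]]
    ei <- exp(-delta * t)
    idx <- off + seq_along(t)
    D[idx, k] <- ei
    sg <- part$segs[[k]]
    for (i in seq_along(sg$l)) {
      l <- sg$l[i]; r <- sg$r[i]; col <- K + sg$sidx[i]
      # segment factor e^{-dt}(e^{d min(r,t)} - e^{dl})/d: for t >= r this is
      # a constant (e^{dr} - e^{dl})/d times e^{-dt}; inside the segment it
      # reduces to (1 - e^{dl} e^{-dt})/d
      el <- exp(delta * l)
      after <- t >= r
      if (any(after)) {
        D[idx[after], col] <- D[idx[after], col] +
          (exp(delta * r) - el) / delta * ei[after]
      }
      mid <- t > l & t < r
      if (any(mid)) {
        D[idx[mid], col] <- D[idx[mid], col] + (1 - el * ei[mid]) / delta
      }
    }
    off <- off + length(t)
  }
  D
}

# Weighted least squares minimizing sum((y - X b)^2 / v^2); u = 1/v.
# Falls back to the minimum-norm solution when the design is rank deficient.
.wls <- function(X, y, u) {
  Xw <- X * u
  yw <- y * u
  p <- ncol(X)
  z <- .lm.fit(Xw, yw)
  if (z$rank == p) {
    beta <- z$coefficients
    rankdef <- FALSE
  } else {
    sv <- svd(Xw)
    tol <- max(sv$d) * max(dim(Xw)) * .Machine$double.eps
    pos <- sv$d > tol
    beta <- drop(sv$v[, pos, drop = FALSE] %*%
                   (crossprod(sv$u[, pos, drop = FALSE], yw) / sv$d[pos]))
    rankdef <- TRUE
  }
  fit <- drop(X %*% beta)
  list(coef = beta, fitted = fit, residuals = y - fit, rank_deficient = rankdef)
}

# Gaussian log-likelihood with sd sigma_k * v_k(t), v_k = w_k^{-psi_k},
# from per-experiment residuals. rssw_k = sum(r^2 w^{2 psi}) is the
# variance-weighted residual sum of squares.
.loglik_terms <- function(rssw, nk, sumlogw, sigma2, psi) {
  -0.5 * (nk * log(2 * pi * sigma2) - 2 * psi * sumlogw + rssw / sigma2)
}

# ---- exported surface ----

#' Regulator activity profile
#'
#' A continuous (piecewise-linear) regulator activity curve per experiment,
#' with its value range computed jointly across all experiments.
#'
#' @param tf_id Regulator label.
#' @param curves Named list (one element per experiment), each a list with
#'   numeric `times` (strictly increasing, starting at 0) and `values` of the
#'   same length.
#' @return An object of class `regulator_profile`.
#' @export
regulator_profile <- function(tf_id, curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  for (cu in curves) {
    stopifnot(length(cu$times) == length(cu$values), !is.unsorted(cu$times, strictly = TRUE))
  }
  vals <- unlist(lapply(curves, `[[`, "values"))
  rng <- range(vals)
  structure(list(tf_id = tf_id, curves = curves, range = rng,
                 horizon = vapply(curves, function(cu) max(cu$times), 0)),
            class = "regulator_profile")
}

#' Evaluate a regulator profile
#'
#' @param profile A [regulator_profile()].
#' @param experiment Experiment name or index.
#' @param t Times at which to evaluate (linear interpolation, edge-held).
#' @return Numeric vector of activity values.
#' @export
profile_at <- function(profile, experiment, t) {
  cu <- profile$curves[[experiment]]
  approx(cu$times, cu$values, xout = t, rule = 2)$y
}

#' Activation trajectory of one regulator
#'
#' Computes where a regulator's activity curve crosses its activation
#' threshold in each experiment. The regulator is active (state 1) exactly
#' where the curve is at or above the threshold.
#'
#' @param profile A [regulator_profile()].
#' @param threshold Activation threshold; must lie strictly inside the
#'   profile's range across experiments, otherwise the regulator never
#'   changes state anywhere and is redundant.
#' @return An `activation_trajectory`: per experiment, the switch times and
#'   the 0/1 state on each inter-switch segment.
#' @export
compute_activation <- function(profile, threshold) {
  rng <- profile$range
  if (threshold <= rng[1] || threshold >= rng[2]) {
    stop("redundant regulator: threshold outside the profile range (",
         signif(rng[1], 4), ", ", signif(rng[2], 4), ")")
  }
  out <- lapply(profile$curves, function(cu) {
    cr <- .crossings(cu$times, cu$values, threshold)
    m <- length(cr$times)
    states <- (as.integer(cr$init) + (0:m)) %% 2L
    list(switch_times = cr$times, states = states, horizon = max(cu$times))
  })
  structure(list(tf_id = profile$tf_id, experiments = out,
                 threshold = threshold), class = "activation_trajectory")
}

#' Enumerate observed joint activation states
#'
#' Merges the per-regulator switch times into a joint partition of each
#' experiment's time horizon, collects the distinct observed joint states,
#' and assigns every segment to its state. Segments of the same joint state
#' in different experiments map to the same transcription-rate parameter:
#' this is the cross-experiment consistency constraint.
#'
#' @param trajectories List of `activation_trajectory` objects (one per
#'   regulator), all defined over the same experiments.
#' @return A `trs_partition` with elements `states` (integer codes, bit j set
#'   when regulator j is active), `states_matrix` (q x nu 0/1 matrix), and
#'   `segs` (per experiment: segment bounds `l`, `r` and state index `sidx`).
#' @export
enumerate_states <- function(trajectories) {
  stopifnot(length(trajectories) >= 1L)
  nu <- length(trajectories)
  exps <- names(trajectories[[1]]$experiments)
  K <- length(trajectories[[1]]$experiments)
  pow <- 2^(seq_len(nu) - 1L)
  horizon <- vapply(trajectories[[1]]$experiments, `[[`, 0, "horizon")
  segs_raw <- vector("list", K)
  codes_all <- integer(0)
  for (k in seq_len(K)) {
    sw <- lapply(trajectories, function(tr) tr$experiments[[k]]$switch_times)
    L <- trajectories[[1]]$experiments[[k]]$horizon
    brks <- sort(unique(c(0, unlist(sw), L)))
    if (length(brks) > 2L) {
      keep <- c(TRUE, diff(brks) > 1e-10); keep[length(brks)] <- TRUE
      brks <- brks[keep]
    }
    l <- brks[-length(brks)]; r <- brks[-1L]
    ok <- (r - l) > 1e-10
    l <- l[ok]; r <- r[ok]
    alpha <- matrix(0L, length(l), nu)
    for (j in seq_len(nu)) {
      trj <- trajectories[[j]]$experiments[[k]]
      nflip <- findInterval(l + 1e-9, trj$switch_times)
      alpha[, j] <- (trj$states[1L] + nflip) %% 2L
    }
    code <- as.integer(alpha %*% pow)
    segs_raw[[k]] <- list(l = l, r = r, code = code)
    codes_all <- c(codes_all, code)
  }
  states <- sort(unique(codes_all))
  segs <- lapply(segs_raw, function(s) list(l = s$l, r = s$r,
                                            sidx = match(s$code, states)))
  names(segs) <- exps
  sm <- t(vapply(states, function(cd) as.integer(bitwAnd(cd, pow) > 0),
                 integer(nu)))
  structure(list(states = states, states_matrix = sm, q = length(states),
                 nu = nu, phi = vapply(trajectories, `[[`, "", "tf_id"),
                 segs = segs, horizon = horizon),
            class = "trs_partition")
}

#' Closed-form solution of the switch ODE
#'
#' Evaluates M(t) solving dM/dt = tau(t) - delta M(t) with M(0) = M0, where
#' tau(t) is piecewise constant on the state partition of one experiment:
#' each segment `[l, r)` of state i with `l < t` contributes
#' `tau_i (e^{-delta (t - min(r, t))} - e^{-delta (t - l)}) / delta`.
#'
#' @param t Times at which to evaluate.
#' @param delta Degradation rate (> 0).
#' @param M0 Initial condition at t = 0.
#' @param partition A `trs_partition` (from [enumerate_states()]).
#' @param tau Transcription rates, one per observed state (indexed as
#'   `partition$states`).
#' @param experiment Which experiment of the partition to use (default 1).
#' @return Numeric vector M(t).
#' @export
solve_trs_ode <- function(t, delta, M0, partition, tau, experiment = 1L) {
  if (delta <= 0) stop("delta must be positive")
  sg <- partition$segs[[experiment]]
  stopifnot(length(tau) == partition$q)
  M <- M0 * exp(-delta * t)
  for (i in seq_along(sg$l)) {
    l <- sg$l[i]; r <- sg$r[i]
    act <- t > l
    if (any(act)) {
      ta <- t[act]; tm <- pmin(r, ta)
      M[act] <- M[act] + tau[sg$sidx[i]] *
        (exp(-delta * (ta - tm)) - exp(-delta * (ta - l))) / delta
    }
  }
  M
}

#' Design matrix of the linearized ODE solution
#'
#' For fixed thresholds and degradation rate the ODE solution is linear in
#' the initial conditions and the per-state transcription rates. Rows are the
#' concatenated observations across experiments; the first K columns are
#' `exp(-delta t)` indicators for the per-experiment initial conditions, the
#' remaining q columns (shared across all experiments) carry the closed-form
#' integral factors of each observed state.
#'
#' @param partition A `trs_partition`.
#' @param delta Degradation rate (> 0).
#' @param times List of observation-time vectors, one per experiment
#'   (replicate observations included as separate entries).
#' @return Numeric matrix with `sum(lengths(times))` rows and `K + q`
#'   columns; attribute `rank_deficient` is set by [wls_fit()] consumers.
#' @export
build_design <- function(partition, delta, times) {
  if (delta <= 0) stop("delta must be positive")
  if (!is.list(times)) times <- list(times)
  .design(partition, delta, times)
}

#' Weighted least squares fit
#'
#' Minimizes `sum((y - X beta)^2 / v^2)` for a known variance scale v (so the
#' effective weights are 1/v^2). With `v = 1` this is ordinary least squares.
#' A rank-deficient design triggers a warning and the minimum-norm solution.
#'
#' @param y Response vector.
#' @param design Design matrix.
#' @param variance_scale Per-observation standard-deviation scale v (recycled).
#' @return List with `coef`, `fitted`, `residuals`, `rank_deficient`.
#' @export
wls_fit <- function(y, design, variance_scale = 1) {
  u <- rep_len(1 / variance_scale, length(y))
  out <- .wls(design, y, u)
  if (out$rank_deficient) {
    warning("rank-deficient design: returning the minimum-norm solution")
  }
  out
}

#' Gaussian log-likelihood of the switch model
#'
#' Evaluates the observation log-likelihood with per-experiment noise scale
#' `sigma_k` and variance model `sd_k(t) = sigma_k * w_k(t)^(-psi_k)`:
#' `-1/2 sum_k sum_i [log(2 pi sigma_k(t_i)^2) + r_{k,i}^2 / sigma_k(t_i)^2]`.
#'
#' @param y List of observation vectors, one per experiment (or one vector).
#' @param fitted List of fitted values matching `y`.
#' @param sigma Per-experiment noise scales (> 0).
#' @param psi Per-experiment variance exponents in `[0, 1]`.
#' @param w Optional list of positive weight functions evaluated at the
#'   observation times (default 1: homoscedastic).
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(y, fitted, sigma, psi = 0, w = NULL) {
  if (!is.list(y)) { y <- list(y); fitted <- list(fitted) }
  K <- length(y)
  sigma <- rep_len(sigma, K)
  psi <- rep_len(psi, K)
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(psi < 0 | psi > 1)) stop("psi must lie in [0, 1]")
  ll <- 0
  for (k in seq_len(K)) {
    wk <- if (is.null(w)) rep(1, length(y[[k]])) else rep_len(w[[k]], length(y[[k]]))
    if (any(wk <= 0)) stop("weights must be positive")
    r <- y[[k]] - fitted[[k]]
    lw <- log(wk)
    ll <- ll + .loglik_terms(sum(r^2 * exp(2 * psi[k] * lw)), length(r),
                             sum(lw), sigma[k]^2, psi[k])
  }
  ll
}

#' Fit the switch model for a fixed structure
#'
#' Composes activation, state enumeration, design construction, weighted
#' least squares and the log-likelihood for a given regulator set and
#' thresholds. The resulting plug-in likelihood (least-squares estimates
#' substituted for the transcription rates and initial conditions) is the
#' likelihood used by all MCMC acceptance ratios.
#'
#' @param data A [trs_data()] object.
#' @param phi Character vector of regulator names (subset of
#'   `data$candidates`), or integer indices.
#' @param rho Thresholds, one per regulator, each strictly inside that
#'   regulator's profile range.
#' @param delta Degradation rate (> 0).
#' @param sigma Per-experiment noise scales; default: estimated from the
#'   residuals of the fit itself (plug-in).
#' @param psi Per-experiment variance exponents (default 0, homoscedastic).
#' @return List with `partition`, `coef` (initial conditions then per-state
#'   transcription rates), `M0`, `tau` (named by state code), `fitted`,
#'   `residuals`, `loglik`, `rss`, `rank_deficient`.
#' @export
fit_given_structure <- function(data, phi, rho, delta, sigma = NULL, psi = 0) {
  stopifnot(inherits(data, "trs_data"))
  if (is.character(phi)) phi <- match(phi, data$candidates)
  if (anyNA(phi)) stop("unknown regulator in phi")
  ord <- order(phi)
  phi <- phi[ord]; rho <- rho[ord]
  for (j in seq_along(phi)) {
    rng <- data$range[phi[j], ]
    if (rho[j] <= rng[1] || rho[j] >= rng[2]) {
      stop("redundant regulator: threshold of ", data$candidates[phi[j]],
           " outside its profile range")
    }
  }
  if (delta <= 0) stop("delta must be positive")
  K <- data$K
  psi <- rep_len(psi, K)
  part <- .partition(data$grid, data$P, data$horizon, phi, rho)
  times <- lapply(data$obs, `[[`, "times")
  D <- .design(part, delta, times)
  u <- unlist(lapply(seq_len(K), function(k) data$obs[[k]]$w^psi[k]))
  y <- unlist(lapply(data$obs, `[[`, "y"))
  fit <- .wls(D, y, u)
  nk <- lengths(times)
  grp <- rep(seq_len(K), nk)
  res_by <- split(fit$residuals, grp)
  rssw <- vapply(seq_len(K), function(k)
    sum(res_by[[k]]^2 * data$obs[[k]]$w^(2 * psi[k])), 0)
  if (is.null(sigma)) {
    sigma <- sqrt(pmax(rssw / nk, 1e-12))
  } else {
    sigma <- rep_len(sigma, K)
  }
  sumlogw <- vapply(seq_len(K), function(k) sum(log(data$obs[[k]]$w)), 0)
  ll <- sum(.loglik_terms(rssw, nk, sumlogw, sigma^2, psi))
  q <- part$q
  tau <- fit$coef[K + seq_len(q)]
  names(tau) <- .code_labels(part$states, part$nu)
  list(partition = part, coef = fit$coef,
       M0 = setNames(fit$coef[seq_len(K)], data$experiments),
       tau = tau, fitted = split(fit$fitted, grp), residuals = res_by,
       rss = vapply(res_by, function(r) sum(r^2), 0), rssw = rssw,
       sigma = sigma, psi = psi, loglik = ll,
       rank_deficient = fit$rank_deficient, design = D)
}

# human-readable binary labels for state codes, low bit = first regulator
.code_labels <- function(codes, nu) {
  vapply(codes, function(cd)
    paste(as.integer(bitwAnd(cd, 2^(seq_len(nu) - 1L)) > 0), collapse = ""),
    "")
}

#' @export
print.trs_partition <- function(x, ...) {
  cat("Joint activation-state partition:", x$q, "observed state(s) of",
      x$nu, "regulator(s)\n")
  lbl <- .code_labels(x$states, x$nu)
  for (k in seq_along(x$segs)) {
    sg <- x$segs[[k]]
    cat("  experiment", k, ": ",
        paste(sprintf("[%.3g,%.3g)=%s", sg$l, sg$r, lbl[sg$sidx]),
              collapse = " "), "\n")
  }
  invisible(x)
}
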