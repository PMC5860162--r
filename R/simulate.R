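# Seeded generators for the two benchmark regulation studies and a generic
# exact-model sampler. Profiles are deterministic ODE/sigmoid shapes scaled
# by an amplitude Omega, observed with i.i.d. Gaussian measurement noise at
# irregular sampling times shared across replicates.

.sig <- function(t, t0, k = 2) 1 / (1 + exp(-k * (t - t0)))

.hill_up <- function(x, K = 0.5, n = 40) {
  xn <- pmax(x, 0)^n
  xn / (xn + K^n)
}

# irregular sampling times: 0, then spacings uniform in `spacing`, capped at L
.sample_times <- function(horizon, spacing) {
  t <- 0
  repeat {
    nxt <- t[length(t)] + runif(1, spacing[1], spacing[2])
    if (nxt >= horizon) break
    t <- c(t, nxt)
  }
  c(t, horizon)
}

# first-order translation filter with unit steady-state gain; infinite
# turnover means the protein tracks the mRNA exactly
.protein_filter <- function(tg, m, deg) {
  if (!is.finite(deg)) return(m)
  .translate_ode(tg, m, deg, deg, m[1])
}

# integrate dM/dt = tau(t) - delta M with tau given on a fine grid, by exact
# exponential stepping with midpoint transcription rate
.integrate_linear_ode <- function(tgrid, tau, delta, M0) {
  n <- length(tgrid)
  M <- numeric(n)
  M[1] <- M0
  for (i in seq_len(n - 1L)) {
    h <- tgrid[i + 1L] - tgrid[i]
    tm <- (tau[i] + tau[i + 1L]) / 2
    ed <- exp(-delta * h)
    M[i + 1L] <- M[i] * ed + tm * (1 - ed) / delta
  }
  M
}

#' Simulate the repressed-activation benchmark study
#'
#' A target gene and six candidate TFs observed in two experimental
#' conditions. The target's transcription is driven by a Hill-type rate law
#' in which f1 activates and f2 represses that activation: the rate is high
#' only while f1 is active and f2 is not. The remaining candidates are
#' designed confounders: f3 shares f2's experiment-2 shape in both
#' experiments, f4 is constant-low in experiment 1 and constant-high in
#' experiment 2, f5 is a reflection of f2 observed with substantially
#' noisier measurements (an AND-activation alternative whose smoothed
#' profile is less reliable), and f6 has f1's shape with a
#' smaller range. Profiles are `Omega * h(t)` plus i.i.d. Gaussian noise;
#' sampling times are irregular (spacings uniform in `spacing`) and shared
#' by all replicates of an experiment.
#'
#' The switches act on the regulators' nuclear protein levels, modelled as
#' first-order translation filters of their mRNA (`dP/dt = delta_p (M - P)`),
#' while only mRNA is observed — as in expression-profiling experiments. The
#' mild protein/mRNA mismatch this induces is part of the study design.
#'
#' @param seed RNG seed (identical seeds give identical datasets).
#' @param replicates Replicates per experiment.
#' @param omega Amplitude scaling of the deterministic profiles.
#' @param noise_sd Measurement noise sd (default `omega / 20`).
#' @param horizon Observation horizon (hours).
#' @param spacing Range of sampling-time spacings (hours).
#' @param delta True mRNA degradation rate of the target (per hour).
#' @param protein_deg Protein turnover rate of the translation filter
#'   (per hour).
#' @return A list of class `trs_sim` with `data` (long-format data.frame:
#'   experiment, replicate, time, gene, value), `truth` (true regulators,
#'   thresholds, transcription rates, degradation rate, initial conditions,
#'   noise sd) and `study`.
#' @export
simulate_repressed_activation <- function(seed = 1L, replicates = 4L,
                                          omega = 1000, noise_sd = omega / 20,
                                          horizon = 10, spacing = c(0.5, 1.5),
                                          delta = 0.345, protein_deg = 1.5) {
  set.seed(seed)
  K <- 2L
  b0 <- 0.1; b1 <- 0.65           # baseline and activated rate (levels / Omega)
  # deterministic shapes h(t) per experiment; f1 crosses 0.5 upward at t=2
  # (exp 1) and downward at t=7 (exp 2); f2 crosses upward at t=6 / t=3
  h <- list(
    f1 = list(function(t) 0.1 + 0.8 * .sig(t, 2),
              function(t) 0.9 - 0.8 * .sig(t, 7)),
    f2 = list(function(t) 0.1 + 0.8 * .sig(t, 6),
              function(t) 0.1 + 0.8 * .sig(t, 3)),
    f3 = list(function(t) 0.1 + 0.8 * .sig(t, 3),
              function(t) 0.1 + 0.8 * .sig(t, 3)),
    f4 = list(function(t) rep(0.15, length(t)),
              function(t) rep(0.85, length(t))),
    f5 = list(function(t) 0.9 - 0.8 * .sig(t, 6),
              function(t) 0.9 - 0.8 * .sig(t, 3)),
    f6 = list(function(t) 0.5 + 0.32 * (.sig(t, 2) - 0.5),
              function(t) 0.5 - 0.32 * (.sig(t, 7) - 0.5))
  )
  tg <- seq(0, horizon, by = 0.005)
  target_curve <- vector("list", K)
  M0 <- numeric(K)
  switch_times <- vector("list", K)
  for (k in seq_len(K)) {
    # switches act on the protein level: a first-order translation filter of
    # the mRNA shape (steady-state gain 1, turnover protein_deg)
    p1 <- .protein_filter(tg, h$f1[[k]](tg), protein_deg)
    p2 <- .protein_filter(tg, h$f2[[k]](tg), protein_deg)
    gate <- .hill_up(p1) * (1 - .hill_up(p2))
    tau <- omega * delta * (b0 + b1 * gate)
    M0[k] <- tau[1] / delta                 # start at the local steady state
    target_curve[[k]] <- .integrate_linear_ode(tg, tau, delta, M0[k])
    switch_times[[k]] <- sort(c(.crossings(tg, p1, 0.5)$times,
                                .crossings(tg, p2, 0.5)$times))
  }
  times <- lapply(seq_len(K), function(k) .sample_times(horizon, spacing))
  genes <- c("target", names(h))
  rows <- list()
  for (k in seq_len(K)) {
    tt <- times[[k]]
    for (g in genes) {
      det <- if (g == "target") {
        approx(tg, target_curve[[k]], xout = tt)$y
      } else {
        omega * h[[g]][[k]](tt)
      }
      # f5 is observed with substantially noisier measurements, making its
      # smoothed profile a less reliable switch than its mirror image f2
      sd_g <- if (g == "f5") 2.5 * noise_sd else noise_sd
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          experiment = paste0("exp", k), replicate = paste0("rep", r),
          time = tt, gene = g,
          value = pmax(det + rnorm(length(tt), 0, sd_g), 0))
      }
    }
  }
  truth <- list(
    phi = c("f1", "f2"), rho = c(f1 = 0.5 * omega, f2 = 0.5 * omega),
    tau = c("00" = omega * delta * b0, "10" = omega * delta * (b0 + b1),
            "01" = omega * delta * b0, "11" = omega * delta * b0),
    delta = delta, M0 = M0, sigma = noise_sd, omega = omega,
    protein_deg = protein_deg,
    switch_times = setNames(switch_times, paste0("exp", seq_len(K))))
  structure(list(data = do.call(rbind, rows), truth = truth,
                 study = "repressed_activation", seed = seed),
            class = "trs_sim")
}

#' Simulate the SOC1 flowering-time benchmark study
#'
#' Emulates the regulation of the Arabidopsis flowering-time integrator gene
#' SOC1 within its published network: five regulators — the activators FT
#' and AGL24, the repressors SVP and FLC, and SOC1 itself through positive
#' auto-regulation — plus three network genes that are not regulators of
#' SOC1 (FD, AP1, LFY) and CO, observed in four experimental conditions over
#' 10 days. The rate law combines OR-type Hill activation by FT/AGL24 and
#' the auto-regulatory term, gated by Hill repression from SVP and FLC.
#' Experiments differ in which regulators switch and when, so that each true
#' regulator's threshold is pinned down by at least one condition.
#'
#' As in the repressed-activation study, the switches act on first-order
#' protein transforms of the regulators' mRNA shapes while only mRNA is
#' observed; the auto-regulatory term senses the target's own mRNA level.
#'
#' @inheritParams simulate_repressed_activation
#' @param horizon Observation horizon (days).
#' @param delta True mRNA degradation rate of the target (per day).
#' @param protein_deg Protein turnover rate of the translation filter
#'   (per day).
#' @return A `trs_sim` list; the target gene is `"SOC1"`, which is also a
#'   candidate regulator of itself.
#' @export
simulate_soc1 <- function(seed = 1L, replicates = 4L, omega = 1000,
                          noise_sd = omega / 20, horizon = 10,
                          spacing = c(0.5, 1.5), delta = 0.345,
                          protein_deg = 4) {
  set.seed(seed)
  K <- 4L
  # full sigmoid transitions (crossing the mid level) and gentle partial
  # drifts (staying on one side of it); no profile sits exactly flat, as
  # in ODE-driven expression dynamics
  up <- function(t0) function(t) 0.1 + 0.8 * .sig(t, t0, k = 3)
  dn <- function(t0) function(t) 0.9 - 0.8 * .sig(t, t0, k = 3)
  low <- function(t0, a = 0.15) function(t) 0.1 + a * .sig(t, t0)
  high <- function(t0, a = 0.15) function(t) 0.95 - a * .sig(t, t0)
  h <- list(
    FT    = list(up(2),       low(7),      up(5),        high(6, 0.12)),
    AGL24 = list(up(4),       up(2),       low(3),       up(6)),
    # SVP releases the target early in condition 1 and represses it again
    # late, so the target rises and then falls within that condition
    SVP   = list(function(t) 0.9 - 0.8 * .sig(t, 3, k = 3) +
                   0.8 * .sig(t, 8, k = 3),
                 dn(6),       low(5, 0.12), dn(2)),
    FLC   = list(low(6, 0.1), dn(3),       low(4, 0.12), high(5)),
    # each non-regulator has one full transition in a single condition and
    # small one-sided drifts elsewhere, as slowly-responding network genes
    FD    = list(low(1, 0.05), low(5, 0.05), low(2, 0.05), up(3)),
    AP1   = list(low(9, 0.05), low(9, 0.05), low(8, 0.05), up(8)),
    LFY   = list(low(2, 0.05), low(4.5, 0.05), low(3.5, 0.05), up(5.5)),
    CO    = list(high(3, 0.05), high(8, 0.05), up(0.7),   high(5, 0.05))
  )
  b0 <- 0.06; bFT <- 0.31; bAG <- 0.31; bAUTO <- 0.32
  auto_K <- 0.18
  tg <- seq(0, horizon, by = 0.005)
  target_curve <- vector("list", K)
  M0 <- numeric(K)
  for (k in seq_len(K)) {
    prot <- function(f) .protein_filter(tg, h[[f]][[k]](tg), protein_deg)
    gFT <- .hill_up(prot("FT")); gAG <- .hill_up(prot("AGL24"))
    rep_gate <- (1 - .hill_up(prot("SVP"))) * (1 - .hill_up(prot("FLC")))
    # auto-regulation makes the rate depend on M itself: step the ODE,
    # starting from the self-consistent steady state of the t=0 rate
    n <- length(tg)
    M <- numeric(n)
    M[1] <- omega * (b0 + (bFT * gFT[1] + bAG * gAG[1]) * rep_gate[1])
    for (it in 1:8) {     # fixed-point refinement of the auto term at t=0
      gM0 <- .hill_up(M[1] / omega, auto_K)
      M[1] <- omega *
        (b0 + (bFT * gFT[1] + bAG * gAG[1] + bAUTO * gM0) * rep_gate[1])
    }
    for (i in seq_len(n - 1L)) {
      hh <- tg[i + 1L] - tg[i]
      gM <- .hill_up(M[i] / omega, auto_K)
      tau_i <- omega * delta *
        (b0 + (bFT * gFT[i] + bAG * gAG[i] + bAUTO * gM) * rep_gate[i])
      ed <- exp(-delta * hh)
      M[i + 1L] <- M[i] * ed + tau_i * (1 - ed) / delta
    }
    M0[k] <- M[1]
    target_curve[[k]] <- M
  }
  times <- lapply(seq_len(K), function(k) .sample_times(horizon, spacing))
  genes <- c("SOC1", names(h))
  rows <- list()
  for (k in seq_len(K)) {
    tt <- times[[k]]
    for (g in genes) {
      det <- if (g == "SOC1") {
        approx(tg, target_curve[[k]], xout = tt)$y
      } else {
        omega * h[[g]][[k]](tt)
      }
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          experiment = paste0("exp", k), replicate = paste0("rep", r),
          time = tt, gene = g,
          value = pmax(det + rnorm(length(tt), 0, noise_sd), 0))
      }
    }
  }
  truth <- list(
    phi = c("SOC1", "FT", "AGL24", "SVP", "FLC"),
    rho = c(SOC1 = auto_K * omega, FT = 0.5 * omega, AGL24 = 0.5 * omega,
            SVP = 0.5 * omega, FLC = 0.5 * omega),
    repressors = c("SVP", "FLC"),
    delta = delta, M0 = M0, sigma = noise_sd, omega = omega)
  structure(list(data = do.call(rbind, rows), truth = truth,
                 study = "soc1", seed = seed),
            class = "trs_sim")
}

#' Simulate data exactly from the switch model
#'
#' Generates a dataset whose target follows the closed-form switch-ODE
#' solution exactly for a given regulator structure, with Gaussian noise of
#' sd `sigma_k * w_k(t)^(-psi_k)`. The gold-standard input for
#' parameter-recovery checks.
#'
#' @param profiles Named list of [regulator_profile()] objects (the
#'   candidate regulators; must share experiments).
#' @param phi Names of the true regulators (subset of `names(profiles)`).
#' @param rho Their thresholds (same order as `phi`).
#' @param tau Named transcription rates; names are the joint activation
#'   states as 0/1 strings with position j for the j-th regulator in `phi`
#'   order sorted by profile position (e.g. `"10"`). Every observed state
#'   must be present.
#' @param delta Degradation rate.
#' @param M0 Initial conditions, one per experiment.
#' @param sigma Noise sd per experiment (recycled).
#' @param psi Variance exponents per experiment (default 0: homoscedastic).
#' @param w Optional list of weight functions of time per experiment (for
#'   `psi > 0`).
#' @param times List of observation-time vectors per experiment; default:
#'   irregular times as in the benchmark studies.
#' @param replicates Replicates per experiment.
#' @param seed RNG seed.
#' @return A `trs_sim` list with `data`, `profiles_df` (noiseless candidate
#'   profiles in long format, usable as the `profiles` argument of
#'   [trs_data()]) and `truth`.
#' @export
simulate_from_trs <- function(profiles, phi, rho, tau, delta, M0,
                              sigma = 1, psi = 0, w = NULL, times = NULL,
                              replicates = 1L, seed = 1L) {
  set.seed(seed)
  stopifnot(all(phi %in% names(profiles)))
  K <- length(profiles[[1]]$curves)
  exps <- names(profiles[[1]]$curves)
  if (is.null(exps)) exps <- paste0("exp", seq_len(K))
  sigma <- rep_len(sigma, K)
  psi <- rep_len(psi, K)
  M0 <- rep_len(M0, K)
  # order regulators by their position in `profiles` for stable state codes
  ord <- order(match(phi, names(profiles)))
  phi <- phi[ord]; rho <- rho[ord]
  traj <- lapply(seq_along(phi), function(j)
    compute_activation(profiles[[phi[j]]], rho[j]))
  part <- enumerate_states(traj)
  lbl <- .code_labels(part$states, part$nu)
  if (!all(lbl %in% names(tau))) {
    stop("tau missing for observed state(s): ",
         paste(setdiff(lbl, names(tau)), collapse = ", "))
  }
  tau_vec <- unname(tau[lbl])
  if (is.null(times)) {
    times <- lapply(seq_len(K), function(k)
      .sample_times(part$horizon[k], c(0.5, 1.5)))
  }
  rows <- list()
  prof_rows <- list()
  for (k in seq_len(K)) {
    tt <- times[[k]]
    Mk <- solve_trs_ode(tt, delta, M0[k], part, tau_vec, experiment = k)
    vk <- if (is.null(w)) rep(1, length(tt)) else w[[k]](tt)^(-psi[k])
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = exps[k], replicate = paste0("rep", r), time = tt,
        gene = "target", value = Mk + rnorm(length(tt), 0, sigma[k] * vk))
    }
    for (g in names(profiles)) {
      pv <- profile_at(profiles[[g]], k, tt)
      prof_rows[[length(prof_rows) + 1L]] <- data.frame(
        experiment = exps[k], time = tt, gene = g, value = pv)
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          experiment = exps[k], replicate = paste0("rep", r), time = tt,
          gene = g, value = pv)
      }
    }
  }
  truth <- list(phi = phi, rho = setNames(rho, phi), tau = tau, delta = delta,
                M0 = M0, sigma = sigma, psi = psi, partition = part)
  structure(list(data = do.call(rbind, rows),
                 profiles_df = do.call(rbind, prof_rows),
                 truth = truth, study = "exact_trs", seed = seed),
            class = "trs_sim")
}

#' @export
print.trs_sim <- function(x, ...) {
  cat("Simulated study '", x$study, "' (seed ", x$seed, "): ",
      length(unique(x$data$gene)), " genes, ",
      length(unique(x$data$experiment)), " experiments, ",
      nrow(x$data), " rows\n", sep = "")
  invisible(x)
}
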