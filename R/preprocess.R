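# Preprocessing: smoothing-spline regulator profiles, wild-bootstrap noise
# characterization, and protein-proxy construction.

#' Smooth an expression time series
#'
#' Fits a cross-validated (GCV) smoothing spline per experiment, pooling
#' replicates, to derive a continuous expression profile.
#'
#' @param df Long-format data.frame for one gene with columns `experiment`,
#'   `replicate`, `time`, `value`.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; default: chosen by generalized
#'   cross-validation.
#' @param df_frac Cap on the equivalent degrees of freedom as a fraction of
#'   the number of distinct time points (ignored when `spar` is given).
#'   GCV tends to undersmooth short replicated series, and the resulting
#'   wiggle propagates into spurious threshold crossings; the cap bounds
#'   the fit's roughness without touching well-behaved GCV choices. `NULL`
#'   disables the cap.
#' @return Object of class `smoothed_profile`: per experiment the spline
#'   fit, the observation times, fitted values and residuals.
#' @export
smooth_profile <- function(df, spar = NULL, df_frac = 0.6) {
  stopifnot(all(c("experiment", "time", "value") %in% names(df)))
  experiments <- unique(df$experiment)
  fits <- lapply(experiments, function(e) {
    sel <- df$experiment == e
    tt <- df$time[sel] - min(df$time[sel])
    yy <- df$value[sel]
    n_u <- length(unique(tt))
    if (n_u < 4L) {
      stop("need at least 4 distinct time points per experiment to smooth")
    }
    fit <- if (is.null(spar)) smooth.spline(tt, yy) else
      smooth.spline(tt, yy, spar = spar)
    if (is.null(spar) && !is.null(df_frac)) {
      df_max <- max(4, df_frac * n_u)
      if (fit$df > df_max) fit <- smooth.spline(tt, yy, df = df_max)
    }
    fv <- predict(fit, tt)$y
    list(fit = fit, times = tt, y = yy, fitted = fv, residuals = yy - fv,
         horizon = max(tt))
  })
  names(fits) <- experiments
  structure(list(gene = df$gene[1], experiments = fits),
            class = "smoothed_profile")
}

#' Evaluate a smoothed profile
#'
#' @param sp A [smooth_profile()] result.
#' @param experiment Experiment name or index.
#' @param t Evaluation times.
#' @return Numeric vector of smoothed values.
#' @export
predict_profile <- function(sp, experiment, t) {
  predict(sp$experiments[[experiment]]$fit, t)$y
}

#' Wild-bootstrap noise envelope around a smoothed profile
#'
#' Resamples `y* = fitted + residual * xi` with two-point Mammen weights
#' `xi` (mean 0, variance 1), refits the smoothing spline to each replicate
#' and returns pointwise quantile envelopes of the smoothed curve. The
#' envelope is a diagnostic of profile uncertainty; inference conditions on
#' the point-estimate curves.
#'
#' @param sp A [smooth_profile()] result.
#' @param B Number of bootstrap replicates (values below 50 are warned
#'   against).
#' @param probs Envelope quantiles.
#' @param grid_len Evaluation grid size per experiment.
#' @param seed Optional seed for reproducibility.
#' @return `sp` with an `envelope` element: per experiment a list with
#'   `times` and a matrix `quantiles` (length(probs) x grid_len).
#' @export
wild_bootstrap <- function(sp, B = 200L, probs = c(0.025, 0.975),
                           grid_len = 101L, seed = NULL) {
  if (B < 50L) warning("B < 50 bootstrap replicates: envelope will be noisy")
  if (!is.null(seed)) set.seed(seed)
  # Mammen's two-point law: golden-ratio support, mean 0, variance 1
  xi_vals <- c((1 - sqrt(5)) / 2, (1 + sqrt(5)) / 2)
  xi_prob <- c((sqrt(5) + 1) / (2 * sqrt(5)), (sqrt(5) - 1) / (2 * sqrt(5)))
  env <- lapply(sp$experiments, function(ex) {
    g <- seq(0, ex$horizon, length.out = grid_len)
    curves <- matrix(0, B, grid_len)
    for (b in seq_len(B)) {
      xi <- sample(xi_vals, length(ex$residuals), replace = TRUE, prob = xi_prob)
      ystar <- ex$fitted + ex$residuals * xi
      fb <- smooth.spline(ex$times, ystar, spar = ex$fit$spar)
      curves[b, ] <- predict(fb, g)$y
    }
    qs <- apply(curves, 2, quantile, probs = probs)
    if (is.null(dim(qs))) qs <- matrix(qs, nrow = 1)
    list(times = g, quantiles = qs, probs = probs)
  })
  sp$envelope <- env
  sp
}

#' Construct a regulator activity proxy from a smoothed mRNA profile
#'
#' TF activity is proxied from the smoothed mRNA curve. Modes:
#' `identity` (the curve itself; appropriate when inference is applied
#' directly to expression-derived profiles), `linear` (affine rescaling),
#' `delay` (time shift by `lag`, edge-held), and `ode` (translation model
#' `dP/dt = k_tl * M(t) - delta_p * P`, integrated exactly over the
#' piecewise-linear interpolant of the smoothed curve).
#'
#' @param sp A [smooth_profile()] result.
#' @param mode One of `"identity"`, `"linear"`, `"delay"`, `"ode"`.
#' @param scale,offset Affine coefficients for `linear` mode.
#' @param lag Delay in time units for `delay` mode.
#' @param k_tl,delta_p,P0 Translation rate, protein degradation rate and
#'   initial protein level for `ode` mode.
#' @param grid_len Grid size per experiment for the proxy curve.
#' @return A [regulator_profile()].
#' @export
protein_proxy <- function(sp, mode = c("identity", "linear", "delay", "ode"),
                          scale = 1, offset = 0, lag = NULL,
                          k_tl = NULL, delta_p = NULL, P0 = 0,
                          grid_len = 201L) {
  mode <- match.arg(mode)
  if (mode == "delay" && is.null(lag)) stop("delay mode requires 'lag'")
  if (mode == "ode" && (is.null(k_tl) || is.null(delta_p))) {
    stop("ode mode requires 'k_tl' and 'delta_p'")
  }
  curves <- lapply(sp$experiments, function(ex) {
    g <- seq(0, ex$horizon, length.out = grid_len)
    v <- switch(mode,
      identity = predict(ex$fit, g)$y,
      linear = scale * predict(ex$fit, g)$y + offset,
      delay = predict(ex$fit, pmin(pmax(g - lag, 0), ex$horizon))$y,
      ode = .translate_ode(g, predict(ex$fit, g)$y, k_tl, delta_p, P0)
    )
    list(times = g, values = v)
  })
  names(curves) <- names(sp$experiments)
  regulator_profile(sp$gene, curves)
}

# Exact integration of dP/dt = k M(t) - d P over each grid interval, with M
# linear on the interval: P(t1) = P(t0) e^{-dh} + k [a (1-e^{-dh})/d +
# b (h - (1-e^{-dh})/d)/d] for M(t0+s) = a + b s.
.translate_ode <- function(g, m, k, d, P0) {
  n <- length(g)
  P <- numeric(n)
  P[1] <- P0
  for (i in seq_len(n - 1L)) {
    h <- g[i + 1L] - g[i]
    a <- m[i]
    b <- (m[i + 1L] - m[i]) / h
    ed <- exp(-d * h)
    f1 <- (1 - ed) / d
    P[i + 1L] <- P[i] * ed + k * (a * f1 + b * (h - f1) / d)
  }
  P
}
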