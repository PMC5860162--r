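# Posterior summaries: regulator-set ranking, inclusion probabilities,
# threshold densities, fitted profiles and regulation-logic classification.

.retained_idx <- function(trace, burnin) {
  if (is.null(burnin)) burnin <- trace$manifest$config$burnin
  cut <- burnin * trace$manifest$config$iterations
  which(trace$iter > cut)
}

.set_key <- function(phi, candidates) {
  vapply(phi, function(p) paste(candidates[p], collapse = "+"), "")
}

#' Summarize a sampler trace
#'
#' Monte-Carlo frequencies over the retained draws: the posterior
#' distribution of the number of regulators, per-candidate inclusion
#' probabilities, ranked regulator sets (keyed by unordered name tuples),
#' and per-candidate threshold draws conditional on inclusion.
#'
#' @param trace A `trs_trace` from [run_trs()].
#' @param burnin Burn-in fraction override (default: the run configuration).
#' @param min_prob Report sets with at least this posterior probability.
#' @param max_sets Cap on the number of reported sets.
#' @return Object of class `trs_summary` with elements `nu_prob`,
#'   `inclusion`, `sets` (data.frame: set, probability, nu), `thresholds`
#'   (list of draws per candidate), `delta`, `n_draws`.
#' @export
summarize_trace <- function(trace, burnin = NULL, min_prob = 0.05,
                            max_sets = 10L) {
  idx <- .retained_idx(trace, burnin)
  if (!length(idx)) stop("empty trace after burn-in")
  n <- length(idx)
  cands <- trace$candidates
  nu <- trace$nu[idx]
  nu_prob <- table(factor(nu, levels = seq_len(max(nu)))) / n
  keys <- .set_key(trace$phi[idx], cands)
  tab <- sort(table(keys), decreasing = TRUE) / n
  sets_all <- data.frame(set = names(tab), probability = as.numeric(tab),
                         nu = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                         row.names = NULL)
  incl <- vapply(seq_along(cands), function(j)
    mean(vapply(trace$phi[idx], function(p) j %in% p, TRUE)), 0)
  names(incl) <- cands
  thr <- lapply(seq_along(cands), function(j) {
    unlist(lapply(idx, function(i) {
      pos <- match(j, trace$phi[[i]])
      if (is.na(pos)) NULL else trace$rho[[i]][pos]
    }))
  })
  names(thr) <- cands
  keep <- sets_all$probability >= min_prob
  sets <- head(sets_all[keep, , drop = FALSE], max_sets)
  if (!nrow(sets)) sets <- head(sets_all, 1L)
  structure(list(nu_prob = nu_prob, inclusion = incl, sets = sets,
                 sets_all = sets_all, thresholds = thr,
                 delta = trace$delta[idx], psi = trace$psi[idx, , drop = FALSE],
                 sigma2 = trace$sigma2[idx, , drop = FALSE],
                 n_draws = n, candidates = cands, target = trace$target,
                 burnin_used = if (is.null(burnin))
                   trace$manifest$config$burnin else burnin),
            class = "trs_summary")
}

#' @export
print.trs_summary <- function(x, ...) {
  cat("Posterior summary over", x$n_draws, "retained draws\n")
  cat("P(number of regulators):\n")
  print(round(x$nu_prob[x$nu_prob > 0], 3))
  cat("Top regulator sets:\n")
  df <- x$sets
  df$probability <- round(df$probability, 3)
  print(df, row.names = FALSE)
  cat("Inclusion probabilities:\n")
  print(round(sort(x$inclusion, decreasing = TRUE), 3))
  invisible(x)
}

#' Classify the regulation logic of a regulator set
#'
#' For each regulator of a chosen set (default: the a-posteriori top set),
#' compares the posterior transcription-rate draws between pairs of observed
#' activation states differing only in that regulator: if the 90%
#' equal-tailed intervals of the two rates are disjoint the switch has an
#' effect (its sign giving activation or repression); if each interval
#' covers the other's median there is no effect; intermediate cases are
#' ambiguous. A regulator whose effect is present at some co-states and
#' absent at others is conditional — e.g. an activator whose activation is
#' suppressed while a repressor is active (repressed activation).
#'
#' @param trace A `trs_trace`.
#' @param set Character vector naming the regulator set to classify
#'   (default: top-ranked set of [summarize_trace()]).
#' @param burnin Burn-in fraction override.
#' @param level Credible-interval level for the effect calls.
#' @return Data.frame with one row per regulator: `tf`, `label` (activator /
#'   repressor / no-effect / undetermined), `conditional` (logical), and a
#'   `contrasts` attribute with the per-contrast calls.
#' @export
classify_logic <- function(trace, set = NULL, burnin = NULL, level = 0.90) {
  idx <- .retained_idx(trace, burnin)
  cands <- trace$candidates
  if (is.null(set)) {
    keys <- .set_key(trace$phi[idx], cands)
    set <- strsplit(names(sort(table(keys), decreasing = TRUE))[1], "+",
                    fixed = TRUE)[[1]]
  }
  set_idx <- sort(match(set, cands))
  if (anyNA(set_idx)) stop("unknown regulator in set")
  nu <- length(set_idx)
  sel <- idx[vapply(trace$phi[idx], function(p) identical(p, set_idx), TRUE)]
  if (!length(sel)) stop("no retained draws for the requested set")
  # tau draws per state label
  tau_draws <- list()
  for (i in sel) {
    tv <- trace$tau[[i]]
    for (s in names(tv)) tau_draws[[s]] <- c(tau_draws[[s]], tv[[s]])
  }
  min_n <- max(20, 0.05 * length(sel))
  lo_p <- (1 - level) / 2
  out <- data.frame(tf = cands[set_idx], label = NA_character_,
                    conditional = NA)
  contrasts <- list()
  for (jj in seq_len(nu)) {
    calls <- character(0)
    signs <- numeric(0)
    for (s0 in names(tau_draws)) {
      if (substr(s0, jj, jj) != "0") next
      s1 <- s0
      substr(s1, jj, jj) <- "1"
      if (is.null(tau_draws[[s1]])) next
      d0 <- tau_draws[[s0]]; d1 <- tau_draws[[s1]]
      if (length(d0) < min_n || length(d1) < min_n) next
      q0 <- quantile(d0, c(lo_p, 1 - lo_p)); m0 <- median(d0)
      q1 <- quantile(d1, c(lo_p, 1 - lo_p)); m1 <- median(d1)
      call <- if (q1[1] > q0[2]) "up" else if (q1[2] < q0[1]) "down"
        else if (m1 >= q0[1] && m1 <= q0[2] && m0 >= q1[1] && m0 <= q1[2])
          "none" else "ambiguous"
      calls <- c(calls, setNames(call, paste(s0, s1, sep = "->")))
      signs <- c(signs, m1 - m0)
    }
    if (!length(calls)) {
      out$label[jj] <- "undetermined"
      out$conditional[jj] <- NA
    } else {
      eff <- calls[calls %in% c("up", "down")]
      if (!length(eff)) {
        out$label[jj] <- "no-effect"
        out$conditional[jj] <- FALSE
      } else if (all(eff == "up")) {
        out$label[jj] <- "activator"
        out$conditional[jj] <- any(calls == "none")
      } else if (all(eff == "down")) {
        out$label[jj] <- "repressor"
        out$conditional[jj] <- any(calls == "none")
      } else {
        out$label[jj] <- "conditional"
        out$conditional[jj] <- TRUE
      }
    }
    contrasts[[cands[set_idx[jj]]]] <- calls
  }
  attr(out, "contrasts") <- contrasts
  attr(out, "n_model_draws") <- length(sel)
  out
}

#' Posterior-fit curves for the top models
#'
#' Refits the switch model at posterior-mean parameters (thresholds and
#' degradation rate conditional on each model) and returns the fitted mRNA
#' curve M_k(t) and the piecewise-constant transcription-rate profile tau(t)
#' on a dense grid per experiment.
#'
#' @param trace A `trs_trace`.
#' @param data The [trs_data()] the trace was sampled from.
#' @param sets List of character vectors naming the models to refit
#'   (default: the top sets of [summarize_trace()]).
#' @param burnin Burn-in fraction override.
#' @param grid_len Grid size per experiment.
#' @return List per model: `set`, `curves` (data.frame: experiment, time,
#'   M, tau), `fit` (the refit object).
#' @export
fitted_profiles <- function(trace, data, sets = NULL, burnin = NULL,
                            grid_len = 200L) {
  idx <- .retained_idx(trace, burnin)
  cands <- trace$candidates
  if (is.null(sets)) {
    sm <- summarize_trace(trace, burnin = burnin)
    sets <- strsplit(sm$sets$set, "+", fixed = TRUE)
  }
  lapply(sets, function(set) {
    set_idx <- sort(match(set, cands))
    sel <- idx[vapply(trace$phi[idx], function(p) identical(p, set_idx), TRUE)]
    if (!length(sel)) return(NULL)
    rho <- rowMeans(vapply(sel, function(i) trace$rho[[i]], numeric(length(set_idx))))
    delta <- mean(trace$delta[sel])
    psi <- colMeans(trace$psi[sel, , drop = FALSE])
    sigma <- sqrt(colMeans(trace$sigma2[sel, , drop = FALSE]))
    ft <- fit_given_structure(data, set_idx, rho, delta, sigma = sigma,
                              psi = psi)
    curves <- do.call(rbind, lapply(seq_len(data$K), function(k) {
      g <- seq(0, data$horizon[k], length.out = grid_len)
      M <- solve_trs_ode(g, delta, ft$M0[k], ft$partition,
                         unname(ft$tau), experiment = k)
      sg <- ft$partition$segs[[k]]
      ti <- findInterval(g, c(sg$l, data$horizon[k] + 1), rightmost.closed = FALSE)
      ti <- pmin(pmax(ti, 1L), length(sg$sidx))
      data.frame(experiment = data$experiments[k], time = g, M = M,
                 tau = unname(ft$tau)[sg$sidx[ti]])
    }))
    list(set = cands[set_idx], curves = curves, fit = ft,
         delta = delta, rho = setNames(rho, cands[set_idx]))
  })
}
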