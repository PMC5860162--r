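# Assembly of observed expression data and smoothed regulator proxies into
# the container consumed by the fitting and sampling functions.

#' Read a long-format expression CSV
#'
#' Expected columns: `experiment`, `replicate`, `time`, `gene`, `value`.
#'
#' @param path Path to the CSV file.
#' @return A data.frame in long format.
#' @export
read_expression_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment", "replicate", "time", "gene", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Assemble a switch-model dataset
#'
#' Builds the container used by [fit_given_structure()] and [run_trs()]:
#' the target's observations per experiment, continuous regulator proxy
#' curves for every candidate (smoothing-spline fits of their mRNA series,
#' or user-supplied pre-smoothed profiles), per-candidate value ranges across
#' experiments, and the fixed variance-model weight function w_k(t) (the
#' reciprocal of a smoothed estimate of the target's expression, floored at
#' a small positive fraction of its maximum).
#'
#' Times are shifted so each experiment starts at 0.
#'
#' @param df Long-format data.frame with columns `experiment`, `replicate`,
#'   `time`, `gene`, `value`.
#' @param target Name of the target gene.
#' @param candidates Candidate regulator names; default: all genes in `df`
#'   (including the target itself, allowing auto-regulation to compete).
#' @param profiles Optional long-format data.frame (`experiment`, `time`,
#'   `gene`, `value`) of pre-smoothed regulator proxies; when supplied these
#'   are interpolated piecewise-linearly instead of smoothing the raw series.
#' @param grid_len Number of grid points per experiment for the proxy curves.
#' @param proxy_mode Protein-proxy mode passed to [protein_proxy()]
#'   (default `"identity"`: the smoothed mRNA curve is used as TF activity).
#' @param w_floor Weight floor as a fraction of the smoothed target maximum.
#' @return An object of class `trs_data`.
#' @export
trs_data <- function(df, target, candidates = NULL, profiles = NULL,
                     grid_len = 201L, proxy_mode = "identity",
                     w_floor = 1e-6) {
  need <- c("experiment", "replicate", "time", "gene", "value")
  stopifnot(all(need %in% names(df)))
  genes <- unique(df$gene)
  if (!target %in% genes) stop("target gene '", target, "' not in data")
  if (is.null(candidates)) candidates <- genes
  miss <- setdiff(candidates, genes)
  if (length(miss)) stop("candidate(s) not in data: ", paste(miss, collapse = ", "))
  experiments <- unique(df$experiment)
  K <- length(experiments)
  N <- length(candidates)

  # 0-based time within each experiment
  for (e in experiments) {
    sel <- df$experiment == e
    df$time[sel] <- df$time[sel] - min(df$time[sel])
  }
  horizon <- vapply(experiments, function(e) max(df$time[df$experiment == e]), 0)
  names(horizon) <- experiments

  obs <- vector("list", K)
  names(obs) <- experiments
  grid <- vector("list", K)
  P <- vector("list", K)
  wcurve <- vector("list", K)

  tgt <- df[df$gene == target, , drop = FALSE]
  sm_target <- smooth_profile(tgt)

  prof_list <- vector("list", N)
  names(prof_list) <- candidates
  for (j in seq_len(N)) {
    gj <- candidates[j]
    if (!is.null(profiles)) {
      pj <- profiles[profiles$gene == gj, , drop = FALSE]
      if (!nrow(pj)) stop("no pre-smoothed profile for ", gj)
      curves <- lapply(experiments, function(e) {
        pe <- pj[pj$experiment == e, , drop = FALSE]
        pe <- pe[order(pe$time), ]
        list(times = pe$time - min(pe$time), values = pe$value)
      })
      names(curves) <- experiments
      prof_list[[j]] <- regulator_profile(gj, curves)
    } else {
      smj <- if (gj == target) sm_target else
        smooth_profile(df[df$gene == gj, , drop = FALSE])
      prof_list[[j]] <- protein_proxy(smj, mode = proxy_mode)
    }
  }

  for (k in seq_len(K)) {
    e <- experiments[k]
    g <- seq(0, horizon[k], length.out = grid_len)
    grid[[k]] <- g
    Pk <- matrix(0, grid_len, N)
    for (j in seq_len(N)) Pk[, j] <- profile_at(prof_list[[j]], e, g)
    P[[k]] <- Pk
    sel <- tgt$experiment == e
    tt <- tgt$time[sel]
    ord <- order(tt, tgt$replicate[sel])
    tt <- tt[ord]
    yy <- tgt$value[sel][ord]
    mhat <- predict_profile(sm_target, e, tt)
    mhat <- pmax(mhat, w_floor * max(mhat))
    obs[[k]] <- list(times = tt, y = yy, replicate = tgt$replicate[sel][ord],
                     w = 1 / mhat)
  }

  rng <- t(vapply(prof_list, `[[`, numeric(2), "range"))
  structure(list(target = target, candidates = candidates,
                 experiments = experiments, K = K, N = N,
                 horizon = horizon, obs = obs, grid = grid, P = P,
                 profiles = prof_list, range = rng,
                 smoothed_target = sm_target),
            class = "trs_data")
}

#' @export
print.trs_data <- function(x, ...) {
  n <- sum(vapply(x$obs, function(o) length(o$y), 0))
  cat("Switch-model dataset: target '", x$target, "', ", x$N,
      " candidate regulator(s), ", x$K, " experiment(s), ", n,
      " target observations\n", sep = "")
  cat("  horizons:", paste(signif(x$horizon, 4), collapse = ", "), "\n")
  invisible(x)
}
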