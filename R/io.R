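# Persistence: traces as a CSV (scalar draws) plus JSON-lines (variable-
# dimension set/threshold/rate draws), manifests and summaries as JSON.

#' Write a sampler trace to disk
#'
#' Scalar draws go to `<stem>.csv`, the variable-dimension draws (regulator
#' set, thresholds, transcription rates) to `<stem>.jsonl` (one JSON object
#' per retained draw), and the run manifest to `<stem>_manifest.json`.
#'
#' @param trace A `trs_trace`.
#' @param stem Output path stem (without extension).
#' @return `stem`, invisibly.
#' @export
write_trace <- function(trace, stem) {
  K <- trace$K
  scal <- data.frame(iter = trace$iter, nu = trace$nu, delta = trace$delta,
                     loglik = trace$loglik, move = trace$move,
                     accepted = trace$accepted)
  for (k in seq_len(K)) {
    scal[[paste0("sigma2_", k)]] <- trace$sigma2[, k]
    scal[[paste0("psi_", k)]] <- trace$psi[, k]
    scal[[paste0("M0_", k)]] <- trace$M0[, k]
  }
  write.csv(scal, paste0(stem, ".csv"), row.names = FALSE)
  con <- file(paste0(stem, ".jsonl"), "w")
  on.exit(close(con))
  for (i in seq_along(trace$iter)) {
    writeLines(jsonlite::toJSON(list(
      iter = trace$iter[i],
      phi = trace$candidates[trace$phi[[i]]],
      rho = trace$rho[[i]],
      tau = as.list(trace$tau[[i]])), auto_unbox = TRUE, digits = NA), con)
  }
  jsonlite::write_json(
    list(candidates = trace$candidates, target = trace$target,
         experiments = trace$experiments, manifest = trace$manifest),
    paste0(stem, "_manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(stem)
}

#' Read a sampler trace written by [write_trace()]
#'
#' @param stem Path stem used at write time.
#' @return A `trs_trace`.
#' @export
read_trace <- function(stem) {
  scal <- read.csv(paste0(stem, ".csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(stem, "_manifest.json"),
                              simplifyVector = TRUE)
  lines <- readLines(paste0(stem, ".jsonl"))
  n <- nrow(scal)
  if (length(lines) != n) {
    stop("corrupt trace: ", length(lines), " JSON lines for ", n,
         " CSV rows (", stem, ".jsonl)")
  }
  cands <- meta$candidates
  phi <- vector("list", n); rho <- vector("list", n); tau <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e)
      stop("corrupt trace line ", i, " of ", stem, ".jsonl: ",
           conditionMessage(e)))
    phi[[i]] <- match(unlist(rec$phi), cands)
    rho[[i]] <- as.numeric(unlist(rec$rho))
    tau[[i]] <- unlist(rec$tau)
  }
  K <- length(meta$experiments)
  out <- list(iter = scal$iter, nu = scal$nu, delta = scal$delta,
              loglik = scal$loglik, move = scal$move,
              accepted = scal$accepted,
              sigma2 = as.matrix(scal[paste0("sigma2_", seq_len(K))]),
              psi = as.matrix(scal[paste0("psi_", seq_len(K))]),
              M0 = as.matrix(scal[paste0("M0_", seq_len(K))]),
              phi = phi, rho = rho, tau = tau,
              candidates = cands, target = meta$target,
              experiments = meta$experiments, K = K,
              manifest = meta$manifest)
  class(out) <- "trs_trace"
  out
}

#' Write a posterior summary as CSV + JSON
#'
#' The set ranking goes to `<stem>_sets.csv`; the full summary (number-of-
#' regulators distribution, inclusion probabilities, ranked sets) to
#' `<stem>.json`.
#'
#' @param summary A `trs_summary`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_summary <- function(summary, stem) {
  write.csv(summary$sets, paste0(stem, "_sets.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    target = summary$target,
    n_draws = summary$n_draws,
    nu_prob = as.list(setNames(as.numeric(summary$nu_prob),
                               names(summary$nu_prob))),
    inclusion = as.list(summary$inclusion),
    sets = summary$sets,
    delta_mean = mean(summary$delta)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}

#' Serialize a state partition to JSON (debugging aid)
#'
#' @param partition A `trs_partition`.
#' @return A JSON string.
#' @export
partition_json <- function(partition) {
  lbl <- .code_labels(partition$states, partition$nu)
  segs <- lapply(partition$segs, function(sg)
    data.frame(l = sg$l, r = sg$r, state = lbl[sg$sidx]))
  jsonlite::toJSON(list(states = lbl, segments = segs), auto_unbox = TRUE,
                   digits = NA, pretty = TRUE)
}
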