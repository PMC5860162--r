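# Posterior summaries, logic classification and fitted profiles.

# build a minimal synthetic trace by hand
fake_trace <- function(phi_list, rho_list, tau_list, candidates,
                       K = 1, delta = 0.3) {
  n <- length(phi_list)
  structure(list(
    iter = seq_len(n), nu = lengths(phi_list), delta = rep(delta, n),
    loglik = rep(0, n), move = rep("M", n), accepted = rep(TRUE, n),
    sigma2 = matrix(1, n, K), psi = matrix(0, n, K),
    M0 = matrix(1, n, K), phi = phi_list, rho = rho_list, tau = tau_list,
    candidates = candidates, target = "target",
    experiments = paste0("exp", seq_len(K)), K = K,
    manifest = list(config = list(burnin = 0, iterations = n), thin = 1,
                    n_kept = n)),
    class = "trs_trace")
}

test_that("summary bookkeeping identities hold exactly", {
  cands <- c("a", "b", "c")
  phi <- c(replicate(6, c(1L, 2L), simplify = FALSE),
           replicate(3, 1L, simplify = FALSE),
           replicate(1, c(2L, 3L), simplify = FALSE))
  rho <- lapply(phi, function(p) rep(0.5, length(p)))
  tau <- lapply(phi, function(p) setNames(rep(1, 2), c("0", "1")))
  tr <- fake_trace(phi, rho, tau, cands)
  sm <- summarize_trace(tr, burnin = 0, min_prob = 0)
  expect_equal(sum(as.numeric(sm$nu_prob)), 1, tolerance = 1e-12)
  # inclusion probability equals the sum over sets containing the TF
  for (j in seq_along(cands)) {
    in_sets <- vapply(strsplit(sm$sets_all$set, "+", fixed = TRUE),
                      function(s) cands[j] %in% s, TRUE)
    expect_equal(unname(sm$inclusion[j]),
                 sum(sm$sets_all$probability[in_sets]), tolerance = 1e-12)
  }
  expect_equal(sm$sets_all$probability[1], 0.6)
  # a trace with a single repeated model concentrates all mass on it
  tr1 <- fake_trace(replicate(5, c(1L, 3L), simplify = FALSE),
                    replicate(5, c(0.4, 0.6), simplify = FALSE),
                    replicate(5, setNames(1:2, c("00", "11")),
                              simplify = FALSE), cands)
  sm1 <- summarize_trace(tr1, burnin = 0)
  expect_equal(sm1$sets$probability, 1)
  expect_equal(sm1$sets$set, "a+c")
  # a late burn-in cut retains only the tail of the trace
  expect_equal(summarize_trace(tr1, burnin = 0.8)$n_draws, 1L)
})

test_that("logic classification separates activators and repressors", {
  cands <- c("A", "B")
  n <- 300
  set.seed(4)
  phi <- replicate(n, c(1L, 2L), simplify = FALSE)
  rho <- replicate(n, c(0.5, 0.5), simplify = FALSE)
  # A raises the rate only when B is inactive; B's activation kills it
  tau <- replicate(n, c("00" = rnorm(1, 1, 0.05),
                        "10" = rnorm(1, 3, 0.05),
                        "11" = rnorm(1, 1, 0.05),
                        "01" = rnorm(1, 1, 0.05)), simplify = FALSE)
  tr <- fake_trace(phi, rho, tau, cands)
  lg <- classify_logic(tr, burnin = 0)
  expect_equal(lg$label[lg$tf == "A"], "activator")
  expect_true(lg$conditional[lg$tf == "A"])      # suppressed when B active
  expect_equal(lg$label[lg$tf == "B"], "repressor")

  # all rates equal: every regulator is a no-effect
  tau0 <- replicate(n, c("00" = rnorm(1, 1, 0.05),
                         "10" = rnorm(1, 1, 0.05),
                         "11" = rnorm(1, 1, 0.05),
                         "01" = rnorm(1, 1, 0.05)), simplify = FALSE)
  lg0 <- classify_logic(fake_trace(phi, rho, tau0, cands), burnin = 0)
  expect_true(all(lg0$label == "no-effect"))

  # a state pair that is never observed leaves the contrast undetermined
  tau2 <- replicate(n, c("10" = rnorm(1, 3, 0.05),
                         "11" = rnorm(1, 1, 0.05)), simplify = FALSE)
  lg2 <- classify_logic(fake_trace(phi, rho, tau2, cands), burnin = 0)
  expect_equal(lg2$label[lg2$tf == "A"], "undetermined")
  expect_equal(lg2$label[lg2$tf == "B"], "repressor")
})

test_that("a designed rate jump is labelled an activator", {
  profs <- two_tf_profiles()
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_from_trs(profs["A"], "A", 0.5,
                             c("0" = 0.4, "1" = 0.8), 0.4, M0 = c(1, 1),
                             sigma = 0.03, replicates = 2, seed = s)
    d <- trs_data(sim$data, "target", "A", profiles = sim$profiles_df)
    tr <- run_trs(d, trs_priors(),
                  trs_mcmc_config(iterations = 3000, seed = s, keep = 1500))
    lg <- classify_logic(tr, set = "A")
    if (lg$label[1] == "activator") hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("fitted profiles interpolate noiseless data and jump at switches", {
  fx <- tiny_trs_dataset(sigma = 0)
  d <- fx$data
  tr <- run_trs(d, trs_priors(),
                trs_mcmc_config(iterations = 3000, seed = 2, keep = 1500))
  fp <- fitted_profiles(tr, d, sets = list(c("A", "B")))
  expect_length(fp, 1)
  cur <- fp[[1]]$curves
  # tau is piecewise constant: few unique values
  expect_lte(length(unique(round(cur$tau, 9))), fp[[1]]$fit$partition$q)
  # fitted curve passes through the noiseless observations
  for (k in 1:2) {
    ek <- paste0("exp", k)
    obs <- d$obs[[k]]
    at <- approx(cur$time[cur$experiment == ek],
                 cur$M[cur$experiment == ek], xout = obs$times)$y
    expect_lt(max(abs(at - obs$y)), 0.02)
  }
  # continuity of M across switch times
  ft <- fp[[1]]$fit
  for (k in 1:2) {
    sg <- ft$partition$segs[[k]]
    sw <- sg$l[-1]
    if (!length(sw)) next
    left <- solve_trs_ode(sw - 1e-9, fp[[1]]$delta, ft$M0[k],
                          ft$partition, unname(ft$tau), k)
    right <- solve_trs_ode(sw + 1e-9, fp[[1]]$delta, ft$M0[k],
                           ft$partition, unname(ft$tau), k)
    expect_lt(max(abs(left - right)), 1e-6)
  }
})
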