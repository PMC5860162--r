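# The reversible-jump sampler: proposals, conditional updates, determinism.

test_that("identical seeds give identical traces", {
  fx <- tiny_trs_dataset(sigma = 0.08)
  cfg <- trs_mcmc_config(iterations = 400, seed = 9, keep = 200)
  t1 <- run_trs(fx$data, trs_priors(), cfg)
  t2 <- run_trs(fx$data, trs_priors(), cfg)
  expect_identical(t1$phi, t2$phi)
  expect_identical(t1$rho, t2$rho)
  expect_identical(t1$delta, t2$delta)
  expect_identical(t1$loglik, t2$loglik)
})

test_that("empirical move-type frequencies match the schedule", {
  pr <- trs_priors(lambda = 0.15)
  sc <- move_schedule(pr, nu_max = 4)
  ranges <- cbind(rep(0, 5), rep(1, 5))
  rownames(ranges) <- letters[1:5]
  set.seed(21)
  n <- 2e4
  moves <- character(n)
  for (i in seq_len(n)) {
    moves[i] <- propose_structure_move(c(1L, 3L), c(0.5, 0.5), sc, ranges,
                                       0.1)$move
  }
  emp <- table(factor(moves, levels = c("M", "S", "B", "D"))) / n
  want <- unlist(sc[2, c("pi_M", "pi_S", "pi_B", "pi_D")])
  mcsd <- sqrt(want * (1 - want) / n)
  expect_true(all(abs(emp - want) < 3 * pmax(mcsd, 1e-4)))
})

test_that("birth and death log proposal ratios are exact negatives", {
  pr <- trs_priors(lambda = 0.15)
  sc <- move_schedule(pr, nu_max = 4)
  ranges <- cbind(c(0, 1, -2), c(2, 3, 2))
  rownames(ranges) <- c("a", "b", "c")
  set.seed(5)
  found <- 0
  for (i in 1:500) {
    prop <- propose_structure_move(2L, 1.5, sc, ranges, 0.1)
    if (prop$move != "B") next
    # scan for the reverse death of the same regulator from the new state
    for (j in 1:500) {
      rev <- propose_structure_move(prop$phi, prop$rho, sc, ranges, 0.1)
      if (rev$move == "D" && rev$tf == prop$tf) {
        expect_equal(rev$log_qratio, -prop$log_qratio, tolerance = 1e-12)
        # and the death restores the original state
        expect_identical(rev$phi, 2L)
        found <- found + 1
        break
      }
    }
    if (found >= 3) break
  }
  expect_gte(found, 3)
})

test_that("threshold moves stay inside the profile range", {
  pr <- trs_priors()
  sc <- move_schedule(pr, nu_max = 2)
  ranges <- cbind(c(0, 0), c(1, 1))
  rownames(ranges) <- c("a", "b")
  set.seed(2)
  for (i in 1:300) {
    prop <- propose_structure_move(1L, 0.999, sc, ranges, 0.3)
    if (prop$move == "M") {
      expect_gt(prop$rho[1], 0)
      expect_lt(prop$rho[1], 1)
    }
  }
})

test_that("the noise-variance draw matches its analytic posterior mean", {
  pr <- trs_priors(sigma_df = 2, sigma_scale = 0.5)
  rssw <- c(30, 80); nk <- c(20, 40)
  set.seed(31)
  draws <- replicate(2e4, trswitch:::.draw_sigma2(rssw, nk, pr))
  df <- 2 + nk
  scl <- (2 * 0.5 + rssw) / df
  want <- df * scl / (df - 2)
  got <- rowMeans(draws)
  expect_equal(got, want, tolerance = 0.03)
  # residuals scaled by 2 quadruple the data term of the posterior scale
  scl4 <- (2 * 0.5 + 4 * rssw) / df
  expect_equal(scl4 - 2 * 0.5 / df, 4 * (scl - 2 * 0.5 / df),
               tolerance = 1e-12)
})

test_that("the psi full conditional is flat when weights are 1", {
  grid <- seq(0, 1, length.out = 201)
  n <- 30
  Epsi <- exp(outer(2 * rep(0, n), grid))    # w == 1 -> log w == 0
  p <- trswitch:::.psi_grid_probs(runif(n), Epsi, 0, 1.3, grid)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_lt(diff(range(p)), 1e-12)
  # and properly normalized for informative weights too
  lw <- rnorm(n, 0, 0.5)
  p2 <- trswitch:::.psi_grid_probs(runif(n), exp(outer(2 * lw, grid)),
                                   sum(lw), 0.8, grid)
  expect_equal(sum(p2), 1, tolerance = 1e-12)
})

test_that("a likelihood-flattened chain samples the prior", {
  fx <- tiny_trs_dataset(sigma = 0.05)
  pr <- trs_priors(lambda = 0.4, tf_prior = "informative",
                   threshold_prior = "uniform")
  cfg <- trs_mcmc_config(iterations = 3e4, seed = 13, keep = 15000,
                         flat_likelihood = TRUE, burnin = 0.1)
  tr <- run_trs(fx$data, pr, cfg)
  sm <- summarize_trace(tr)
  pd <- prior_data(fx$data, pr)
  pnu <- exp(pd$log_pnu)
  got <- as.numeric(sm$nu_prob[seq_along(pnu)])
  expect_lt(max(abs(got - pnu)), 0.05)
  incl <- trswitch:::.prior_inclusion(pr, pd)
  expect_lt(max(abs(sm$inclusion - incl)), 0.05)
})

test_that("acceptance rates are reported and sane on a small run", {
  fx <- tiny_trs_dataset(sigma = 0.08)
  tr <- run_trs(fx$data, trs_priors(),
                trs_mcmc_config(iterations = 2000, seed = 3, keep = 1000))
  ar <- tr$manifest$acceptance_rates
  expect_true(all(is.na(ar) | (ar >= 0 & ar <= 1)))
  expect_true(ar["M"] > 0 && ar["M"] < 1)
  expect_true(ar["delta"] > 0 && ar["delta"] < 1)
  # the cache is consistent: refitting a recorded draw reproduces its
  # log-likelihood
  i <- length(tr$iter)
  ft <- fit_given_structure(fx$data, tr$phi[[i]], tr$rho[[i]],
                            tr$delta[i], sigma = sqrt(tr$sigma2[i, ]),
                            psi = tr$psi[i, ])
  expect_equal(ft$loglik, tr$loglik[i], tolerance = 1e-8)
})

test_that("the degradation rate is recovered from exact-model data", {
  prof <- two_tf_profiles()
  tau <- c("00" = 0.3, "10" = 1.2, "11" = 0.3, "01" = 0.3)
  tt <- list(seq(0, 10, by = 0.4), seq(0, 10, by = 0.4))
  sim <- simulate_from_trs(prof, c("A", "B"), c(0.5, 0.5), tau, 0.345,
                           M0 = c(0.75, 3), sigma = 0.03, replicates = 2,
                           times = tt, seed = 8)
  d <- trs_data(sim$data, "target", c("A", "B"),
                profiles = sim$profiles_df)
  tr <- run_trs(d, trs_priors(),
                trs_mcmc_config(iterations = 4000, seed = 5, keep = 2000))
  sm <- summarize_trace(tr)
  expect_lt(abs(mean(sm$delta) - 0.345) / 0.345, 0.15)
})
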