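# Activation switches, state enumeration, the closed-form ODE solution,
# the linear-regression design, weighted least squares and the likelihood.

test_that("threshold crossings of a piecewise-linear curve are exact", {
  p <- regulator_profile("f", list(e1 = list(times = c(0, 5, 10),
                                             values = c(0, 2, 0))))
  a <- compute_activation(p, 1)
  expect_equal(a$experiments$e1$switch_times, c(2.5, 7.5))
  expect_equal(a$experiments$e1$states, c(0L, 1L, 0L))

  # dense-grid oracle: state is 1 exactly where the curve >= threshold
  g <- seq(0.01, 9.99, length.out = 400)
  v <- approx(c(0, 5, 10), c(0, 2, 0), xout = g)$y
  seg <- findInterval(g, c(0, a$experiments$e1$switch_times))
  expect_equal(a$experiments$e1$states[seg], as.integer(v >= 1))
})

test_that("a threshold outside the profile range is a redundant regulator", {
  p <- ramp_profile(from = 0.2, to = 0.8)
  expect_error(compute_activation(p, 0.9), "redundant regulator")
  expect_error(compute_activation(p, 0.1), "redundant regulator")
  # constant-below curve never crosses: range degenerate above threshold
  a <- compute_activation(p, 0.5)
  expect_length(a$experiments$exp1$switch_times, 1L)
})

test_that("state enumeration merges experiments into shared rate indices", {
  # one TF, one experiment, one upward crossing
  p <- ramp_profile()
  a <- compute_activation(p, 0.3)
  part <- enumerate_states(list(a))
  expect_equal(part$q, 2L)
  expect_equal(part$segs$exp1$l, c(0, 3))
  expect_equal(part$segs$exp1$r, c(3, 10))

  # repressed-activation structure: state (1,0) spans
  # [s1,s2] of exp1 and [0, s1'] of exp2 and maps to ONE rate index
  profs <- two_tf_profiles()
  trajs <- list(compute_activation(profs$A, 0.5),
                compute_activation(profs$B, 0.5))
  part2 <- enumerate_states(trajs)
  expect_equal(part2$q, 4L)
  lbl <- apply(part2$states_matrix, 1, paste, collapse = "")
  i10 <- which(lbl == "10")
  e1 <- part2$segs$exp1; e2 <- part2$segs$exp2
  expect_equal(unname(cbind(e1$l, e1$r)[e1$sidx == i10, ]), c(2, 6))
  expect_equal(unname(cbind(e2$l, e2$r)[e2$sidx == i10, ]), c(0, 3))

  # a joint state that never occurs carries no rate parameter
  pA <- ramp_profile("A")            # rises: 0 then 1
  pB <- ramp_profile("B")            # same direction: (1,0)/(0,1) asymmetry
  t2 <- list(compute_activation(pA, 0.3), compute_activation(pB, 0.7))
  p3 <- enumerate_states(t2)
  expect_equal(p3$q, 3L)             # (0,0), (1,0), (1,1); never (0,1)
})

test_that("segments tile each experiment horizon exactly", {
  set.seed(42)
  for (rep in 1:25) {
    K <- sample(1:3, 1)
    nu <- sample(1:3, 1)
    profs <- lapply(seq_len(nu), function(j) {
      curves <- lapply(seq_len(K), function(k) {
        g <- seq(0, 10, length.out = 41)
        list(times = g, values = cumsum(rnorm(41)))
      })
      names(curves) <- paste0("exp", seq_len(K))
      regulator_profile(paste0("tf", j), curves)
    })
    trajs <- lapply(profs, function(p)
      compute_activation(p, mean(p$range) + 1e-9))
    part <- enumerate_states(trajs)
    for (k in seq_len(K)) {
      sg <- part$segs[[k]]
      expect_equal(sum(sg$r - sg$l), 10, tolerance = 1e-9)
      if (length(sg$l) > 1) expect_equal(sg$l[-1], sg$r[-length(sg$r)])
    }
  }
})

test_that("closed-form ODE solution matches equilibrium and pure decay", {
  p <- ramp_profile()
  part <- enumerate_states(list(compute_activation(p, 0.5)))
  tt <- seq(0, 10, by = 0.5)
  # both states at tau = delta * M0: equilibrium
  expect_equal(solve_trs_ode(tt, 0.7, 2, part, rep(0.7 * 2, part$q)),
               rep(2, length(tt)))
  # tau = 0 everywhere: exponential decay
  expect_equal(solve_trs_ode(tt, 0.7, 1, part, rep(0, part$q)),
               exp(-0.7 * tt))
  expect_error(solve_trs_ode(tt, -1, 1, part, rep(0, part$q)), "delta")
})

test_that("closed-form ODE solution matches a numerical integrator", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  for (rep in 1:20) {
    p <- tent_profile(peak = 2)
    rho <- runif(1, 0.2, 1.8)
    part <- enumerate_states(list(compute_activation(p, rho)))
    delta <- runif(1, 0.1, 1)
    M0 <- runif(1, 0, 5)
    tau <- runif(part$q, 0, 3)
    sg <- part$segs[[1]]
    rate <- function(t, y, parms) {
      i <- findInterval(t, c(sg$l, 10.001), rightmost.closed = FALSE)
      i <- min(max(i, 1L), length(sg$sidx))
      list(tau[sg$sidx[i]] - delta * y)
    }
    tt <- sort(c(0, runif(12, 0, 10), 10))
    num <- deSolve::ode(c(M = M0), tt, rate, NULL,
                        rtol = 1e-10, atol = 1e-10)[, "M"]
    cf <- solve_trs_ode(tt, delta, M0, part, tau)
    expect_lt(max(abs(cf - num) / pmax(abs(num), 1e-8)), 1e-8)
  }
})

test_that("the design matrix linearizes the ODE solution", {
  profs <- two_tf_profiles()
  trajs <- list(compute_activation(profs$A, 0.5),
                compute_activation(profs$B, 0.5))
  part <- enumerate_states(trajs)
  delta <- 0.3
  tt <- list(seq(0, 10, by = 0.8), seq(0, 10, by = 1.1))
  D <- build_design(part, delta, tt)
  expect_equal(dim(D), c(length(tt[[1]]) + length(tt[[2]]), 2 + part$q))
  M0 <- c(1.5, 4); tau <- c(0.2, 1.3, 0.5, 0.9)
  pred <- drop(D %*% c(M0, tau))
  direct <- c(solve_trs_ode(tt[[1]], delta, M0[1], part, tau, 1),
              solve_trs_ode(tt[[2]], delta, M0[2], part, tau, 2))
  expect_equal(pred, direct, tolerance = 1e-12)

  # a state observed in both experiments has nonzero entries in both blocks
  lbl <- apply(part$states_matrix, 1, paste, collapse = "")
  col <- 2 + which(lbl == "10")
  expect_gt(max(abs(D[seq_along(tt[[1]]), col])), 0)
  expect_gt(max(abs(D[-seq_along(tt[[1]]), col])), 0)

  # observation at time 0 only: initial-condition column only
  D0 <- build_design(part, delta, list(0, numeric(0)))
  expect_equal(drop(D0), c(1, rep(0, 1 + part$q)))
})

test_that("weighted least squares matches the normal-equations oracle", {
  set.seed(11)
  for (rep in 1:10) {
    X <- matrix(rnorm(36), 12, 3)
    y <- rnorm(12)
    v <- runif(12, 0.4, 2.5)
    fit <- wls_fit(y, X, v)
    W <- diag(1 / v^2)
    oracle <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
    expect_equal(fit$coef, drop(oracle), tolerance = 1e-10)
  }
  # equal weights reduce to OLS; noiseless data recovered exactly
  X <- cbind(1, seq_len(10))
  y <- drop(X %*% c(2, -0.5))
  expect_equal(wls_fit(y, X, 3)$coef, c(2, -0.5), tolerance = 1e-10)
  expect_equal(wls_fit(y, X, 3)$coef, wls_fit(y, X, 1)$coef)
  # rank-deficient design: minimum-norm solution with a warning
  Xr <- cbind(X, X[, 2])
  expect_warning(fr <- wls_fit(y, Xr, 1), "minimum-norm")
  expect_equal(drop(Xr %*% fr$coef), y, tolerance = 1e-8)
})

test_that("the log-likelihood matches its closed form and an oracle", {
  expect_equal(log_likelihood(rep(0, 7), rep(0, 7), sigma = 1),
               -(7 / 2) * log(2 * pi))
  # doubling sigma with zero residuals lowers the value by n log 2
  expect_equal(log_likelihood(rep(1, 9), rep(1, 9), sigma = 2),
               log_likelihood(rep(1, 9), rep(1, 9), sigma = 1) - 9 * log(2))
  expect_error(log_likelihood(1, 1, sigma = 0), "positive")

  # term-by-term independent summation over 2 experiments
  set.seed(3)
  y <- list(rnorm(5, 2), rnorm(5, 3))
  f <- list(rep(2, 5), rep(3, 5))
  w <- list(runif(5, 0.5, 2), runif(5, 0.5, 2))
  sigma <- c(0.8, 1.3); psi <- c(0.4, 0.9)
  oracle <- 0
  for (k in 1:2) for (i in 1:5) {
    v <- w[[k]][i]^(-psi[k])
    oracle <- oracle - 0.5 * (log(2 * pi * (sigma[k] * v)^2) +
                                (y[[k]][i] - f[[k]][i])^2 / (sigma[k] * v)^2)
  }
  expect_equal(log_likelihood(y, f, sigma, psi, w), oracle)
})

test_that("fitting the true structure on noiseless data is exact", {
  fx <- tiny_trs_dataset(sigma = 0)
  d <- fx$data
  ft <- fit_given_structure(d, c("A", "B"), c(0.5, 0.5), delta = 0.4,
                            sigma = 1, psi = 0)
  expect_lt(sum(ft$rss), 1e-12)
  expect_equal(unname(ft$tau[c("00", "10")]), c(0.3, 1.2), tolerance = 1e-6)
  expect_equal(unname(ft$M0), c(0.75, 3), tolerance = 1e-6)
  # saturated likelihood: zero residual term
  expect_equal(ft$loglik,
               log_likelihood(lapply(d$obs, `[[`, "y"), ft$fitted,
                              sigma = 1, psi = 0,
                              w = lapply(d$obs, `[[`, "w")))
  # supplying the regulators in the other order changes nothing
  ft2 <- fit_given_structure(d, c("B", "A"), c(0.5, 0.5), delta = 0.4,
                             sigma = 1, psi = 0)
  expect_equal(ft2$loglik, ft$loglik)
})

test_that("experiments with disjoint state sets decouple exactly", {
  # A crosses up in exp1 only (high throughout exp2); B is low in exp1 and
  # high in exp2, and A crosses down in exp2: exp1 sees (0,0),(1,0) and
  # exp2 sees (1,1),(0,1) - no shared rate parameter
  g <- seq(0, 10, length.out = 51)
  A <- regulator_profile("A", list(
    exp1 = list(times = g, values = pmin(1, pmax(0, (g - 2) / 2))),
    exp2 = list(times = g, values = pmin(1, pmax(0.0, 1 - (g - 6) / 2)))))
  B <- regulator_profile("B", list(
    exp1 = list(times = g, values = rep(0.1, 51)),
    exp2 = list(times = g, values = rep(0.9, 51))))
  tau <- c("00" = 0.3, "10" = 1, "11" = 0.8, "01" = 0.2)
  sim <- simulate_from_trs(list(A = A, B = B), c("A", "B"), c(0.5, 0.5),
                           tau, delta = 0.4, M0 = c(1, 2), sigma = 0.05,
                           replicates = 2, seed = 5)
  d1 <- trs_data(sim$data, "target", c("A", "B"), profiles = sim$profiles_df)
  f1 <- fit_given_structure(d1, c("A", "B"), c(0.5, 0.5), 0.4, sigma = 1)
  # perturb experiment 2 observations only
  df2 <- sim$data
  sel <- df2$experiment == "exp2" & df2$gene == "target"
  df2$value[sel] <- df2$value[sel] + 0.5
  d2 <- trs_data(df2, "target", c("A", "B"), profiles = sim$profiles_df)
  f2 <- fit_given_structure(d2, c("A", "B"), c(0.5, 0.5), 0.4, sigma = 1)
  expect_equal(f2$tau[c("00", "10")], f1$tau[c("00", "10")],
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(f2$tau["11"], f1$tau["11"])))
})

test_that("the fit is continuous in psi with OLS at the endpoint", {
  fx <- tiny_trs_dataset(sigma = 0.1)
  d <- fx$data
  f0 <- fit_given_structure(d, c("A", "B"), c(0.5, 0.5), 0.4,
                            sigma = c(1, 1), psi = 0)
  feps <- fit_given_structure(d, c("A", "B"), c(0.5, 0.5), 0.4,
                              sigma = c(1, 1), psi = 1e-9)
  expect_equal(feps$coef, f0$coef, tolerance = 1e-6)
  expect_equal(feps$loglik, f0$loglik, tolerance = 1e-4)
  # psi = 0 equals plain OLS on the same design
  ols <- wls_fit(unlist(lapply(d$obs, `[[`, "y")), f0$design, 1)
  expect_equal(f0$coef, ols$coef, tolerance = 1e-10)
})
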