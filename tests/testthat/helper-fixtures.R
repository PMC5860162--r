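# Shared fixture builders: tiny profiles and datasets constructed in code.

# piecewise-linear regulator profile over [0, L] in one or two experiments
ramp_profile <- function(id = "tfA", L = 10, from = 0, to = 1, K = 1) {
  curves <- lapply(seq_len(K), function(k)
    list(times = c(0, L), values = c(from, to)))
  names(curves) <- paste0("exp", seq_len(K))
  regulator_profile(id, curves)
}

tent_profile <- function(id = "tfT", L = 10, peak = 2, K = 1) {
  curves <- lapply(seq_len(K), function(k)
    list(times = c(0, L / 2, L), values = c(0, peak, 0)))
  names(curves) <- paste0("exp", seq_len(K))
  regulator_profile(id, curves)
}

# two regulators over two experiments realizing the repressed-activation
# interval structure: A rises through 0.5 in exp1 (t=2) and starts high,
# falling at t=7, in exp2; B rises at t=6 (exp1) and t=3 (exp2)
two_tf_profiles <- function(L = 10) {
  lin <- function(t0) {
    # piecewise-linear sigmoid-ish ramp crossing 0.5 at t0
    function(tt) pmin(1, pmax(0, 0.5 + (tt - t0) / 4))
  }
  g <- seq(0, L, length.out = 101)
  mk <- function(f1, f2) list(
    exp1 = list(times = g, values = f1(g)),
    exp2 = list(times = g, values = f2(g)))
  list(
    A = regulator_profile("A", mk(lin(2), function(tt) 1 - lin(7)(tt))),
    B = regulator_profile("B", mk(lin(6), lin(3))))
}

# small exact-model dataset with gentle noise; returns the trs_data and truth
tiny_trs_dataset <- function(seed = 1, sigma = 0.05, replicates = 2,
                             times = NULL) {
  profs <- two_tf_profiles()
  sim <- simulate_from_trs(
    profs, phi = c("A", "B"), rho = c(0.5, 0.5),
    tau = c("00" = 0.3, "10" = 1.2, "11" = 0.3, "01" = 0.3),
    delta = 0.4, M0 = c(0.75, 3), sigma = sigma,
    replicates = replicates, times = times, seed = seed)
  d <- trs_data(sim$data, target = "target",
                candidates = c("A", "B"), profiles = sim$profiles_df)
  list(data = d, sim = sim)
}
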