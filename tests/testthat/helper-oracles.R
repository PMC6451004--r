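# Independent oracles, written without reference to the package internals.

# plain bisection on the implicit depletion equation
oracle_bisect <- function(a_eff, h, n0, time, iter = 200) {
  res <- function(ne) ne - n0 * (1 - exp(a_eff * (ne * h - time)))
  lo <- 0
  hi <- n0
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (res(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# direct summation of the binomial log-likelihood via the factorial formula
oracle_nll <- function(prepared, p_fun) {
  tot <- 0
  for (i in seq_len(nrow(prepared))) {
    n0 <- prepared$corrected_initial[i]
    if (n0 == 0) next
    ne <- prepared$eaten[i]
    p <- min(max(p_fun(n0, prepared$exposure_time[i]) / n0, 1e-9), 1 - 1e-9)
    tot <- tot + lchoose(n0, ne) + ne * log(p) + (n0 - ne) * log(1 - p)
  }
  -tot
}

# iteratively reweighted least squares for a binomial logit GLM,
# written out longhand
oracle_irls <- function(X, eaten, n0, iter = 60) {
  beta <- rep(0, ncol(X))
  y <- eaten / n0
  for (i in seq_len(iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- n0 * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    beta_new <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
    if (max(abs(beta_new - beta)) < 1e-12) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.vector(beta)
}

# one-treatment design of the standard experiment (11 densities x 6 reps,
# 4-h exposure in days)
one_treatment_design <- function(replicates = 6) {
  fr_design(replicates = replicates,
            treatments = tibble::tibble(prey_size = "small",
                                        substrate = "absent"))
}

truth_flexible <- function(b = 0.173, q = 0.739, h = 0.003) {
  fr_truth("flexible", b = b, q = q, h = h)
}

truth_typeII <- function(a = 2.686, h = 0.001) {
  fr_truth("typeII", a = a, h = h)
}

# simulate + prepare a single-treatment dataset in one step
sim_prepared <- function(truth, seed, replicates = 6) {
  fr_prepare_trials(
    fr_simulate_trials(one_treatment_design(replicates), truth, seed = seed),
    exposure_time = 1 / 6)
}

design_densities <- c(5, 10, 15, 20, 30, 50, 75, 100, 150, 200, 300)
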