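# Small fixture builders shared across test files.

# two-modality toy dataset with fixed values
toy_dataset <- function(n = 4) {
  set.seed(99)
  Xn <- matrix(rnorm(n * 3), n, 3,
               dimnames = list(sprintf("s%02d", 1:n), c("g1", "g2", "g3")))
  Xb <- matrix(rbinom(n * 2, 1, 0.5), n, 2,
               dimnames = list(sprintf("s%02d", 1:n), c("m1", "m2")))
  mm_dataset(list(expr = Xn, alt = Xb), kinds = c("normal", "bernoulli"))
}

# a prepared state triple for exercising single coordinate updates
toy_state <- function(data = toy_dataset(), H = 3, seed = 1,
                      hyper = netdpm_hyper(H = H),
                      control = netdpm_control(seed = seed),
                      graphs = empty_graphs(data)) {
  pre <- netdpm:::vb_prepare(data, graphs, hyper)
  state <- netdpm:::vb_init(pre, hyper, control)
  list(pre = pre, state = state, hyper = hyper, control = control)
}

# the scaled-down planted benchmark used throughout: 3 groups, 10% signal,
# Normal means -2/2/6 sd 0.1, Bernoulli 0.2/0.5/0.8, standard-Normal noise
bench_sim <- function(seed, n = 300, p = 200) {
  simulate_multimodal(sim_design(n = n, p = p, seed = seed))
}

# hyperparameters calibrated for the benchmark via the vignette's rule:
# eta above the noise-vs-null evidence (~1.04 nat per subject, taken at the
# full sample) and below the weakest signal evidence per cluster
bench_hyper <- function(H = 10, ...) netdpm_hyper(alpha0 = 1,
                                                  eta = c(200, 5),
                                                  H = H, ...)

bench_fit <- function(sim, seed, ...) {
  suppressWarnings(netdpm(sim$data, hyper = bench_hyper(...),
                          control = netdpm_control(seed = seed)))
}

# selection summaries against planted truth
selection_recovery <- function(fit, sim) {
  occ <- seq_len(max(fit$occupied, 1L))
  sel <- fit$selection
  sig <- rownames(sel) %in% sim$truth$signal_features
  list(
    sensitivity = mean(apply(sel[sig, occ, drop = FALSE], 1L, max) > 0.5),
    specificity = mean(apply(sel[!sig, occ, drop = FALSE], 1L, max) <= 0.5))
}

elbo_monotone <- function(fit, tol = 1e-8) {
  e <- fit$elbo
  length(e) < 2L || all(diff(e) >= -tol * abs(e[-length(e)]))
}
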