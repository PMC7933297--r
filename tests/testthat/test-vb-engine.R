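test_that("stick expectations follow the digamma identities", {
  expect_equal(expected_log_sticks(1, 1), list(Elw = -1, El1w = -1))
  expect_equal(expected_log_sticks(2, 1), list(Elw = -1 / 2, El1w = -3 / 2))
  expect_equal(expected_log_sticks(1, 3),
               list(Elw = -11 / 6, El1w = -1 / 3))
  expect_error(expected_log_sticks(0, 1), "positive")
})

test_that("stick-breaking weights form the telescoping simplex", {
  expect_equal(stick_weights(c(0.5, 0.5, 1)), c(0.5, 0.25, 0.25))
  expect_equal(stick_weights(c(1, 1, 1)), c(1, 0, 0))
  expect_equal(stick_weights(c(0.2, 0.5, 1)), c(0.2, 0.4, 0.4))
  expect_error(stick_weights(c(0.2, 0.5)), "last stick")
  set.seed(1)
  for (i in 1:10) {
    w <- c(runif(5), 1)
    expect_equal(sum(stick_weights(w)), 1)
    expect_true(all(stick_weights(w) >= 0))
  }
})

test_that("initialisation is deterministic and symmetric in selection", {
  tt1 <- toy_state(seed = 5)
  tt2 <- toy_state(seed = 5)
  expect_identical(tt1$state, tt2$state)
  expect_true(all(tt1$state$Q == 0.5))
  expect_true(all(tt1$state$C == 0))
  d <- toy_dataset()
  expect_warning(
    netdpm:::vb_init(netdpm:::vb_prepare(d, empty_graphs(d),
                                         netdpm_hyper(H = 10)),
                     netdpm_hyper(H = 10), netdpm_control(seed = 1)),
    "exceeds")
})

test_that("responsibility update is symmetric for identical clusters and
           sharp for separated ones", {
  tt <- toy_state(H = 2)
  st <- tt$state
  # two exactly identical clusters with symmetric sticks (H = 2, f = g
  # gives equal expected log weights for both components)
  for (f in c("C", "Q")) st[[f]][] <- st[[f]][, 1]
  st$Mn[] <- st$Mn[, 1]; st$Vn[] <- st$Vn[, 1]
  st$Dn[] <- st$Dn[, 1]; st$Rn[] <- st$Rn[, 1]
  st$Sb[] <- st$Sb[, 1]; st$Tb[] <- st$Tb[, 1]
  st$f <- 1; st$g <- 1
  st2 <- netdpm:::vb_update_z(st, tt$pre)
  expect_equal(st2$R[, 1], st2$R[, 2])
  expect_equal(unname(rowSums(st2$R)), rep(1, nrow(st2$R)),
               tolerance = 1e-12)

  # one normal feature, two well-separated clusters, x = 5 near cluster 1
  X <- matrix(c(5, -5), 2, 1, dimnames = list(c("s1", "s2"), "f"))
  d <- mm_dataset(list(m = X), kinds = "normal")
  hy <- netdpm_hyper(H = 2)
  pre <- netdpm:::vb_prepare(d, empty_graphs(d), hy)
  st <- netdpm:::vb_init(pre, hy, netdpm_control(seed = 1))
  st$Q[] <- 1
  st$Mn <- matrix(c(5, -5), 1, 2)
  st$Vn <- matrix(1e6, 1, 2)             # essentially point-mass means
  st$Dn <- matrix(2e6, 1, 2); st$Rn <- matrix(2e6, 1, 2)  # var ~ 1
  st$f <- 1; st$g <- 1
  st2 <- netdpm:::vb_update_z(st, pre)
  expect_gt(st2$R[1, 1], 0.99)
  expect_gt(st2$R[2, 2], 0.99)
})

test_that("stick update accumulates soft counts", {
  tt <- toy_state(H = 3, hyper = netdpm_hyper(alpha0 = 1, H = 3))
  st <- tt$state
  n <- nrow(st$R)
  st$R[] <- 0; st$R[, 1] <- 1            # all mass on cluster 1
  st$N <- colSums(st$R)
  st2 <- netdpm:::vb_update_sticks(st, tt$hyper)
  expect_equal(st2$f[1], 1 + n)
  expect_equal(st2$g[1], 1)
  # n = 4 subjects split evenly over two of three clusters
  st$R[] <- 0; st$R[, 1] <- 0.5; st$R[, 2] <- 0.5
  st$N <- colSums(st$R)
  st3 <- netdpm:::vb_update_sticks(st, tt$hyper)
  expect_equal(st3$f[1], 1 + n / 2)
  expect_equal(st3$g[1], 1 + n / 2)
})

test_that("selection update reflects evidence, penalty and clamp", {
  # a feature exactly matching the null gives ~zero evidence
  set.seed(3)
  X <- matrix(rnorm(40, 0, sqrt(20)), 40, 1,
              dimnames = list(sprintf("s%02d", 1:40), "f"))
  d <- mm_dataset(list(m = X), kinds = "normal")
  for (eta in c(0, 4)) {
    hy <- netdpm_hyper(eta = eta, H = 2, lambda = 1e6)
    # lambda huge pins the active mean to the null mean; active variance
    # posterior then matches the sample, leaving only weak curvature terms
    pre <- netdpm:::vb_prepare(d, empty_graphs(d), hy)
    st <- netdpm:::vb_init(pre, hy, netdpm_control(seed = 1))
    st$Dn[] <- 4e6; st$Rn[] <- 4e6 * 20   # active var pinned to 20
    st$Vn[] <- 1e6; st$Mn[] <- 0
    cache <- netdpm:::vb_cache(st, pre)
    st2 <- netdpm:::vb_update_gamma(st, pre, hy, netdpm_control(seed = 1),
                                    cache)
    expect_equal(st2$C[1, 1], -eta + 0, tolerance = 0.02)
  }
  # clamp contract
  tt <- toy_state()
  ctl <- netdpm_control(seed = 1, logit_clamp = 30)
  st <- tt$state
  st$R[] <- 0; st$R[, 1] <- 1; st$N <- colSums(st$R)
  cache <- netdpm:::vb_cache(st, tt$pre)
  st$Dn[] <- 1e6; st$Rn[] <- 1          # absurdly tight variance: huge |c|
  st2 <- netdpm:::vb_update_gamma(st, tt$pre, tt$hyper, ctl, cache)
  expect_true(all(abs(st2$C) <= 30))
  expect_true(any(abs(st2$C) == 30))
})

test_that("Gaussian block is the weighted conjugate update", {
  X <- matrix(3, 1, 1, dimnames = list("s1", "f"))
  d <- mm_dataset(list(m = X), kinds = "normal")
  hy <- netdpm_hyper(lambda = 1, alpha_sigma = 1, beta_sigma = 1, H = 2)
  pre <- netdpm:::vb_prepare(d, empty_graphs(d), hy)
  st <- suppressWarnings(netdpm:::vb_init(pre, hy,
                                          netdpm_control(seed = 1)))
  # cluster 1 owns the subject with selection probability one
  st$R <- matrix(c(1, 0), 1, 2); st$N <- colSums(st$R)
  st$Q[] <- c(1, 0)
  cache <- netdpm:::vb_cache(st, pre)
  st2 <- netdpm:::vb_update_gauss(st, pre, hy, cache)
  expect_equal(unname(st2$Vn[1, 1]), 2)          # lambda + 1
  expect_equal(unname(st2$Mn[1, 1]), 1.5)        # 3 / 2
  expect_equal(unname(st2$Dn[1, 1]), 3)          # 2 alpha + 1
  # zero-weight cluster stays at the prior
  expect_equal(unname(st2$Vn[1, 2]), hy$lambda)
  expect_equal(unname(st2$Mn[1, 2]), 0)
  expect_equal(unname(st2$Dn[1, 2]), 2 * hy$alpha_sigma)
  expect_equal(unname(st2$Rn[1, 2]), 2 * hy$beta_sigma)
})

test_that("Gaussian block is invariant to splitting responsibilities", {
  set.seed(8)
  X <- matrix(rnorm(6), 6, 1, dimnames = list(sprintf("s%d", 1:6), "f"))
  d1 <- mm_dataset(list(m = X), kinds = "normal")
  X2 <- rbind(X, X); rownames(X2) <- sprintf("s%d", 1:12)
  d2 <- mm_dataset(list(m = X2), kinds = "normal")
  hy <- netdpm_hyper(H = 2)
  fitpars <- function(d, w) {
    pre <- netdpm:::vb_prepare(d, empty_graphs(d), hy)
    st <- netdpm:::vb_init(pre, hy, netdpm_control(seed = 1))
    st$R <- matrix(c(rep(w, d$n), rep(1 - w, d$n)), d$n, 2)
    st$N <- colSums(st$R); st$Q[] <- 1
    cache <- netdpm:::vb_cache(st, pre)
    st2 <- netdpm:::vb_update_gauss(st, pre, hy, cache)
    lapply(st2[c("Mn", "Vn", "Dn", "Rn")], function(m) m[, 1])
  }
  expect_equal(fitpars(d1, 1), fitpars(d2, 0.5))
})

test_that("Bernoulli block counts successes with soft weights", {
  X <- matrix(c(1, 1, 0), 3, 1, dimnames = list(sprintf("s%d", 1:3), "f"))
  d <- mm_dataset(list(m = X), kinds = "bernoulli")
  hy <- netdpm_hyper(alpha_p = 1, beta_p = 1, H = 2)
  pre <- netdpm:::vb_prepare(d, empty_graphs(d), hy)
  st <- suppressWarnings(netdpm:::vb_init(pre, hy,
                                          netdpm_control(seed = 1)))
  st$R <- cbind(rep(1, 3), rep(0, 3)); st$N <- colSums(st$R)
  st$Q[] <- c(1, 0)
  cache <- netdpm:::vb_cache(st, pre)
  st2 <- netdpm:::vb_update_bern(st, pre, hy, cache)
  expect_equal(unname(st2$Sb[1, 1]), 3)          # alpha_p + 2 successes
  expect_equal(unname(st2$Tb[1, 1]), 2)          # beta_p + 1 failure
  expect_equal(unname(st2$Sb[1, 2]), 1)          # untouched prior
  # soft weights
  X <- matrix(c(1, 0), 2, 1, dimnames = list(c("s1", "s2"), "f"))
  d <- mm_dataset(list(m = X), kinds = "bernoulli")
  pre <- netdpm:::vb_prepare(d, empty_graphs(d), hy)
  st <- netdpm:::vb_init(pre, hy, netdpm_control(seed = 1))
  st$R <- matrix(0.5, 2, 2); st$N <- colSums(st$R); st$Q[] <- 1
  st2 <- netdpm:::vb_update_bern(st, pre, hy, netdpm:::vb_cache(st, pre))
  expect_equal(unname(st2$Sb[1, 1]), 1.5)
  expect_equal(unname(st2$Tb[1, 1]), 1.5)
})

test_that("each blockwise update never decreases the ELBO", {
  set.seed(21)
  sim <- simulate_multimodal(sim_design(n = 40, p = 16, seed = 21))
  gs <- simulate_graphset(sim, within_density = 0.5, seed = 21)
  hy <- netdpm_hyper(eta = c(25, 2), nu = 1, H = 4)
  ctl <- netdpm_control(seed = 21)
  pre <- netdpm:::vb_prepare(sim$data, gs, hy)
  st <- netdpm:::vb_init(pre, hy, ctl)
  cache <- netdpm:::vb_cache(st, pre)
  st <- netdpm:::vb_update_sticks(st, hy)
  e <- netdpm:::vb_elbo(st, pre, hy)
  for (sweep in 1:4) {
    st <- netdpm:::vb_update_z(st, pre)
    cache <- netdpm:::vb_cache(st, pre)
    for (blk in c("sticks", "gamma", "gauss", "bern")) {
      st <- switch(blk,
        sticks = netdpm:::vb_update_sticks(st, hy),
        gamma = netdpm:::vb_update_gamma(st, pre, hy, ctl, cache),
        gauss = netdpm:::vb_update_gauss(st, pre, hy, cache),
        bern = netdpm:::vb_update_bern(st, pre, hy, cache))
      e2 <- netdpm:::vb_elbo(st, pre, hy)
      expect_gte(e2, e - 1e-8 * abs(e))
      e <- e2
    }
  }
})

test_that("fits are deterministic given the seed", {
  sim <- bench_sim(31, n = 80, p = 40)
  f1 <- bench_fit(sim, 31)
  f2 <- bench_fit(sim, 31)
  expect_identical(f1$elbo, f2$elbo)
  expect_identical(f1$labels, f2$labels)
})

test_that("degenerate data collapse to a single occupied cluster", {
  X <- matrix(rep(c(1.5, -0.5, 0.25), each = 30), 30, 3,
              dimnames = list(sprintf("s%02d", 1:30), c("a", "b", "c")))
  d <- mm_dataset(list(m = X), kinds = "normal")
  fit <- suppressWarnings(
    netdpm(d, hyper = netdpm_hyper(eta = 10, H = 5),
           control = netdpm_control(seed = 2)))
  expect_equal(fit$occupied, 1L)
  expect_equal(length(unique(fit$labels)), 1L)
})

test_that("fit output satisfies its structural invariants", {
  sim <- bench_sim(32, n = 120, p = 60)
  fit <- bench_fit(sim, 32)
  expect_true(all(fit$labels >= 1 & fit$labels <= 10))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
  expect_true(all(fit$selection >= 0 & fit$selection <= 1))
  expect_true(all(diff(fit$cluster_sizes) <= 1e-8))   # size-ordered
  expect_true(all(fit$params$var > 0))
  expect_true(all(fit$params$prob > 0 & fit$params$prob < 1))
  expect_true(elbo_monotone(fit))
})

test_that("subject order equivariance and feature order invariance hold", {
  sim <- bench_sim(33, n = 90, p = 40)
  fit <- bench_fit(sim, 33)
  # permute subjects
  perm <- sample(sim$data$n)
  d2 <- sim$data
  for (m in seq_along(d2$modalities))
    d2$modalities[[m]]$X <- d2$modalities[[m]]$X[perm, ]
  d2$sample_ids <- d2$sample_ids[perm]
  fit2 <- suppressWarnings(netdpm(d2, hyper = bench_hyper(),
                                  control = netdpm_control(seed = 33,
                                                           init = "random")))
  fit1r <- suppressWarnings(netdpm(sim$data, hyper = bench_hyper(),
                                   control = netdpm_control(seed = 33,
                                                            init = "random")))
  # k-means is order-sensitive, so equivariance is asserted through the
  # partition itself rather than raw labels
  expect_equal(rand_index(fit1r$labels[d2$sample_ids], fit2$labels)$rand, 1)

  # permute features within the first modality
  d3 <- sim$data
  fperm <- sample(ncol(d3$modalities[[1]]$X))
  d3$modalities[[1]]$X <- d3$modalities[[1]]$X[, fperm]
  d3$registry <- unlist(lapply(d3$modalities, function(m)
    paste(m$name, colnames(m$X), sep = ":")), use.names = FALSE)
  fit3 <- suppressWarnings(netdpm(d3, hyper = bench_hyper(),
                                  control = netdpm_control(seed = 33)))
  expect_equal(rand_index(fit$labels, fit3$labels)$rand, 1)
})

test_that("an overwhelming sparsity penalty empties the selection", {
  sim <- bench_sim(34, n = 60, p = 30)
  fit <- suppressWarnings(
    netdpm(sim$data, hyper = netdpm_hyper(eta = 1e5, nu = 0, H = 5),
           control = netdpm_control(seed = 34)))
  expect_true(all(fit$selection < 0.5))
  # with no features selected every subject is scored identically, so the
  # point partition is a single cluster (soft mass may still spread)
  expect_equal(length(unique(fit$labels)), 1L)
})

test_that("planted parameters are recovered by the posterior means", {
  sim <- bench_sim(35)
  fit <- bench_fit(sim, 35)
  expect_equal(fit$occupied, 3L)
  # match clusters to planted groups through the labels
  map <- sapply(1:3, function(h)
    as.integer(names(which.max(table(
      sim$truth$labels[fit$labels == h])))))
  expect_equal(sort(map), 1:3)
  des <- sim$truth$design
  sig_n <- paste0("expr:",
                  colnames(sim$data$modalities[[1]]$X)[
                    sim$truth$signal_cols[[1]]])
  sig_b <- paste0("alt:",
                  colnames(sim$data$modalities[[2]]$X)[
                    sim$truth$signal_cols[[2]]])
  for (h in 1:3) {
    g <- map[h]
    expect_lt(max(abs(fit$params$mean[sig_n, h] - des$normal_means[g])),
              0.1)
    expect_lt(mean(abs(fit$params$prob[sig_b, h] - des$bern_probs[g])),
              0.05)
  }
})

test_that("classification matches fitted labels and generalises", {
  sim <- bench_sim(36)
  fit <- bench_fit(sim, 36)
  # refitting the training subjects reproduces their labels
  self <- predict(fit, sim$data)
  expect_equal(unname(self), unname(fit$labels))
  pr <- predict(fit, sim$data, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, sim$data$n), tolerance = 1e-12)
  # holdout subjects drawn from the same planted feature structure
  holdout <- simulate_multimodal(sim_design(n = 300, p = 200, seed = 37),
                                 truth = sim$truth)
  cls <- predict(fit, holdout$data)
  expect_gte(rand_index(cls, holdout$truth$labels)$rand, 0.95)
  # feature mismatch is structural
  expect_error(predict(fit, toy_dataset()), "registry")
})
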