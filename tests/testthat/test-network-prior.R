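graph_toy <- function() {
  X <- matrix(rnorm(2 * 4), 2, 4,
              dimnames = list(c("s1", "s2"), c("a", "b", "c", "d")))
  B <- matrix(rbinom(2 * 2, 1, 0.5), 2, 2,
              dimnames = list(c("s1", "s2"), c("x", "y")))
  mm_dataset(list(expr = X, alt = B), kinds = c("normal", "bernoulli"))
}

test_that("graph construction dedupes, drops self-loops and counts edges", {
  d <- graph_toy()
  g <- graph_set(d, within = list(expr = rbind(c("a", "b"), c("b", "a"),
                                               c("a", "a"))))
  expect_equal(g$e, 1L)
  expect_equal(empty_graphs(d)$e, 0L)
  full <- graph_set(d, within = list(
    expr = t(combn(c("a", "b", "c"), 2))))
  expect_equal(full$e, 3L)
})

test_that("graph construction rejects bad inputs", {
  d <- graph_toy()
  expect_error(graph_set(d, within = list(expr = rbind(c("a", "zz")))),
               "unresolvable.*zz")
  expect_error(graph_set(d, cross = list("expr:expr" = rbind(c("a", "b")))),
               "single modality")
  expect_error(graph_set(d, within = list(nope = rbind(c("a", "b")))),
               "unknown modality")
})

test_that("Ising log-potential matches hand-computed examples", {
  d <- graph_toy()
  g0 <- empty_graphs(d)
  # sparsity only: 3 active features, eta = 1 everywhere
  expect_equal(
    ising_log_potential(list(c(1, 1, 0, 1), c(0, 0)), g0, eta = 1), -3)
  # one satisfied within-modality edge
  g1 <- graph_set(d, within = list(expr = rbind(c("a", "b"))))
  expect_equal(
    ising_log_potential(list(c(1, 1, 0, 0), c(0, 0)), g1,
                        eta = 0, nu = 2), 2)
  # chain a-b-c, gamma = (1,1,0,...): one concordant edge of two
  g2 <- graph_set(d, within = list(expr = rbind(c("a", "b"), c("b", "c"))))
  expect_equal(
    ising_log_potential(list(c(1, 1, 0, 0), c(0, 0)), g2,
                        eta = 1, nu = 1), -1)
})

test_that("Ising potential is exchangeable when smoothness is zero and
           saturates for constant configurations", {
  d <- graph_toy()
  set.seed(2)
  g <- graph_set(d,
                 within = list(expr = rbind(c("a", "b"), c("c", "d")),
                               alt = rbind(c("x", "y"))),
                 cross = list("expr:alt" = rbind(c("a", "x"), c("b", "y"))))
  gam1 <- list(c(1, 0, 1, 0), c(1, 0))
  gam2 <- list(c(0, 1, 0, 1), c(0, 1))   # same per-modality counts
  expect_equal(ising_log_potential(gam1, g, eta = c(2, 3), nu = 0),
               ising_log_potential(gam2, g, eta = c(2, 3), nu = 0))
  # fully active: every indicator agrees
  expect_equal(
    ising_log_potential(list(rep(1, 4), rep(1, 2)), g, eta = 0,
                        nu = c(2, 3), nu_cross = 5),
    2 * 2 + 3 * 1 + 5 * 2)
  expect_equal(
    ising_log_potential(list(rep(0, 4), rep(0, 2)), g, eta = 0,
                        nu = c(2, 3), nu_cross = 5),
    2 * 2 + 3 * 1 + 5 * 2)
})

test_that("edge concordance expectation enumerates correctly", {
  expect_equal(edge_concordance(1, 1), 1)
  expect_equal(edge_concordance(0.5, 0.5), 0.5)
  expect_equal(edge_concordance(0.3, 0.8), 0.3 * 0.8 + 0.7 * 0.2)
  expect_error(edge_concordance(1.2, 0.5), "\\[0, 1\\]")
})

test_that("neighbour field matches hand examples and the brute-force
           expectation difference", {
  d <- graph_toy()
  g <- graph_set(d, within = list(expr = rbind(c("a", "b"), c("a", "c"))))
  # isolated feature d: field = -eta
  Q <- matrix(0.5, 6, 2)
  fld <- ising_field(Q, g, eta = c(2, 0), nu = 1)
  expect_equal(fld[4, 1], -2)              # feature "d", isolated
  # one neighbour with probability 1
  Q2 <- Q; Q2[2, ] <- 1                    # neighbour "b" of "a"
  fld2 <- ising_field(Q2, g, eta = c(0, 0), nu = 3)
  # a has neighbours b (prob 1 -> +3) and c (prob .5 -> 0)
  expect_equal(fld2[1, 1], 3)
  # two neighbours 0.9 / 0.1, eta = 1, nu = 1 -> -1 + 0.8 - 0.8
  Q3 <- Q; Q3[2, ] <- 0.9; Q3[3, ] <- 0.1
  fld3 <- ising_field(Q3, g, eta = c(1, 0), nu = 1)
  expect_equal(fld3[1, 1], -1)

  # oracle: E[potential | gamma_j = 1] - E[potential | gamma_j = 0] by
  # exhaustive enumeration over the other features' Bernoullis
  set.seed(7)
  qv <- runif(6)
  Qr <- matrix(qv, 6, 1)
  fld_all <- ising_field(Qr, g, eta = c(1.3, 0.4), nu = 0.9)
  enum_field <- function(j) {
    others <- setdiff(1:6, j)
    tot <- c(0, 0)
    for (bits in 0:(2^5 - 1)) {
      gam <- integer(6)
      gam[others] <- as.integer(intToBits(bits))[1:5]
      w <- prod(ifelse(gam[others] == 1, qv[others], 1 - qv[others]))
      for (gj in 0:1) {
        gam[j] <- gj
        pot <- ising_log_potential(list(gam[1:4], gam[5:6]), g,
                                   eta = c(1.3, 0.4), nu = 0.9)
        tot[gj + 1] <- tot[gj + 1] + w * pot
      }
    }
    tot[2] - tot[1]
  }
  for (j in c(1, 2, 4, 5))
    expect_equal(fld_all[j, 1], enum_field(j), tolerance = 1e-10)
})

test_that("a Gibbs chain on the Ising prior reproduces enumerated
           marginals", {
  d <- graph_toy()
  g <- graph_set(d, within = list(expr = rbind(c("a", "b"), c("b", "c"))),
                 cross = list("expr:alt" = rbind(c("c", "x"))))
  eta <- c(0.5, 0.2); nu <- 0.8; nuc <- 0.6
  pot <- function(gam) ising_log_potential(list(gam[1:4], gam[5:6]), g,
                                           eta = eta, nu = nu,
                                           nu_cross = nuc)
  # exhaustive normalisation over the 2^6 configurations
  configs <- as.matrix(expand.grid(rep(list(0:1), 6)))
  lp <- apply(configs, 1, pot)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  marg <- colSums(configs * pr)
  # single-site Gibbs over the same unnormalised potential
  set.seed(11)
  gam <- integer(6); acc <- numeric(6)
  iters <- 6000
  for (it in seq_len(iters)) {
    for (j in 1:6) {
      g1 <- gam; g1[j] <- 1L; g0 <- gam; g0[j] <- 0L
      pj <- plogis(pot(g1) - pot(g0))
      gam[j] <- as.integer(runif(1) < pj)
    }
    if (it > 1000) acc <- acc + gam
  }
  expect_equal(unname(acc / (iters - 1000)), unname(marg),
               tolerance = 0.05)
})
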