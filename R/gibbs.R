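#' Gibbs sampler configuration
#'
#' @param iters Total iterations.
#' @param burnin Discarded initial iterations (`< iters`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed.
#' @param H Truncation level of the blocked sampler.
#' @return An object of class `"gibbs_config"`.
#' @export
gibbs_config <- function(iters = 2000L, burnin = 1000L, thin = 2L,
                         seed = 1L, H = 10L) {
  iters <- as.integer(iters); burnin <- as.integer(burnin)
  stopifnot(iters > burnin, burnin >= 0L, thin >= 1L, H >= 2L)
  structure(list(iters = iters, burnin = burnin, thin = as.integer(thin),
                 seed = as.integer(seed), H = as.integer(H)),
            class = "gibbs_config")
}

#' Blocked Gibbs sampler for the network-guided DP mixture
#'
#' Reference posterior sampler for the same model fitted by [netdpm()],
#' intended as a small-scale correctness oracle for the variational engine.
#' It alternates full-conditional draws of cluster labels (categorical given
#' stick weights and likelihoods), truncated sticks (Beta), selection
#' indicators (Bernoulli with log-odds = likelihood difference plus the
#' Ising conditional over current neighbour states), and active parameters
#' (Normal-Inverse-Gamma / Beta conjugate posteriors over the subjects
#' currently in each cluster with the feature selected).
#'
#' @inheritParams netdpm
#' @param config See [gibbs_config()].
#' @param guard Refuse instances with `n * p * H` above this bound unless
#'   raised (the sampler is deliberately small-scale).
#' @return An object of class `"netdpm_gibbs"`: retained draws of `z`
#'   (draws x n), `w` (draws x H), the running mean of `gamma` per cluster
#'   and the last parameter state.
#' @export
netdpm_gibbs <- function(data, graphs = NULL, hyper = netdpm_hyper(),
                         config = gibbs_config(), guard = 1e7) {
  stopifnot(inherits(data, "netdpm_data"))
  validate_dataset(data)
  if (is.null(graphs)) graphs <- empty_graphs(data)
  H <- config$H
  if (data$n * data$p * H > guard)
    stop("instance too large for the reference sampler (n*p*H = ",
         data$n * data$p * H, " > guard); raise `guard` to override",
         call. = FALSE)
  pre <- vb_prepare(data, graphs, hyper)
  n <- pre$n; p <- pre$p
  set.seed(config$seed)
  # initial labels from k-means (pure fragments give sharp first parameter
  # draws); the sparsity penalty is ramped up over the first part of
  # burn-in so that selection indicators of still-small fragments are not
  # all absorbed into the null before fragments of one population merge.
  # Retained draws are taken after burn-in at the full penalty, so the
  # stationary distribution is untouched.
  Zs <- scale(cbind(pre$Xn, pre$Xb)); Zs[!is.finite(Zs)] <- 0
  z <- tryCatch(
    stats::kmeans(Zs, centers = min(H, n), nstart = 5L,
                  iter.max = 50L)$cluster,
    error = function(e) sample.int(H, n, replace = TRUE))
  Gam <- matrix(1L, p, H)   # start fully selected; eta ramps up from 0
  Mu <- matrix(0, pre$p1, H)
  S2 <- matrix(1, pre$p1, H)
  Pr <- matrix(0.5, pre$p2, H)
  w <- rep(1 / H, H)
  keep <- seq(config$burnin + 1L, config$iters, by = config$thin)
  Zd <- matrix(NA_integer_, length(keep), n)
  Wd <- matrix(NA_real_, length(keep), H)
  Gsum <- matrix(0, p, H)
  kidx <- 0L
  clamp <- 500
  ramp_end <- max(1L, config$burnin)
  for (it in seq_len(config$iters)) {
    eta_it <- pre$eta_vec * min(1, it / ramp_end)
    # --- sticks given current label counts
    nh <- tabulate(z, H)
    tails <- rev(cumsum(rev(nh)))
    v <- stats::rbeta(H - 1L, 1 + nh[-H], hyper$alpha0 + c(tails, 0)[2:H])
    wts <- stick_weights(c(v, 1))
    lw <- log(pmax(wts, 1e-300))
    # --- per-cluster sufficient statistics of the current labels
    Rz <- matrix(0, n, H); Rz[cbind(seq_len(n), z)] <- 1
    TXnR <- if (pre$p1) crossprod(pre$Xn, Rz) else NULL
    TXn2R <- if (pre$p1) crossprod(pre$Xn2, Rz) else NULL
    TLnR <- if (pre$p1) crossprod(pre$lnull_n, Rz) else NULL
    TXbR <- if (pre$p2) crossprod(pre$Xb, Rz) else NULL
    TLbR <- if (pre$p2) crossprod(pre$lnull_b, Rz) else NULL
    # --- active parameters from conjugate posteriors
    if (pre$p1) {
      Gn <- Gam[pre$nidx, , drop = FALSE]
      Nm <- matrix(nh, pre$p1, H, byrow = TRUE)
      W <- Gn * Nm
      Vp <- hyper$lambda + W
      Mp <- Gn * TXnR / Vp
      Ap <- hyper$alpha_sigma + W / 2
      Bp <- hyper$beta_sigma +
        pmax(Gn * TXn2R - Vp * Mp^2, 0) / 2
      S2 <- 1 / stats::rgamma(length(Ap), shape = Ap, rate = Bp)
      dim(S2) <- dim(Ap)
      S2 <- pmin(pmax(S2, 1e-8), 1e8)
      Mu <- Mp + sqrt(S2 / Vp) * stats::rnorm(length(Mp))
      dim(Mu) <- dim(Mp)
    }
    if (pre$p2) {
      Gb <- Gam[pre$bidx, , drop = FALSE]
      Nm <- matrix(nh, pre$p2, H, byrow = TRUE)
      Sp <- hyper$alpha_p + Gb * TXbR
      Tp <- hyper$beta_p + Gb * (Nm - TXbR)
      Pr <- stats::rbeta(length(Sp), Sp, Tp)
      dim(Pr) <- dim(Sp)
      Pr <- pmin(pmax(Pr, 1e-6), 1 - 1e-6)
    }
    # --- selection indicators: likelihood log-odds + Ising conditional
    L <- matrix(0, p, H)
    if (pre$p1) {
      Nm <- matrix(nh, pre$p1, H, byrow = TRUE)
      L[pre$nidx, ] <- Nm * (-0.5 * (LOG2PI + log(S2))) -
        0.5 * (TXn2R - 2 * Mu * TXnR + Nm * Mu^2) / S2 - TLnR
    }
    if (pre$p2) {
      Nm <- matrix(nh, pre$p2, H, byrow = TRUE)
      L[pre$bidx, ] <- log(Pr) * TXbR + log1p(-Pr) * (Nm - TXbR) - TLbR
    }
    free <- setdiff(seq_len(p), pre$coupled)
    if (length(free)) {
      lo <- pmin(pmax(L[free, , drop = FALSE] - eta_it[free],
                      -clamp), clamp)
      Gam[free, ] <- (matrix(stats::runif(length(lo)), nrow(lo)) <
                        stats::plogis(lo)) + 0L
    }
    for (j in pre$coupled) {       # systematic scan in registry order
      nb <- pre$adj[[j]]
      fld <- colSums((2 * Gam[nb[, 1L], , drop = FALSE] - 1) * nb[, 2L])
      lo <- pmin(pmax(L[j, ] - eta_it[j] + fld, -clamp), clamp)
      Gam[j, ] <- (stats::runif(H) < stats::plogis(lo)) + 0L
    }
    # --- labels given sticks, selection and parameters
    LL <- matrix(lw, n, H, byrow = TRUE)
    if (pre$p1) {
      Gn <- Gam[pre$nidx, , drop = FALSE]
      A2 <- Gn / S2
      LL <- LL - 0.5 * (pre$Xn2 %*% A2) + pre$Xn %*% (A2 * Mu) +
        matrix(colSums(Gn * (-0.5 * (LOG2PI + log(S2)))) -
                 0.5 * colSums(A2 * Mu^2), n, H, byrow = TRUE) +
        pre$lnull_n %*% (1 - Gn)
    }
    if (pre$p2) {
      Gb <- Gam[pre$bidx, , drop = FALSE]
      LL <- LL + pre$Xb %*% (Gb * (log(Pr) - log1p(-Pr))) +
        matrix(colSums(Gb * log1p(-Pr)), n, H, byrow = TRUE) +
        pre$lnull_b %*% (1 - Gb)
    }
    Pz <- exp(LL - row_log_sum_exp(LL))
    u <- stats::runif(n)
    cs <- t(apply(Pz, 1L, cumsum))     # inverse-cdf draw, vectorised
    z <- rowSums(u > cs) + 1L
    z[z > H] <- H
    if (it %in% keep) {
      kidx <- kidx + 1L
      Zd[kidx, ] <- z
      Wd[kidx, ] <- wts
      Gsum <- Gsum + Gam
    }
  }
  structure(
    list(z = Zd, w = Wd, gamma_mean = Gsum / max(kidx, 1L),
         last = list(z = z, gamma = Gam, mu = Mu, sigma2 = S2, prob = Pr),
         sample_ids = data$sample_ids, registry = data$registry,
         config = config),
    class = "netdpm_gibbs")
}

#' @export
print.netdpm_gibbs <- function(x, ...) {
  cat("Blocked Gibbs reference:", nrow(x$z), "retained draws over",
      ncol(x$z), "subjects\n")
  invisible(x)
}

#' Posterior co-clustering summary of Gibbs draws
#'
#' Computes the posterior similarity matrix (fraction of retained draws in
#' which two subjects share a cluster) and a point partition: the retained
#' draw with maximal Rand index against the partition obtained by
#' thresholding the similarity matrix at 0.5 and taking connected
#' components (ties broken toward the earliest draw).
#'
#' @param draws A `"netdpm_gibbs"` object.
#' @return A list with `psm` (n x n matrix) and `partition` (integer
#'   labels).
#' @export
posterior_similarity <- function(draws) {
  stopifnot(inherits(draws, "netdpm_gibbs"))
  Z <- draws$z
  D <- nrow(Z); n <- ncol(Z)
  if (D < 1L) stop("no retained draws", call. = FALSE)
  psm <- matrix(0, n, n)
  for (d in seq_len(D))
    psm <- psm + outer(Z[d, ], Z[d, ], "==")
  psm <- psm / D
  dimnames(psm) <- list(draws$sample_ids, draws$sample_ids)
  # connected components of the thresholded similarity graph
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      stack <- i
      while (length(stack)) {
        v <- stack[[1L]]; stack <- stack[-1L]
        if (comp[v] == 0L) {
          comp[v] <- cur
          stack <- c(stack, which(psm[v, ] >= 0.5 & comp == 0L))
        }
      }
    }
  }
  ri <- vapply(seq_len(D), function(d) rand_index(Z[d, ], comp)$rand, 0)
  best <- which.max(ri)     # which.max takes the earliest maximum
  part <- Z[best, ]
  names(part) <- draws$sample_ids
  list(psm = psm, partition = part, best_draw = best)
}
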