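LOG2PI <- log(2 * pi)

#' Expected log stick proportions under a Beta variational factor
#'
#' For `w ~ Beta(f, g)`, returns `E[log w] = psi(f) - psi(f + g)` and
#' `E[log(1 - w)] = psi(g) - psi(f + g)` (digamma identities).  Vectorised.
#'
#' @param f,g Positive Beta parameters.
#' @return A list with components `Elw` and `El1w`.
#' @export
expected_log_sticks <- function(f, g) {
  if (any(f <= 0) || any(g <= 0))
    stop("Beta parameters must be positive", call. = FALSE)
  list(Elw = digamma(f) - digamma(f + g),
       El1w = digamma(g) - digamma(f + g))
}

#' Stick-breaking weights
#'
#' Maps stick proportions `w` (with the last entry fixed to 1 by the
#' truncation) to mixture weights `w'_h = w_h prod_{l<h} (1 - w_l)`.
#'
#' @param w Vector in `[0, 1]` whose last entry equals 1.
#' @return A nonnegative vector summing to 1.
#' @export
stick_weights <- function(w) {
  H <- length(w)
  if (any(w < 0 | w > 1)) stop("sticks must lie in [0, 1]", call. = FALSE)
  if (w[H] != 1)
    stop("the last stick must equal 1 (truncation)", call. = FALSE)
  w * cumprod(c(1, 1 - w[-H]))
}

# E[log w'_h] for h = 1..H from variational Beta sticks (H-th stick == 1)
elog_stick_weights <- function(f, g) {
  H <- length(f) + 1L
  es <- expected_log_sticks(f, g)
  cum <- c(0, cumsum(es$El1w))
  c(es$Elw + cum[seq_len(H - 1L)], cum[H])
}

row_log_sum_exp <- function(B) {
  m <- do.call(pmax, c(as.data.frame(B), list(na.rm = FALSE)))
  m + log(rowSums(exp(B - m)))
}

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# ---------------------------------------------------------------------------
# Pre-computed fixed quantities for a fit

vb_prepare <- function(data, graphs, hyper) {
  kinds <- feature_kinds(data)
  midx <- feature_modality(data)
  nidx <- which(kinds == "normal")
  bidx <- which(kinds == "bernoulli")
  Xn <- if (length(nidx))
    do.call(cbind, lapply(data$modalities, function(m)
      if (m$kind == "normal") m$X else NULL))
  else matrix(0, data$n, 0L)
  Xb <- if (length(bidx))
    do.call(cbind, lapply(data$modalities, function(m)
      if (m$kind == "bernoulli") m$X else NULL))
  else matrix(0, data$n, 0L)
  lnull_n <- if (length(nidx))
    stats::dnorm(Xn, data$null$mu0, sqrt(data$null$sigma0_sq), log = TRUE)
  else Xn
  lnull_b <- if (length(bidx))
    Xb * log(data$null$p0) + (1 - Xb) * log1p(-data$null$p0)
  else Xb
  M <- length(data$modalities)
  eta_m <- rep_len(hyper$eta, M)
  p_m <- vapply(data$modalities, function(m) ncol(m$X), 0L)
  eta_vec <- rep(eta_m, p_m)
  edges <- global_edges(graphs, hyper$nu, hyper$nu_cross)
  adj <- adjacency_list(edges, data$p)
  coupled <- which(!vapply(adj, is.null, TRUE))
  list(n = data$n, p = data$p, p1 = length(nidx), p2 = length(bidx),
       nidx = nidx, bidx = bidx, Xn = Xn, Xn2 = Xn * Xn, Xb = Xb,
       lnull_n = lnull_n, lnull_b = lnull_b, eta_vec = eta_vec,
       edges = edges, adj = adj, coupled = coupled, e = length(edges$w))
}

# ---------------------------------------------------------------------------
# Variational state

vb_init <- function(pre, hyper, control) {
  n <- pre$n; H <- hyper$H
  set.seed(control$seed)
  if (H > n)
    warning("truncation level H = ", H, " exceeds n = ", n,
            "; surplus clusters will stay empty", call. = FALSE)
  R <- matrix(1 / H, n, H)
  if (control$init == "kmeans") {
    Z <- cbind(pre$Xn, pre$Xb)
    Z <- scale(Z)
    Z[!is.finite(Z)] <- 0
    K <- min(H, n, max(1L, nrow(unique(Z))))
    cl <- tryCatch(
      stats::kmeans(Z, centers = K, nstart = 5L, iter.max = 50L)$cluster,
      error = function(e) sample.int(K, n, replace = TRUE))
    # hard assignments: soft smearing here would let every cluster absorb
    # a sliver of cross-group mass and blur the initial variances
    R <- matrix(0, n, H)
    R[cbind(seq_len(n), cl)] <- 1
  } else {
    R <- matrix(stats::rexp(n * H), n, H)
    R <- R / rowSums(R)
  }
  list(R = R, N = colSums(R),
       f = rep(1, H - 1L), g = rep(hyper$alpha0, H - 1L),
       C = matrix(0, pre$p, H), Q = matrix(0.5, pre$p, H),
       Mn = matrix(0, pre$p1, H), Vn = matrix(hyper$lambda, pre$p1, H),
       Dn = matrix(2 * hyper$alpha_sigma, pre$p1, H),
       Rn = matrix(2 * hyper$beta_sigma, pre$p1, H),
       Sb = matrix(hyper$alpha_p, pre$p2, H),
       Tb = matrix(hyper$beta_p, pre$p2, H))
}

# x-independent part of E_q[log N(x; mu_jh, sigma2_jh)] and the quadratic
# coefficient E[1/sigma2] = d/r
gauss_expect <- function(state) {
  elog_s2 <- log(state$Rn / 2) - digamma(state$Dn / 2)
  dr <- state$Dn / state$Rn
  list(cn = -0.5 * (LOG2PI + elog_s2 + 1 / state$Vn), dr = dr,
       elog_s2 = elog_s2)
}

bern_expect <- function(state) {
  dst <- digamma(state$Sb + state$Tb)
  list(psis = digamma(state$Sb) - dst, psit = digamma(state$Tb) - dst)
}

# n x H matrix of E_q-weighted per-subject per-cluster scores:
# E[log w'_h] + sum_j { q_jh E[log f_act] + (1 - q_jh) log f_null }
vb_scores <- function(state, pre) {
  n <- pre$n; H <- ncol(state$R)
  Qn <- state$Q[pre$nidx, , drop = FALSE]
  Qb <- state$Q[pre$bidx, , drop = FALSE]
  B <- matrix(elog_stick_weights(state$f, state$g), n, H, byrow = TRUE)
  if (pre$p1) {
    ge <- gauss_expect(state)
    A2 <- Qn * ge$dr
    B <- B - 0.5 * (pre$Xn2 %*% A2) + pre$Xn %*% (A2 * state$Mn) +
      matrix(colSums(Qn * ge$cn) - 0.5 * colSums(A2 * state$Mn^2),
             n, H, byrow = TRUE)
    B <- B + pre$lnull_n %*% (1 - Qn)
  }
  if (pre$p2) {
    be <- bern_expect(state)
    B <- B + pre$Xb %*% (Qb * (be$psis - be$psit)) +
      matrix(colSums(Qb * be$psit), n, H, byrow = TRUE)
    B <- B + pre$lnull_b %*% (1 - Qb)
  }
  B
}

vb_update_z <- function(state, pre) {
  B <- vb_scores(state, pre)
  logR <- B - row_log_sum_exp(B)
  state$R <- exp(logR)
  state$logR <- logR
  state$N <- colSums(state$R)
  state
}

vb_update_sticks <- function(state, hyper) {
  H <- length(state$N)
  tailsum <- rev(cumsum(rev(state$N)))      # sum_{l >= h} N_l
  state$f <- 1 + state$N[-H]
  state$g <- hyper$alpha0 + c(tailsum, 0)[2:H]
  state
}

# responsibility-weighted sufficient statistics, valid until R changes
vb_cache <- function(state, pre) {
  list(TXnR = crossprod(pre$Xn, state$R),
       TXn2R = crossprod(pre$Xn2, state$R),
       TLnR = crossprod(pre$lnull_n, state$R),
       TXbR = crossprod(pre$Xb, state$R),
       TLbR = crossprod(pre$lnull_b, state$R))
}

# evidence matrix: sum_i r_ih (E[log f_act(x_ij)] - log f_null(x_ij)), p x H
vb_evidence <- function(state, pre, cache) {
  H <- ncol(state$R)
  L <- matrix(0, pre$p, H)
  Nm1 <- matrix(state$N, pre$p1, H, byrow = TRUE)
  if (pre$p1) {
    ge <- gauss_expect(state)
    L[pre$nidx, ] <- Nm1 * ge$cn -
      0.5 * ge$dr * (cache$TXn2R - 2 * state$Mn * cache$TXnR +
                       Nm1 * state$Mn^2) - cache$TLnR
  }
  if (pre$p2) {
    be <- bern_expect(state)
    Nm2 <- matrix(state$N, pre$p2, H, byrow = TRUE)
    L[pre$bidx, ] <- be$psis * cache$TXbR +
      be$psit * (Nm2 - cache$TXbR) - cache$TLbR
  }
  L
}

vb_update_gamma <- function(state, pre, hyper, control, cache,
                            counter = NULL, eta_vec = pre$eta_vec) {
  L <- vb_evidence(state, pre, cache)
  cl <- control$logit_clamp
  H <- ncol(state$R)
  free <- setdiff(seq_len(pre$p), pre$coupled)
  if (length(free)) {
    Cf <- pmin(pmax(L[free, , drop = FALSE] - eta_vec[free], -cl), cl)
    state$C[free, ] <- Cf
    state$Q[free, ] <- stats::plogis(Cf)
  }
  if (length(pre$coupled)) {
    for (pass in seq_len(control$gamma_passes)) {
      delta <- 0
      for (j in pre$coupled) {
        nb <- pre$adj[[j]]
        fld <- colSums((2 * state$Q[nb[, 1L], , drop = FALSE] - 1) *
                         nb[, 2L])
        cj <- pmin(pmax(L[j, ] - eta_vec[j] + fld, -cl), cl)
        qj <- stats::plogis(cj)
        delta <- max(delta, max(abs(qj - state$Q[j, ])))
        state$C[j, ] <- cj
        state$Q[j, ] <- qj
        if (!is.null(counter))
          counter$ops <- counter$ops + 2 * nrow(nb) * H
      }
      if (delta < control$gamma_tol) break
    }
  }
  if (anyNA(state$C))
    stop("selection update produced NaN", call. = FALSE)
  state
}

vb_update_gauss <- function(state, pre, hyper, cache) {
  if (!pre$p1) return(state)
  Qn <- state$Q[pre$nidx, , drop = FALSE]
  Nm <- matrix(state$N, pre$p1, ncol(Qn), byrow = TRUE)
  W <- Qn * Nm
  state$Vn <- hyper$lambda + W
  state$Mn <- Qn * cache$TXnR / state$Vn
  state$Dn <- 2 * hyper$alpha_sigma + W
  Rn <- 2 * hyper$beta_sigma + Qn * cache$TXn2R - state$Vn * state$Mn^2
  floor_r <- 2 * hyper$beta_sigma * 1e-8
  if (any(Rn < floor_r)) {
    warning("inverse-gamma scale floored after floating-point cancellation",
            call. = FALSE)
    Rn <- pmax(Rn, floor_r)
  }
  state$Rn <- Rn
  state
}

vb_update_bern <- function(state, pre, hyper, cache) {
  if (!pre$p2) return(state)
  Qb <- state$Q[pre$bidx, , drop = FALSE]
  Nm <- matrix(state$N, pre$p2, ncol(Qb), byrow = TRUE)
  state$Sb <- hyper$alpha_p + Qb * cache$TXbR
  state$Tb <- hyper$beta_p + Qb * (Nm - cache$TXbR)
  state
}

# Evidence lower bound, up to the additive (q-independent) log partition
# function of the Ising prior.  Stick terms follow the truncated bookkeeping
# (sticks h < H only).
vb_elbo <- function(state, pre, hyper) {
  vb_elbo_scaled(state, pre, hyper, pre$eta_vec)
}

vb_elbo_scaled <- function(state, pre, hyper, eta_vec) {
  B <- vb_scores(state, pre)
  term1 <- sum(state$R * B)
  term2 <- -sum(xlogx(state$R))
  es <- expected_log_sticks(state$f, state$g)
  term3 <- sum(log(hyper$alpha0) + (hyper$alpha0 - 1) * es$El1w -
                 (state$f - 1) * es$Elw - (state$g - 1) * es$El1w +
                 lbeta(state$f, state$g))
  Q <- state$Q
  term4 <- -sum(eta_vec * Q) - sum(xlogx(Q)) - sum(xlogx(1 - Q))
  if (pre$e) {
    ab <- pre$edges$ab
    conc <- Q[ab[, 1L], , drop = FALSE] * Q[ab[, 2L], , drop = FALSE] +
      (1 - Q[ab[, 1L], , drop = FALSE]) * (1 - Q[ab[, 2L], , drop = FALSE])
    term4 <- term4 + sum(pre$edges$w * rowSums(conc))
  }
  term5 <- 0
  if (pre$p1) {
    ge <- gauss_expect(state)
    elogq <- 0.5 * log(state$Vn / (2 * pi)) - 0.5 * ge$elog_s2 - 0.5 +
      (state$Dn / 2) * log(state$Rn / 2) - lgamma(state$Dn / 2) -
      (state$Dn / 2 + 1) * ge$elog_s2 - state$Dn / 2
    elogp <- 0.5 * log(hyper$lambda / (2 * pi)) - 0.5 * ge$elog_s2 -
      0.5 * hyper$lambda * (state$Mn^2 * ge$dr + 1 / state$Vn) +
      hyper$alpha_sigma * log(hyper$beta_sigma) -
      lgamma(hyper$alpha_sigma) -
      (hyper$alpha_sigma + 1) * ge$elog_s2 - hyper$beta_sigma * ge$dr
    term5 <- -sum(elogq - elogp)
  }
  term6 <- 0
  if (pre$p2) {
    kl <- lbeta(hyper$alpha_p, hyper$beta_p) - lbeta(state$Sb, state$Tb) +
      (state$Sb - hyper$alpha_p) * digamma(state$Sb) +
      (state$Tb - hyper$beta_p) * digamma(state$Tb) +
      (hyper$alpha_p - state$Sb + hyper$beta_p - state$Tb) *
        digamma(state$Sb + state$Tb)
    term6 <- -sum(kl)
  }
  val <- term1 + term2 + term3 + term4 + term5 + term6
  if (!is.finite(val))
    stop("ELBO is not finite (blocks: ",
         paste(round(c(term1, term2, term3, term4, term5, term6), 3),
               collapse = ", "), ")", call. = FALSE)
  val
}

# Merge proposals: for each pair of occupied clusters that look redundant
# (overlapping selected-feature sets with close active parameters),
# tentatively pool the responsibilities of one into the other, refresh the
# dependent blocks and keep the merged state only if it improves the ELBO.
# Mean-field coordinate ascent cannot perform this collective move on its
# own (a small duplicate cluster holds a self-reinforcing overfitting
# advantage), and acceptance by ELBO comparison preserves the monotone-
# ascent guarantee.  Candidate screening keeps the move in its intended
# role -- repairing a fragmented partition -- rather than letting the
# optimiser chase the degenerate pooled optimum that the diffuse fixed
# null admits when clusters holding different populations are pooled.
vb_merge_candidate <- function(state, pre, a, b) {
  sa <- state$Q[, a] > 0.5; sb <- state$Q[, b] > 0.5
  uni <- sum(sa | sb)
  if (uni == 0L) return(TRUE)            # two all-null clusters
  if (sum(sa & sb) / uni < 0.5) return(FALSE)
  both <- which(sa & sb)
  jn <- match(intersect(both, pre$nidx), pre$nidx)
  if (length(jn)) {
    s2a <- state$Rn[jn, a] / pmax(state$Dn[jn, a] - 2, 1)
    s2b <- state$Rn[jn, b] / pmax(state$Dn[jn, b] - 2, 1)
    zd <- abs(state$Mn[jn, a] - state$Mn[jn, b]) /
      sqrt(pmax((s2a + s2b) / 2, 1e-12))
    if (max(zd) > 3) return(FALSE)
  }
  jb <- match(intersect(both, pre$bidx), pre$bidx)
  if (length(jb)) {
    pa <- state$Sb[jb, a] / (state$Sb[jb, a] + state$Tb[jb, a])
    pb <- state$Sb[jb, b] / (state$Sb[jb, b] + state$Tb[jb, b])
    if (max(abs(pa - pb)) > 0.4) return(FALSE)
  }
  TRUE
}

vb_try_merges <- function(state, pre, hyper, control, cache, elbo_cur,
                          counter = NULL, eta_vec = pre$eta_vec) {
  refresh_cols <- function(st, ca, cols) {
    # one coordinate pass of the selection block restricted to `cols`
    L <- vb_evidence(st, pre, ca)
    cl <- control$logit_clamp
    fld <- matrix(0, pre$p, length(cols))
    if (length(pre$coupled)) {
      S <- 2 * st$Q[, cols, drop = FALSE] - 1
      for (j in pre$coupled) {
        nb <- pre$adj[[j]]
        fld[j, ] <- colSums(S[nb[, 1L], , drop = FALSE] * nb[, 2L])
      }
    }
    Cc <- pmin(pmax(L[, cols, drop = FALSE] - eta_vec + fld, -cl), cl)
    st$C[, cols] <- Cc
    st$Q[, cols] <- stats::plogis(Cc)
    st
  }
  repeat {
    occ <- which(state$N >= 1)
    if (length(occ) < 2L) break
    improved <- FALSE
    pairs <- utils::combn(occ, 2L)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      if (!vb_merge_candidate(state, pre, a, b)) next
      st2 <- state; ca2 <- cache
      st2$R[, a] <- st2$R[, a] + st2$R[, b]
      st2$R[, b] <- 0
      st2$N <- colSums(st2$R)
      for (nm in names(ca2)) {
        if (ncol(ca2[[nm]])) {
          ca2[[nm]][, a] <- ca2[[nm]][, a] + ca2[[nm]][, b]
          ca2[[nm]][, b] <- 0
        }
      }
      st2 <- vb_update_sticks(st2, hyper)
      st2 <- refresh_cols(st2, ca2, c(a, b))
      st2 <- vb_update_gauss(st2, pre, hyper, ca2)
      st2 <- vb_update_bern(st2, pre, hyper, ca2)
      e2 <- vb_elbo_scaled(st2, pre, hyper, eta_vec)
      if (!is.null(counter))
        counter$ops <- counter$ops +
          (3 * pre$p1 + 2 * pre$p2) * pre$n * ncol(state$R)
      if (e2 > elbo_cur) {
        state <- st2; cache <- ca2; elbo_cur <- e2; improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(state = state, cache = cache, elbo = elbo_cur)
}

# ---------------------------------------------------------------------------

#' Fit the network-guided Dirichlet process mixture by variational Bayes
#'
#' Clusters subjects measured on multiple modalities with a truncated
#' stick-breaking Dirichlet process mixture while selecting, per cluster,
#' the features that define it.  Each feature's observations follow either a
#' cluster-specific active distribution (Normal with NIG base measure, or
#' Bernoulli with Beta base measure) or a fixed diffuse null (N(0, 20) /
#' Bern(0.5)); a multi-modal Ising prior over the supplied graphs couples
#' the selection indicators of connected features.  Inference maximises the
#' evidence lower bound by blockwise coordinate ascent in the fixed order
#' responsibilities, sticks, selection, Normal parameters, Bernoulli
#' parameters; per-sweep cost is O(npH + eH) with `e` graph edges.
#'
#' Clusters are re-indexed by decreasing expected size in every output.
#'
#' @param data A [mm_dataset()].
#' @param graphs A [graph_set()] over the dataset's features (default: no
#'   edges, i.e. independent selection).
#' @param hyper Hyperparameters, see [netdpm_hyper()].
#' @param control Optimisation settings, see [netdpm_control()].
#' @return An object of class `"netdpm"` with elements `labels` (named
#'   cluster assignments), `selection` (p x H matrix of selection
#'   probabilities), `params` (posterior-mean cluster parameters), `weights`
#'   (expected mixture weights), `cluster_sizes`, `occupied`, `elbo`
#'   (trace), `converged`, `iterations`, `ops` (per-iteration operation
#'   counts), and the final variational `state`.
#' @examples
#' sim <- simulate_multimodal(sim_design(n = 60, p = 40, seed = 7))
#' fit <- netdpm(sim$data,
#'               hyper = netdpm_hyper(eta = c(60, 5), H = 6),
#'               control = netdpm_control(seed = 7))
#' table(fit$labels, sim$truth$labels)
#' @export
netdpm <- function(data, graphs = NULL, hyper = netdpm_hyper(),
                   control = netdpm_control()) {
  stopifnot(inherits(data, "netdpm_data"), inherits(hyper, "netdpm_hyper"),
            inherits(control, "netdpm_control"))
  cl <- match.call()
  validate_dataset(data)
  scaling <- NULL
  if (control$standardize) {
    scaling <- lapply(data$modalities, function(m) {
      if (m$kind != "normal") return(NULL)
      s <- apply(m$X, 2L, stats::sd)
      s[s == 0 | !is.finite(s)] <- 1
      list(center = colMeans(m$X), scale = s)
    })
    data <- standardize_continuous(data)
  }
  if (is.null(graphs)) graphs <- empty_graphs(data)
  stopifnot(inherits(graphs, "netdpm_graphs"))
  pre <- vb_prepare(data, graphs, hyper)
  counter <- new.env(parent = emptyenv())
  counter$ops <- 0
  state <- vb_init(pre, hyper, control)
  H <- hyper$H; n <- pre$n; p <- pre$p
  # initialisation phase: bring sticks and cluster parameters in line with
  # the initial responsibilities, then run `anneal_sweeps` full sweeps with
  # the sparsity penalty ramped geometrically up to its target so that
  # signal features of not-yet-merged small clusters stay selected while
  # noise is already rejected.  These sweeps are part of initialisation and
  # precede the recorded coordinate ascent.
  cache <- vb_cache(state, pre)
  state <- vb_update_sticks(state, hyper)
  state <- vb_update_gauss(state, pre, hyper, cache)
  state <- vb_update_bern(state, pre, hyper, cache)
  A <- control$anneal_sweeps
  if (A > 0L) {
    for (t in seq_len(A)) {
      sc <- control$anneal_start ^ ((A - t + 1) / A)
      state <- vb_update_gamma(state, pre, hyper, control, cache, counter,
                               eta_vec = pre$eta_vec * sc)
      state <- vb_update_gauss(state, pre, hyper, cache)
      state <- vb_update_bern(state, pre, hyper, cache)
      state <- vb_update_z(state, pre)
      cache <- vb_cache(state, pre)
      state <- vb_update_sticks(state, hyper)
      if (control$merge_every > 0L) {
        mg <- vb_try_merges(state, pre, hyper, control, cache,
                            vb_elbo_scaled(state, pre, hyper,
                                           pre$eta_vec * sc),
                            counter, eta_vec = pre$eta_vec * sc)
        state <- mg$state; cache <- mg$cache
      }
    }
  } else {
    state <- vb_update_gamma(state, pre, hyper, control, cache, counter)
  }
  elbo <- numeric(0)
  converged <- FALSE
  ops0 <- counter$ops
  iters <- 0L
  for (it in seq_len(control$max_iter)) {
    state <- vb_update_z(state, pre)
    cache <- vb_cache(state, pre)
    state <- vb_update_sticks(state, hyper)
    state <- vb_update_gamma(state, pre, hyper, control, cache, counter)
    state <- vb_update_gauss(state, pre, hyper, cache)
    state <- vb_update_bern(state, pre, hyper, cache)
    counter$ops <- counter$ops +
      (3 * pre$p1 + 2 * pre$p2) * n * H +   # responsibility scores
      (3 * pre$p1 + 2 * pre$p2) * n * H +   # sufficient statistics
      n * H +                               # sticks
      4 * p * H +                           # selection logits
      (6 * pre$p1 + 4 * pre$p2) * H         # conjugate parameter blocks
    elbo <- c(elbo, vb_elbo(state, pre, hyper))
    counter$ops <- counter$ops + (3 * pre$p1 + 2 * pre$p2) * n * H +
      2 * pre$e * H
    if (control$merge_every > 0L && it %% control$merge_every == 0L) {
      mg <- vb_try_merges(state, pre, hyper, control, cache,
                          elbo[it], counter)
      state <- mg$state; cache <- mg$cache; elbo[it] <- mg$elbo
    }
    iters <- it
    if (it > 1L) {
      d <- elbo[it] - elbo[it - 1L]
      if (abs(d) <= control$rel_tol * (abs(elbo[it - 1L]) + 1e-12)) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning("variational fit did not converge in ", control$max_iter,
            " sweeps", call. = FALSE)
  # re-index clusters by decreasing expected size
  perm <- order(state$N, decreasing = TRUE)
  Rp <- state$R[, perm, drop = FALSE]
  Np <- state$N[perm]
  labels <- max.col(Rp, ties.method = "first")
  names(labels) <- data$sample_ids
  ew <- state$f / (state$f + state$g)
  weights <- stick_weights(c(ew, 1))[perm]
  elogwp <- elog_stick_weights(state$f, state$g)[perm]
  sel <- state$Q[, perm, drop = FALSE]
  dimnames(sel) <- list(data$registry, paste0("cluster", seq_len(H)))
  sigma2 <- ifelse(state$Dn > 2, state$Rn / (state$Dn - 2),
                   state$Rn / state$Dn)
  prob <- state$Sb / (state$Sb + state$Tb)
  prob <- pmin(pmax(prob, 1e-6), 1 - 1e-6)
  params <- list(
    mean = structure(state$Mn[, perm, drop = FALSE],
                     dimnames = list(data$registry[pre$nidx], NULL)),
    var = structure(sigma2[, perm, drop = FALSE],
                    dimnames = list(data$registry[pre$nidx], NULL)),
    prob = structure(prob[, perm, drop = FALSE],
                     dimnames = list(data$registry[pre$bidx], NULL)))
  structure(
    list(labels = labels, cluster_sizes = Np,
         occupied = sum(Np >= 1), weights = weights, selection = sel,
         params = params, elbo = elbo, converged = converged,
         iterations = iters, elogwp = elogwp,
         ops = list(total = counter$ops, warmup = ops0,
                    per_iter = (counter$ops - ops0) / max(iters, 1L)),
         state = c(state, list(perm = perm)),
         data_info = list(registry = data$registry,
                          kinds = feature_kinds(data),
                          modalities = vapply(data$modalities,
                                              function(m) m$name, ""),
                          p_m = vapply(data$modalities,
                                       function(m) ncol(m$X), 0L),
                          nidx = pre$nidx, bidx = pre$bidx,
                          null = data$null, scaling = scaling),
         hyper = hyper, control = control, call = cl),
    class = "netdpm")
}
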