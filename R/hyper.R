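#' Model hyperparameters
#'
#' Collects the Dirichlet-process concentration, the base-measure constants
#' and the Ising prior hyperparameters.
#'
#' @param alpha0 DP concentration (> 0).  Larger values spread prior mass
#'   over more clusters.
#' @param eta Nonnegative Ising sparsity penalty, one value per modality
#'   (recycled).  `eta` is in log-odds units: a useful calibration is to set
#'   it above the total per-cluster log-likelihood advantage a pure noise
#'   feature gains from being fitted (roughly cluster size times the KL
#'   divergence between the noise and null distributions) but below the
#'   weakest signal feature's total evidence.
#' @param nu Nonnegative within-modality smoothness reward per graph edge,
#'   one value per modality (recycled).
#' @param nu_cross Nonnegative cross-modality smoothness reward.
#' @param lambda Prior precision scale of the Normal-Inverse-Gamma base
#'   measure NIG(0, lambda, alpha_sigma, beta_sigma) for active Normal
#'   features.  Kept small by default: the base measure is centred at 0,
#'   and a large `lambda` would shrink active cluster means toward 0 and
#'   inflate the fitted residual variance by roughly
#'   `mean^2 * lambda * W / (lambda + W)` for a cluster with effective
#'   size `W`, eroding the very evidence that separates active features
#'   from the null.
#' @param alpha_sigma,beta_sigma Inverse-Gamma shape/scale of the NIG base
#'   measure (> 0).  The defaults put the prior mean residual variance at
#'   `beta_sigma / (alpha_sigma - 1) = 0.1`, appropriate for standardized
#'   data where cluster-defining features have sub-unit spread.
#' @param alpha_p,beta_p Beta base measure for active Bernoulli features.
#' @param H Truncation level of the stick-breaking variational family
#'   (>= 2).  Choose conservatively larger than the plausible cluster
#'   number; superfluous clusters empty out.
#' @return An object of class `"netdpm_hyper"`.
#' @export
netdpm_hyper <- function(alpha0 = 1, eta = 10, nu = 1, nu_cross = 1,
                         lambda = 0.01, alpha_sigma = 2, beta_sigma = 0.1,
                         alpha_p = 1, beta_p = 1, H = 30L) {
  stopifnot(alpha0 > 0, lambda > 0, alpha_sigma > 0, beta_sigma > 0,
            alpha_p > 0, beta_p > 0)
  if (any(eta < 0) || any(nu < 0) || any(nu_cross < 0))
    stop("`eta`, `nu`, `nu_cross` must be nonnegative", call. = FALSE)
  H <- as.integer(H)
  if (H < 2L) stop("truncation level `H` must be at least 2", call. = FALSE)
  structure(list(alpha0 = alpha0, eta = eta, nu = nu, nu_cross = nu_cross,
                 lambda = lambda, alpha_sigma = alpha_sigma,
                 beta_sigma = beta_sigma, alpha_p = alpha_p,
                 beta_p = beta_p, H = H),
            class = "netdpm_hyper")
}

#' Fitting control parameters
#'
#' @param max_iter Maximum number of full coordinate-ascent sweeps.
#' @param rel_tol Relative ELBO change declaring convergence.
#' @param seed Integer seed controlling initialisation (and nothing else:
#'   the updates are deterministic).
#' @param init `"kmeans"` (k-means on standardized concatenated features) or
#'   `"random"` responsibilities.
#' @param logit_clamp Selection logits are clamped to `[-logit_clamp,
#'   logit_clamp]` to keep the mean field numerically stable.
#' @param standardize If `TRUE`, continuous modalities are column-
#'   standardized before fitting (the diffuse null N(0, 20) presumes roughly
#'   standardized data).  Default `FALSE`: the data are used as given.
#' @param gamma_passes Inner fixed-point passes of the coupled selection
#'   block per sweep.
#' @param gamma_tol Early-exit threshold on the maximum selection-
#'   probability change within the inner passes.
#' @param anneal_sweeps Number of initialisation sweeps during which the
#'   sparsity penalty `eta` is ramped geometrically from
#'   `anneal_start * eta` up to `eta`.  Because the selection evidence of a
#'   feature scales with cluster size, a full-strength penalty applied
#'   while the initial partition still contains many small fragments can
#'   push every indicator to the null, an absorbing state of the
#'   coordinate ascent; the ramped phase lets fragments of the same group
#'   merge first.  These sweeps are part of initialisation and are not part
#'   of the recorded ELBO trace, which starts once `eta` is at its target.
#' @param anneal_start Starting fraction of `eta` for the ramp, in (0, 1].
#' @param merge_every Propose cluster merges (accepted only when they
#'   increase the ELBO) every this many sweeps; 0 disables merge moves.
#'   Coordinate ascent alone cannot pool a duplicated cluster into its
#'   twin, so merge proposals are part of the standard optimisation
#'   repertoire for truncated stick-breaking families.
#' @return An object of class `"netdpm_control"`.
#' @export
netdpm_control <- function(max_iter = 500L, rel_tol = 1e-6, seed = 1L,
                           init = c("kmeans", "random"), logit_clamp = 30,
                           standardize = FALSE, gamma_passes = 3L,
                           gamma_tol = 1e-6, anneal_sweeps = 10L,
                           anneal_start = 0.2, merge_every = 1L) {
  stopifnot(max_iter >= 1L, rel_tol > 0, logit_clamp > 0, gamma_passes >= 1L,
            anneal_sweeps >= 0L, anneal_start > 0, anneal_start <= 1)
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 seed = as.integer(seed), init = match.arg(init),
                 logit_clamp = logit_clamp, standardize = standardize,
                 gamma_passes = as.integer(gamma_passes),
                 gamma_tol = gamma_tol,
                 anneal_sweeps = as.integer(anneal_sweeps),
                 anneal_start = anneal_start,
                 merge_every = as.integer(merge_every)),
            class = "netdpm_control")
}
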