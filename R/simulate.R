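#' Simulation design with planted clusters and signal features
#'
#' Describes a two-modality benchmark: subjects fall into `K` groups; a
#' fraction `signal_frac` of the features in each modality are signal
#' features whose distribution depends on the group (Normal with
#' group-specific means, or Bernoulli with group-specific probabilities),
#' while the remaining features are noise (standard Normal, or Bernoulli
#' with a fixed probability).
#'
#' @param n Number of subjects.
#' @param p Total number of features across modalities.
#' @param modality_split Fraction of `p` per modality (default an even
#'   continuous/binary split).
#' @param modality_kinds Kind of each modality.
#' @param signal_frac Fraction of features that are signal (default 0.10).
#' @param K Number of planted groups.
#' @param normal_means Group means of continuous signal features (length
#'   `K`).
#' @param normal_sd Standard deviation of continuous signal features.
#' @param bern_probs Group success probabilities of binary signal features
#'   (length `K`).
#' @param noise_bern_prob Success probability of binary noise features.
#' @param pair_signals If `TRUE`, the same column positions are signal in
#'   every modality (needed for meaningful cross-modality edges).
#' @param seed Integer seed.
#' @return An object of class `"sim_design"`.
#' @export
sim_design <- function(n = 300L, p = 200L, modality_split = c(0.5, 0.5),
                       modality_kinds = c("normal", "bernoulli"),
                       signal_frac = 0.10, K = 3L,
                       normal_means = c(-2, 2, 6), normal_sd = 0.1,
                       bern_probs = c(0.2, 0.5, 0.8),
                       noise_bern_prob = 0.5, pair_signals = FALSE,
                       seed = 1L) {
  K <- as.integer(K)
  stopifnot(n >= 1L, p >= length(modality_split), K >= 1L,
            signal_frac > 0, signal_frac <= 1, normal_sd > 0,
            length(modality_split) == length(modality_kinds),
            all(modality_kinds %in% MODALITY_KINDS),
            abs(sum(modality_split) - 1) < 1e-8)
  if (length(normal_means) != K || length(bern_probs) != K)
    stop("`normal_means` and `bern_probs` must have one entry per group",
         call. = FALSE)
  if (any(bern_probs <= 0 | bern_probs >= 1) ||
      noise_bern_prob <= 0 || noise_bern_prob >= 1)
    stop("Bernoulli probabilities must lie strictly inside (0, 1)",
         call. = FALSE)
  structure(list(n = as.integer(n), p = as.integer(p),
                 modality_split = modality_split,
                 modality_kinds = modality_kinds,
                 signal_frac = signal_frac, K = K,
                 normal_means = normal_means, normal_sd = normal_sd,
                 bern_probs = bern_probs, noise_bern_prob = noise_bern_prob,
                 pair_signals = isTRUE(pair_signals),
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate a multi-modal dataset with planted structure
#'
#' Group labels are drawn uniformly over the `K` groups; signal feature
#' positions are sampled per modality (or shared across modalities when
#' `pair_signals`); signal observations follow the group-specific
#' distributions and noise observations the noise models of the design.
#'
#' @param design A [sim_design()].
#' @param truth Optionally, the `truth` element of a previous simulation:
#'   its signal column positions are reused so the new subjects follow the
#'   same planted feature structure (e.g. holdout subjects for
#'   classification).  Group labels are still drawn fresh under `design`.
#' @return An object of class `"netdpm_sim"`: `data` (an [mm_dataset()])
#'   and `truth` (planted `labels`, `signal_features` as registry ids,
#'   per-modality signal column indices and the echoed design).
#' @export
simulate_multimodal <- function(design = sim_design(), truth = NULL) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  n <- design$n; K <- design$K
  M <- length(design$modality_split)
  p_m <- round(design$modality_split * design$p)
  p_m[M] <- design$p - sum(p_m[-M])
  if (any(p_m < 1L)) stop("empty modality in design", call. = FALSE)
  labels <- sample.int(K, n, replace = TRUE)
  sample_ids <- sprintf("s%03d", seq_len(n))
  mats <- vector("list", M)
  signal_cols <- vector("list", M)
  modnames <- ifelse(design$modality_kinds == "normal", "expr", "alt")
  if (anyDuplicated(modnames))
    modnames <- paste0(modnames, seq_len(M))
  for (m in seq_len(M)) {
    pm <- p_m[m]
    ns <- round(design$signal_frac * pm)
    sig <- if (!is.null(truth)) {
      truth$signal_cols[[m]]
    } else if (design$pair_signals && m > 1L) {
      intersect(signal_cols[[1L]], seq_len(pm))
    } else sort(sample.int(pm, ns))
    kind <- design$modality_kinds[m]
    X <- if (kind == "normal") {
      matrix(stats::rnorm(n * pm), n, pm)
    } else {
      matrix(stats::rbinom(n * pm, 1L, design$noise_bern_prob), n, pm)
    }
    if (length(sig)) {
      if (kind == "normal") {
        X[, sig] <- matrix(stats::rnorm(n * length(sig),
                                        mean = design$normal_means[labels],
                                        sd = design$normal_sd),
                           n, length(sig))
      } else {
        X[, sig] <- matrix(stats::rbinom(n * length(sig), 1L,
                                         design$bern_probs[labels]),
                           n, length(sig))
      }
    }
    dimnames(X) <- list(sample_ids,
                        sprintf("%s_%04d", modnames[m], seq_len(pm)))
    mats[[m]] <- X
    signal_cols[[m]] <- sig
  }
  names(mats) <- modnames
  data <- mm_dataset(mats, kinds = design$modality_kinds)
  signal_registry <- unlist(lapply(seq_len(M), function(m)
    paste(modnames[m], colnames(mats[[m]])[signal_cols[[m]]], sep = ":")),
    use.names = FALSE)
  structure(list(
    data = data,
    truth = list(labels = stats::setNames(labels, sample_ids),
                 signal_features = signal_registry,
                 signal_cols = stats::setNames(signal_cols, modnames),
                 design = design)),
    class = "netdpm_sim")
}

#' @export
print.netdpm_sim <- function(x, ...) {
  cat("Simulated dataset:", x$truth$design$n, "subjects,",
      x$truth$design$K, "planted groups,",
      length(x$truth$signal_features), "signal features\n")
  invisible(x)
}

#' Simulate graphs over a planted simulation
#'
#' Draws within-modality edges among signal features with probability
#' `within_density` per pair and among noise features with probability
#' `decoy_density` (decoy edges connect noise features only; signal and
#' noise features are never linked), plus `cross_pairs` random
#' signal-signal edges between the first two modalities.
#'
#' @param sim A `"netdpm_sim"` object.
#' @param within_density Edge probability among signal features, per
#'   modality pair of signal features.
#' @param cross_pairs Number of random signal-signal cross-modality edges.
#' @param decoy_density Edge probability among noise features.
#' @param seed Integer seed.
#' @return A [graph_set()] over the simulated features.
#' @export
simulate_graphset <- function(sim, within_density = 0.3, cross_pairs = 0L,
                              decoy_density = 0, seed = 1L) {
  stopifnot(inherits(sim, "netdpm_sim"))
  if (within_density < 0 || within_density > 1 ||
      decoy_density < 0 || decoy_density > 1)
    stop("densities must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  data <- sim$data
  modnames <- vapply(data$modalities, function(m) m$name, "")
  within <- list()
  random_pairs <- function(ids, density) {
    if (length(ids) < 2L || density == 0) return(NULL)
    pairs <- t(utils::combn(ids, 2L))
    pairs[stats::runif(nrow(pairs)) < density, , drop = FALSE]
  }
  for (m in seq_along(modnames)) {
    feats <- colnames(data$modalities[[m]]$X)
    sig <- feats[sim$truth$signal_cols[[m]]]
    noi <- setdiff(feats, sig)
    ed <- rbind(random_pairs(sig, within_density),
                random_pairs(noi, decoy_density))
    if (!is.null(ed) && nrow(ed)) within[[modnames[m]]] <- ed
  }
  cross <- list()
  if (cross_pairs > 0L && length(modnames) >= 2L) {
    s1 <- colnames(data$modalities[[1L]]$X)[sim$truth$signal_cols[[1L]]]
    s2 <- colnames(data$modalities[[2L]]$X)[sim$truth$signal_cols[[2L]]]
    if (length(s1) && length(s2)) {
      cross[[paste(modnames[1L], modnames[2L], sep = ":")]] <-
        cbind(sample(s1, cross_pairs, replace = TRUE),
              sample(s2, cross_pairs, replace = TRUE))
    }
  }
  graph_set(data, within = within, cross = cross)
}

#' Simulate truth-linked scoring covariates
#'
#' Produces a continuous covariate equal to the planted group index plus
#' `N(0, 1/snr)` noise and a binary covariate drawn with group-dependent
#' probabilities, for exercising the grid-search scoring end to end.
#'
#' @param sim A `"netdpm_sim"` object.
#' @param snr Positive signal-to-noise factor; the continuous covariate's
#'   noise standard deviation is `1/snr`.
#' @param bin_probs Per-group probabilities of the binary covariate.
#' @param seed Integer seed.
#' @return A data frame with `sample_id`, `index` (continuous) and
#'   `alteration` (binary).
#' @export
simulate_covariates <- function(sim, snr = 10, bin_probs = NULL,
                                seed = 1L) {
  stopifnot(inherits(sim, "netdpm_sim"), snr > 0)
  set.seed(seed)
  labels <- sim$truth$labels
  K <- sim$truth$design$K
  if (is.null(bin_probs))
    bin_probs <- seq(0.2, 0.8, length.out = K)
  data.frame(
    sample_id = names(labels),
    index = as.numeric(labels) + stats::rnorm(length(labels), 0, 1 / snr),
    alteration = stats::rbinom(length(labels), 1L, bin_probs[labels]))
}
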