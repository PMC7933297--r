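#' Fixed null-distribution parameters
#'
#' The null (cluster-inactive) component is shared by every cluster and is
#' never updated during inference: continuous features fall back to a diffuse
#' N(`mu0`, `sigma0_sq`) and binary features to Bern(`p0`).  The diffuse
#' variance presumes roughly standardized continuous data.
#'
#' @param mu0 Null mean for continuous features.
#' @param sigma0_sq Null variance for continuous features (> 0).
#' @param p0 Null success probability for binary features (in (0,1)).
#' @return An object of class `"netdpm_null"`.
#' @export
null_params <- function(mu0 = 0, sigma0_sq = 20, p0 = 0.5) {
  stopifnot(is.numeric(mu0), length(mu0) == 1L, is.finite(mu0))
  if (!is.numeric(sigma0_sq) || sigma0_sq <= 0)
    stop("`sigma0_sq` must be a positive number", call. = FALSE)
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1)
    stop("`p0` must lie strictly inside (0, 1)", call. = FALSE)
  structure(list(mu0 = mu0, sigma0_sq = sigma0_sq, p0 = p0),
            class = "netdpm_null")
}

MODALITY_KINDS <- c("normal", "bernoulli")

#' Assemble a multi-modal dataset
#'
#' Bundles one matrix per modality (samples in rows, features in columns)
#' together with the likelihood family of each modality.  All modalities must
#' share the same samples in the same order; binary modalities may contain
#' only 0/1 values and no entry may be missing.
#'
#' @param x Named list of numeric matrices, samples x features, with row and
#'   column names.  Row names are the sample ids.
#' @param kinds Character vector, one of `"normal"` or `"bernoulli"` per
#'   modality (recycled if length 1).
#' @param null Null-distribution parameters, see [null_params()].
#' @return An object of class `"netdpm_data"`: a list with elements
#'   `modalities` (each with `name`, `kind`, `X`), `sample_ids`, `n`, `p`,
#'   `registry` (global `"modality:feature"` ids) and `null`.
#' @seealso [validate_dataset()], [align_modalities()]
#' @export
mm_dataset <- function(x, kinds, null = null_params()) {
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x) || length(x) == 0L)
    stop("`x` must be a non-empty list of matrices", call. = FALSE)
  if (is.null(names(x)) || any(names(x) == ""))
    names(x) <- paste0("mod", seq_along(x))
  kinds <- rep_len(as.character(kinds), length(x))
  if (!all(kinds %in% MODALITY_KINDS))
    stop("modality kinds must be 'normal' or 'bernoulli'", call. = FALSE)
  mods <- vector("list", length(x))
  for (m in seq_along(x)) {
    X <- x[[m]]
    if (!is.matrix(X)) X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (is.null(rownames(X)))
      rownames(X) <- paste0("s", seq_len(nrow(X)))
    if (is.null(colnames(X)))
      colnames(X) <- paste0("f", seq_len(ncol(X)))
    mods[[m]] <- list(name = names(x)[m], kind = kinds[m], X = X)
  }
  names(mods) <- names(x)
  obj <- structure(
    list(modalities = mods,
         sample_ids = rownames(mods[[1L]]$X),
         n = nrow(mods[[1L]]$X),
         p = sum(vapply(mods, function(m) ncol(m$X), 0L)),
         registry = unlist(lapply(mods, function(m)
           paste(m$name, colnames(m$X), sep = ":")), use.names = FALSE),
         null = null),
    class = "netdpm_data")
  validate_dataset(obj)
  obj
}

#' Validate a multi-modal dataset
#'
#' Checks sample alignment across modalities, missing values, non-binary
#' entries in Bernoulli modalities and duplicated feature ids.  Fatal
#' violations raise an error naming the offending feature/sample; otherwise a
#' summary report is returned invisibly.
#'
#' @param data A `"netdpm_data"` object (or the bare list that will become
#'   one during construction).
#' @return Invisibly, a list with `n`, `p`, per-modality dimensions and an
#'   empty `violations` list.
#' @export
validate_dataset <- function(data) {
  mods <- data$modalities
  ids <- rownames(mods[[1L]]$X)
  if (anyDuplicated(ids))
    stop("duplicated sample ids: ", ids[duplicated(ids)][1L], call. = FALSE)
  for (m in mods) {
    if (nrow(m$X) != length(ids))
      stop("modality '", m$name, "' has ", nrow(m$X),
           " samples; expected ", length(ids), call. = FALSE)
    if (!identical(rownames(m$X), ids))
      stop("sample ids of modality '", m$name,
           "' do not match the first modality (same samples, same order, ",
           "are required); use align_modalities() to join inputs",
           call. = FALSE)
    if (anyDuplicated(colnames(m$X)))
      stop("duplicated feature id in modality '", m$name, "': ",
           colnames(m$X)[duplicated(colnames(m$X))][1L], call. = FALSE)
    bad <- which(!is.finite(m$X))
    if (length(bad)) {
      i <- ((bad[1L] - 1L) %% nrow(m$X)) + 1L
      j <- ((bad[1L] - 1L) %/% nrow(m$X)) + 1L
      stop("missing/non-finite value in modality '", m$name, "', feature '",
           colnames(m$X)[j], "', sample '", rownames(m$X)[i],
           "' (missing data are not supported)", call. = FALSE)
    }
    if (m$kind == "bernoulli") {
      bad <- which(!(m$X == 0 | m$X == 1))
      if (length(bad)) {
        i <- ((bad[1L] - 1L) %% nrow(m$X)) + 1L
        j <- ((bad[1L] - 1L) %/% nrow(m$X)) + 1L
        stop("non-binary value ", m$X[bad[1L]], " in bernoulli modality '",
             m$name, "', feature '", colnames(m$X)[j], "', sample '",
             rownames(m$X)[i], "'", call. = FALSE)
      }
    }
  }
  invisible(list(
    n = length(ids),
    p = sum(vapply(mods, function(m) ncol(m$X), 0L)),
    p_m = vapply(mods, function(m) ncol(m$X), 0L),
    kinds = vapply(mods, function(m) m$kind, ""),
    violations = list()))
}

#' @export
print.netdpm_data <- function(x, ...) {
  cat("Multi-modal dataset:", x$n, "samples,", x$p, "features in",
      length(x$modalities), "modalities\n")
  for (m in x$modalities)
    cat(sprintf("  %s (%s): %d features\n", m$name, m$kind, ncol(m$X)))
  invisible(x)
}

# kind of every feature in registry order
feature_kinds <- function(data) {
  unlist(lapply(data$modalities,
                function(m) rep(m$kind, ncol(m$X))), use.names = FALSE)
}

# modality index of every feature in registry order
feature_modality <- function(data) {
  rep(seq_along(data$modalities),
      vapply(data$modalities, function(m) ncol(m$X), 0L))
}

#' Log-density of the active (cluster-specific) component
#'
#' Normal features use `log N(x; mean, var)`; Bernoulli features use
#' `x log(prob) + (1 - x) log(1 - prob)`.  Vectorised over `x` and the
#' parameters.
#'
#' @param x Observations (0/1 for `kind = "bernoulli"`).
#' @param kind `"normal"` or `"bernoulli"`.
#' @param mean,var Normal parameters (`var` > 0).
#' @param prob Bernoulli success probability in (0,1).
#' @return Log-density values.
#' @export
ldens_active <- function(x, kind, mean = NULL, var = NULL, prob = NULL) {
  kind <- match.arg(kind, MODALITY_KINDS)
  if (kind == "normal") {
    if (is.null(mean) || is.null(var))
      stop("normal kind requires `mean` and `var`", call. = FALSE)
    if (any(var <= 0)) stop("variance must be positive", call. = FALSE)
    stats::dnorm(x, mean = mean, sd = sqrt(var), log = TRUE)
  } else {
    if (is.null(prob)) stop("bernoulli kind requires `prob`", call. = FALSE)
    if (any(prob <= 0 | prob >= 1))
      stop("prob must lie strictly inside (0, 1)", call. = FALSE)
    if (any(!(x == 0 | x == 1)))
      stop("bernoulli observations must be 0 or 1", call. = FALSE)
    x * log(prob) + (1 - x) * log1p(-prob)
  }
}

#' Log-density of the shared null component
#'
#' Evaluates [ldens_active()] at the fixed null parameters (diffuse Normal
#' for continuous features, Bern(0.5) for binary ones).
#'
#' @inheritParams ldens_active
#' @param null See [null_params()].
#' @return Log-density values.
#' @export
ldens_null <- function(x, kind, null = null_params()) {
  kind <- match.arg(kind, MODALITY_KINDS)
  if (kind == "normal")
    ldens_active(x, "normal", mean = null$mu0, var = null$sigma0_sq)
  else
    ldens_active(x, "bernoulli", prob = null$p0)
}

#' Log-likelihood of one subject under one cluster
#'
#' Per feature, the selection indicator `gamma` picks the cluster-specific
#' active density or the shared null density; contributions add in log across
#' features and modalities.
#'
#' @param x Numeric vector, one subject's observations over all `p` features
#'   in registry order.
#' @param kind Character vector of per-feature kinds (length `p`).
#' @param gamma Binary selection vector (length `p`).
#' @param mean,var,prob Per-feature active parameters (entries for the other
#'   family are ignored; may be `NA` there).
#' @param null See [null_params()].
#' @return A single finite log-likelihood value.
#' @export
subject_cluster_loglik <- function(x, kind, gamma, mean = NULL, var = NULL,
                                   prob = NULL, null = null_params()) {
  p <- length(x)
  if (length(kind) != p || length(gamma) != p)
    stop("`x`, `kind` and `gamma` must have equal length", call. = FALSE)
  out <- 0
  for (j in seq_len(p)) {
    lj <- if (gamma[j] > 0) {
      if (kind[j] == "normal")
        ldens_active(x[j], "normal", mean = mean[j], var = var[j])
      else
        ldens_active(x[j], "bernoulli", prob = prob[j])
    } else {
      ldens_null(x[j], kind[j], null = null)
    }
    out <- out + lj
  }
  out
}

# column-standardize the continuous modalities of a dataset (in place copy)
standardize_continuous <- function(data) {
  for (m in seq_along(data$modalities)) {
    if (data$modalities[[m]]$kind == "normal") {
      X <- data$modalities[[m]]$X
      mu <- colMeans(X)
      sd <- apply(X, 2L, stats::sd)
      sd[sd == 0 | !is.finite(sd)] <- 1
      data$modalities[[m]]$X <- sweep(sweep(X, 2L, mu), 2L, sd, "/")
    }
  }
  data
}
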