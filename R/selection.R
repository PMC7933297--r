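#' One-way ANOVA F statistic of a covariate across clusters
#'
#' Scores how strongly a continuous covariate differs across a partition.
#' Degenerate cases are flagged rather than erroring so that downstream
#' Fisher combination always has a defined p-value: a single group (no
#' between-cluster contrast) is scored p = 1, and perfect separation with
#' zero within-group variance is scored p = 0.
#'
#' @param values Numeric covariate, one value per sample.
#' @param labels Cluster labels (any atomic type), same length.
#' @return A list with `statistic`, `p.value`, `df` and `degenerate`
#'   (`NA`, `"single_group"` or `"zero_within_variance"`).
#' @export
anova_f <- function(values, labels) {
  if (length(values) != length(labels))
    stop("`values` and `labels` must have equal length", call. = FALSE)
  labels <- factor(labels)
  K <- nlevels(labels)
  n <- length(values)
  if (K < 2L || n - K < 1L)
    return(list(statistic = NA_real_, p.value = 1, df = c(NA, NA),
                degenerate = "single_group"))
  gm <- mean(values)
  means <- tapply(values, labels, mean)
  sizes <- tabulate(labels)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((values - means[labels])^2)
  df1 <- K - 1L; df2 <- n - K
  if (ssw <= .Machine$double.eps * sum(values^2)) {
    if (ssb > 0)
      return(list(statistic = Inf, p.value = 0, df = c(df1, df2),
                  degenerate = "zero_within_variance"))
    return(list(statistic = 0, p.value = 1, df = c(df1, df2),
                degenerate = "zero_within_variance"))
  }
  Fst <- (ssb / df1) / (ssw / df2)
  list(statistic = Fst,
       p.value = stats::pf(Fst, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), degenerate = NA_character_)
}

#' Pearson chi-square statistic of a binary covariate across clusters
#'
#' Builds the 2 x K contingency table of a 0/1 indicator against cluster
#' labels and applies Pearson's test without continuity correction.  Empty
#' margins (indicator constant, or a single cluster) are flagged degenerate
#' with p = 1.
#'
#' @param binary 0/1 indicator per sample.
#' @param labels Cluster labels, same length.
#' @return A list with `statistic`, `p.value`, `df` and `degenerate`.
#' @export
chisq_stat <- function(binary, labels) {
  if (length(binary) != length(labels))
    stop("`binary` and `labels` must have equal length", call. = FALSE)
  if (any(!(binary == 0 | binary == 1)))
    stop("`binary` must contain only 0/1", call. = FALSE)
  tab <- table(factor(binary, levels = c(0, 1)), factor(labels))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  K <- ncol(tab)
  if (K < 2L || any(rowSums(tab) == 0))
    return(list(statistic = NA_real_, p.value = 1, df = NA_integer_,
                degenerate = "empty_margin"))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  deg <- if (any(ht$expected == 0)) "zero_expected" else NA_character_
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value),
       df = unname(ht$parameter), degenerate = deg)
}

#' Fisher's method for combining p-values
#'
#' `X = -2 sum log(p_i)` is referred to the upper tail of a chi-square
#' distribution with `2k` degrees of freedom.  Zero p-values are clamped to
#' the smallest positive double with a warning.
#'
#' @param pvals Vector of p-values in (0, 1].
#' @return A list with `statistic`, `df` and `p.value`.
#' @export
fisher_combine <- function(pvals) {
  if (length(pvals) < 1L) stop("need at least one p-value", call. = FALSE)
  if (any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(pvals == 0)) {
    warning("zero p-value clamped for Fisher combination", call. = FALSE)
    pvals <- pmax(pvals, .Machine$double.xmin)
  }
  X <- -2 * sum(log(pvals))
  k <- length(pvals)
  list(statistic = X, df = 2L * k,
       p.value = stats::pchisq(X, df = 2 * k, lower.tail = FALSE))
}

#' Rand index and adjusted Rand index between two partitions
#'
#' The classic Rand index is the fraction of sample pairs on which two
#' partitions agree (co-clustered in both or separated in both); the
#' adjusted version corrects for chance agreement.
#'
#' @param labels_a,labels_b Two label vectors of equal length.
#' @return A list with `rand` and `adjusted`.
#' @export
rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("partitions must have equal length", call. = FALSE)
  n <- length(labels_a)
  if (n < 2L) return(list(rand = 1, adjusted = 1))
  tab <- table(labels_a, labels_b)
  nij2 <- sum(choose(tab, 2))
  a2 <- sum(choose(rowSums(tab), 2))
  b2 <- sum(choose(colSums(tab), 2))
  n2 <- choose(n, 2)
  rand <- (n2 + 2 * nij2 - a2 - b2) / n2
  exp_idx <- a2 * b2 / n2
  max_idx <- (a2 + b2) / 2
  adj <- if (max_idx == exp_idx) 1 else (nij2 - exp_idx) / (max_idx - exp_idx)
  list(rand = rand, adjusted = adj)
}

#' Score a partition against biological covariates
#'
#' Applies [anova_f()] to each continuous covariate and [chisq_stat()] to
#' each binary one, then combines all p-values with [fisher_combine()].
#'
#' @param labels Cluster labels per sample.
#' @param covariates Data frame of scoring covariates (rows aligned with
#'   `labels`; a `sample_id` column, if present, is ignored for scoring).
#' @param binary Character vector naming the 0/1 columns (others are treated
#'   as continuous).
#' @return A list with the per-covariate `tests` data frame and the
#'   `fisher` combination.
#' @export
score_partition <- function(labels, covariates, binary = character()) {
  covariates <- as.data.frame(covariates)
  cols <- setdiff(names(covariates), "sample_id")
  if (!length(cols)) stop("no scoring covariates supplied", call. = FALSE)
  rows <- lapply(cols, function(cn) {
    v <- covariates[[cn]]
    r <- if (cn %in% binary) chisq_stat(v, labels) else anova_f(v, labels)
    data.frame(covariate = cn,
               type = if (cn %in% binary) "chisq" else "anova_f",
               statistic = r$statistic, p.value = r$p.value,
               degenerate = r$degenerate)
  })
  tests <- do.call(rbind, rows)
  list(tests = tests, fisher = fisher_combine(tests$p.value))
}

#' Hyperparameter grid search scored by covariate separation
#'
#' Fits the model at every grid point (all fits use the same seed and
#' control settings), scores each solution by how strongly the supplied
#' covariates differ across its clusters (ANOVA F / chi-square p-values
#' combined by Fisher's method) and ranks solutions by ascending combined
#' p-value; ties prefer fewer occupied clusters, then grid order.
#'
#' @inheritParams netdpm
#' @param covariates Data frame of scoring covariates aligned with the
#'   samples.
#' @param grid Named list of value vectors to cross: `alpha0`, `eta1`,
#'   `eta2`, ... (one per modality), `nu1`, ..., `nu_cross`.  Omitted
#'   entries keep the value in `hyper`.
#' @param binary Names of the binary covariate columns.
#' @return An object of class `"netdpm_grid"`: `table` (one row per
#'   setting, ranked), `best` (the best fit) and `fits` if `keep_fits`.
#' @param keep_fits Keep every fitted model (memory permitting).
#' @export
netdpm_grid <- function(data, graphs = NULL, covariates, grid,
                        hyper = netdpm_hyper(), control = netdpm_control(),
                        binary = character(), keep_fits = FALSE) {
  stopifnot(is.list(grid), length(grid) > 0)
  if (any(vapply(grid, length, 0L) == 0L))
    stop("grid value lists must be non-empty", call. = FALSE)
  settings <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  M <- length(data$modalities)
  fits <- vector("list", nrow(settings))
  rows <- vector("list", nrow(settings))
  for (i in seq_len(nrow(settings))) {
    hp <- hyper
    s <- settings[i, , drop = FALSE]
    if (!is.null(s$alpha0)) hp$alpha0 <- s$alpha0
    eta <- rep_len(hp$eta, M); nu <- rep_len(hp$nu, M)
    for (m in seq_len(M)) {
      if (!is.null(s[[paste0("eta", m)]])) eta[m] <- s[[paste0("eta", m)]]
      if (!is.null(s[[paste0("nu", m)]])) nu[m] <- s[[paste0("nu", m)]]
    }
    hp$eta <- eta; hp$nu <- nu
    if (!is.null(s$nu_cross)) hp$nu_cross <- s$nu_cross
    fit <- withCallingHandlers(
      netdpm(data, graphs, hp, control),
      warning = function(w) invokeRestart("muffleWarning"))
    sc <- score_partition(fit$labels, covariates, binary)
    rows[[i]] <- cbind(s, data.frame(
      occupied = fit$occupied, converged = fit$converged,
      fisher_stat = sc$fisher$statistic, fisher_p = sc$fisher$p.value))
    if (keep_fits) fits[[i]] <- fit else fits[[i]] <- NULL
    if (i == 1L || sc$fisher$p.value < best_p ||
        (sc$fisher$p.value == best_p && fit$occupied < best_occ)) {
      best_p <- sc$fisher$p.value; best_occ <- fit$occupied
      best_fit <- fit; best_i <- i
    }
  }
  tab <- do.call(rbind, rows)
  tab$setting <- seq_len(nrow(tab))
  ord <- order(tab$fisher_p, tab$occupied, tab$setting)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, best = best_fit, best_setting = best_i,
                 fits = if (keep_fits) fits[ord] else NULL),
            class = "netdpm_grid")
}

#' @export
print.netdpm_grid <- function(x, ...) {
  cat("Grid search over", nrow(x$table), "settings; best setting",
      x$best_setting, "\n")
  print(utils::head(x$table, 10L), row.names = FALSE)
  invisible(x)
}
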