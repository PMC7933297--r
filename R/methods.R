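#' @export
print.netdpm <- function(x, ...) {
  cat("Network-guided DP mixture fit\n")
  cat(sprintf("  %d subjects, %d features, truncation H = %d\n",
              length(x$labels), nrow(x$selection), x$hyper$H))
  cat(sprintf("  occupied clusters: %d (expected size >= 1)\n", x$occupied))
  cat(sprintf("  ELBO: %.4f after %d sweeps (%s)\n",
              x$elbo[length(x$elbo)], x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.netdpm <- function(object, sel_threshold = 0.5, ...) {
  occ <- seq_len(object$occupied)
  nsel <- colSums(object$selection[, occ, drop = FALSE] > sel_threshold)
  out <- list(
    occupied = object$occupied,
    cluster_table = data.frame(
      cluster = occ,
      size = as.integer(round(object$cluster_sizes[occ])),
      weight = object$weights[occ],
      n_selected = as.integer(nsel)),
    elbo = object$elbo[length(object$elbo)],
    converged = object$converged,
    iterations = object$iterations)
  class(out) <- "summary.netdpm"
  out
}

#' @export
print.summary.netdpm <- function(x, ...) {
  cat("Occupied clusters:", x$occupied, "\n")
  print(x$cluster_table, row.names = FALSE)
  cat(sprintf("Final ELBO %.4f after %d sweeps (%s)\n", x$elbo,
              x$iterations, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Posterior-mean cluster parameters
#'
#' @param object A fitted `"netdpm"` object.
#' @param ... Unused.
#' @return A list with matrices `mean`, `var` (Normal features) and `prob`
#'   (Bernoulli features), one column per cluster in size order.
#' @export
coef.netdpm <- function(object, ...) object$params

#' @export
plot.netdpm <- function(x, ...) {
  graphics::plot(seq_along(x$elbo), x$elbo, type = "b", pch = 16,
                 xlab = "sweep", ylab = "ELBO (up to a constant)",
                 main = "Coordinate-ascent ELBO trace", ...)
  invisible(x)
}

#' Classify new subjects under a fitted model
#'
#' Scores each new subject against every cluster with the expected log
#' mixture weight plus the selection-weighted active/null log-likelihood at
#' the posterior-mean cluster parameters, and normalises with a softmax.
#'
#' @param object A fitted `"netdpm"` object.
#' @param newdata A [mm_dataset()] with the same modalities and features as
#'   the training data (sample set may differ).
#' @param type `"class"` for hard assignments, `"prob"` for the full
#'   posterior membership matrix.
#' @param ... Unused.
#' @return An integer vector of cluster labels, or an `n x H` probability
#'   matrix with rows summing to 1.
#' @export
predict.netdpm <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "netdpm_data"))
  if (!identical(newdata$registry, object$data_info$registry))
    stop("`newdata` features do not match the fitted feature registry",
         call. = FALSE)
  if (!is.null(object$data_info$scaling)) {
    for (m in seq_along(newdata$modalities)) {
      sc <- object$data_info$scaling[[m]]
      if (!is.null(sc))
        newdata$modalities[[m]]$X <-
          sweep(sweep(newdata$modalities[[m]]$X, 2L, sc$center), 2L,
                sc$scale, "/")
    }
  }
  info <- object$data_info
  n <- newdata$n; H <- ncol(object$selection)
  Xn <- do.call(cbind, lapply(newdata$modalities, function(m)
    if (m$kind == "normal") m$X else NULL))
  Xb <- do.call(cbind, lapply(newdata$modalities, function(m)
    if (m$kind == "bernoulli") m$X else NULL))
  B <- matrix(object$elogwp, n, H, byrow = TRUE)
  if (length(info$nidx)) {
    Qn <- object$selection[info$nidx, , drop = FALSE]
    Mu <- object$params$mean; S2 <- object$params$var
    iv <- 1 / S2
    cn <- -0.5 * (LOG2PI + log(S2))
    A2 <- Qn * iv
    B <- B - 0.5 * (Xn^2 %*% A2) + Xn %*% (A2 * Mu) +
      matrix(colSums(Qn * cn) - 0.5 * colSums(A2 * Mu^2), n, H, byrow = TRUE)
    ln <- stats::dnorm(Xn, info$null$mu0, sqrt(info$null$sigma0_sq),
                       log = TRUE)
    B <- B + ln %*% (1 - Qn)
  }
  if (length(info$bidx)) {
    Qb <- object$selection[info$bidx, , drop = FALSE]
    Pr <- object$params$prob
    B <- B + Xb %*% (Qb * (log(Pr) - log1p(-Pr))) +
      matrix(colSums(Qb * log1p(-Pr)), n, H, byrow = TRUE)
    lb <- Xb * log(info$null$p0) + (1 - Xb) * log1p(-info$null$p0)
    B <- B + lb %*% (1 - Qb)
  }
  P <- exp(B - row_log_sum_exp(B))
  rownames(P) <- newdata$sample_ids
  colnames(P) <- colnames(object$selection)
  if (type == "prob") P else {
    cls <- max.col(P, ties.method = "first")
    names(cls) <- newdata$sample_ids
    cls
  }
}

#' Write a fit to delimited text files
#'
#' Writes labels (`labels.tsv`), selection probabilities of occupied
#' clusters (`selection.tsv`), the ELBO trace (`elbo.txt`) and a plain-text
#' reproducibility manifest (`manifest.txt`) into `dir`.
#'
#' @param fit A `"netdpm"` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("labels.tsv", "selection.tsv", "elbo.txt",
                            "manifest.txt"))
  utils::write.table(
    data.frame(sample_id = names(fit$labels), cluster = fit$labels),
    paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  occ <- seq_len(max(fit$occupied, 1L))
  sel <- data.frame(feature = rownames(fit$selection),
                    fit$selection[, occ, drop = FALSE],
                    check.names = FALSE)
  utils::write.table(sel, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(format(fit$elbo, digits = 12), paths[3L])
  writeLines(c(
    paste("seed:", fit$control$seed),
    paste("H:", fit$hyper$H),
    paste("alpha0:", fit$hyper$alpha0),
    paste("eta:", paste(fit$hyper$eta, collapse = ",")),
    paste("nu:", paste(fit$hyper$nu, collapse = ",")),
    paste("nu_cross:", fit$hyper$nu_cross),
    paste("occupied:", fit$occupied),
    paste("converged:", fit$converged),
    paste("version:", as.character(utils::packageVersion("netdpm")))),
    paths[4L])
  invisible(paths)
}
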