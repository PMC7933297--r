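#' Read a labelled matrix from delimited text or Matrix Market files
#'
#' Delimited files must carry a header row and ids in the first column.
#' Matrix Market files (`.mtx`) need sidecar files `<path>.rownames` and
#' `<path>.colnames` with one id per line.  The returned matrix is always
#' samples x features; `orientation` states how the file is laid out.
#'
#' @param path Input file.
#' @param orientation `"features_in_rows"` (the common gene-by-sample
#'   layout, default) or `"samples_in_rows"`.
#' @param sep Field separator for delimited files.
#' @return A dense numeric matrix with sample row names and feature column
#'   names.
#' @export
read_matrix <- function(path,
                        orientation = c("features_in_rows",
                                        "samples_in_rows"),
                        sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.mtx$", path)) {
    M <- as.matrix(Matrix::readMM(path))
    rn <- paste0(path, ".rownames"); cn <- paste0(path, ".colnames")
    if (!file.exists(rn) || !file.exists(cn))
      stop("MTX input needs sidecar files ", rn, " and ", cn, call. = FALSE)
    rownames(M) <- readLines(rn)
    colnames(M) <- readLines(cn)
  } else {
    nf <- utils::count.fields(path, sep = sep, comment.char = "#")
    if (length(unique(nf)) > 1L)
      stop("ragged rows in ", path, " (first at line ",
           which(nf != nf[1L])[1L], ")", call. = FALSE)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            row.names = NULL, check.names = FALSE,
                            comment.char = "#")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
      stop("duplicate row id in ", path, ": ",
           ids[duplicated(ids)][1L], call. = FALSE)
    M <- as.matrix(df[, -1L, drop = FALSE])
    rownames(M) <- ids
  }
  if (anyDuplicated(colnames(M)))
    stop("duplicate column id in ", path, ": ",
         colnames(M)[duplicated(colnames(M))][1L], call. = FALSE)
  storage.mode(M) <- "double"
  if (orientation == "features_in_rows") M <- t(M)
  M
}

#' Write a labelled matrix as delimited text
#'
#' Inverse of [read_matrix()] for the delimited format.
#'
#' @param M Samples x features matrix with dimnames.
#' @param path Output file.
#' @inheritParams read_matrix
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(M, path,
                         orientation = c("features_in_rows",
                                         "samples_in_rows"),
                         sep = "\t") {
  orientation <- match.arg(orientation)
  out <- if (orientation == "features_in_rows") t(M) else M
  df <- data.frame(id = rownames(out), out, check.names = FALSE)
  names(df)[1L] <- if (orientation == "features_in_rows") "feature"
    else "sample"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align modality matrices into one dataset
#'
#' @param mats Named list of samples x features matrices.
#' @param kinds Modality kinds, as in [mm_dataset()].
#' @param policy `"strict"` requires identical sample sets in identical
#'   order; `"intersect"` inner-joins on sample ids (order of the first
#'   matrix) and reports how many samples were dropped.
#' @return An [mm_dataset()].
#' @export
align_modalities <- function(mats, kinds, policy = c("strict", "intersect")) {
  policy <- match.arg(policy)
  stopifnot(length(mats) >= 1L)
  ids1 <- rownames(mats[[1L]])
  if (policy == "strict") {
    for (m in seq_along(mats)) {
      if (!identical(rownames(mats[[m]]), ids1)) {
        off <- c(setdiff(rownames(mats[[m]]), ids1),
                 setdiff(ids1, rownames(mats[[m]])))
        if (length(off))
          stop("strict alignment failed; offending sample ids: ",
               paste(utils::head(off, 10L), collapse = ", "),
               call. = FALSE)
        stop("strict alignment failed: same samples but different order",
             call. = FALSE)
      }
    }
    common <- ids1
  } else {
    common <- ids1
    for (m in seq_along(mats)[-1L])
      common <- common[common %in% rownames(mats[[m]])]
    if (!length(common))
      stop("empty sample intersection across modalities", call. = FALSE)
    dropped <- length(unique(unlist(lapply(mats, rownames)))) -
      length(common)
    if (dropped > 0L)
      message("align_modalities: dropped ", dropped,
              " samples absent from some modality")
    mats <- lapply(mats, function(M) M[common, , drop = FALSE])
  }
  mm_dataset(mats, kinds = kinds)
}

#' Read graph edge lists from a tagged TSV file
#'
#' Expected columns: `graph_tag`, `feature_a`, `feature_b`, where
#' `graph_tag` is `within:<modality>` or `cross:<modA>:<modB>`.  Lines
#' starting with `#` are comments.
#'
#' @param path Edge-list file.
#' @param data The [mm_dataset()] whose features the edges reference.
#' @return A [graph_set()].
#' @export
read_edge_lists <- function(path, data) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("edge-list file needs columns graph_tag, feature_a, feature_b",
         call. = FALSE)
  within <- list(); cross <- list()
  for (tag in unique(df[[1L]])) {
    ed <- as.matrix(df[df[[1L]] == tag, 2:3])
    if (startsWith(tag, "within:")) {
      within[[sub("^within:", "", tag)]] <- ed
    } else if (startsWith(tag, "cross:")) {
      cross[[sub("^cross:", "", tag)]] <- ed
    } else {
      stop("unknown graph tag: ", tag, call. = FALSE)
    }
  }
  graph_set(data, within = within, cross = cross)
}

#' Write a graph set as a tagged edge-list TSV
#'
#' @param graphs A [graph_set()].
#' @param data The dataset the graph was built over (for feature ids).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_edge_lists <- function(graphs, data, path) {
  rows <- list()
  feats <- lapply(data$modalities, function(m) colnames(m$X))
  names(feats) <- vapply(data$modalities, function(m) m$name, "")
  for (nm in names(graphs$within)) {
    ed <- graphs$within[[nm]]
    if (nrow(ed))
      rows[[length(rows) + 1L]] <- data.frame(
        graph_tag = paste0("within:", nm),
        feature_a = feats[[nm]][ed[, 1L]],
        feature_b = feats[[nm]][ed[, 2L]])
  }
  for (nm in names(graphs$cross)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    ed <- graphs$cross[[nm]]
    if (nrow(ed))
      rows[[length(rows) + 1L]] <- data.frame(
        graph_tag = paste0("cross:", nm),
        feature_a = feats[[parts[1L]]][ed[, 1L]],
        feature_b = feats[[parts[2L]]][ed[, 2L]])
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(graph_tag = character(), feature_a = character(),
               feature_b = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# minimal --flag value parser for run_cli
parse_flags <- function(args) {
  out <- list(); i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[[i + 1L]]; i <- i + 2L
    }
  }
  out
}

cli_usage <- function() {
  cat("usage: netdpm-cli.R <subcommand> [--flags]\n",
      "subcommands:\n",
      "  simulate --out DIR [--n N --p P --seed S]\n",
      "  fit --normal FILE --bernoulli FILE --out DIR\n",
      "      [--graphs FILE --eta E1,E2 --nu V1,V2 --nu-cross V --alpha0 A\n",
      "       --H H --seed S --no-standardize --gibbs]\n",
      "  select --normal FILE --bernoulli FILE --covariates FILE --out DIR\n",
      "      [--binary COLS --alpha0-grid A1,A2 --eta1-grid ... --seed S]\n",
      "  evaluate --labels-a FILE --labels-b FILE\n", sep = "")
}

num_list <- function(x) as.numeric(strsplit(as.character(x), ",")[[1L]])

#' Command-line entry point
#'
#' A thin shell interface over the package's functions with subcommands
#' `simulate`, `fit`, `select` and `evaluate`; see
#' `system.file("scripts", "netdpm-cli.R", package = "netdpm")` for the
#' launcher.  The `fit` subcommand standardizes continuous modalities by
#' default (disable with `--no-standardize`), matching the diffuse null.
#' Every run writes a manifest recording seed and settings.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly (0 on success).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { cli_usage(); return(invisible(1L)) }
  sub <- args[[1L]]
  fl <- tryCatch(parse_flags(args[-1L]), error = function(e) e)
  if (inherits(fl, "error") ||
      !sub %in% c("simulate", "fit", "select", "evaluate")) {
    cli_usage(); return(invisible(1L))
  }
  status <- tryCatch({
    switch(sub,
      simulate = cli_simulate(fl),
      fit = cli_fit(fl),
      select = cli_select(fl),
      evaluate = cli_evaluate(fl))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_simulate <- function(fl) {
  if (is.null(fl$out)) stop("simulate needs --out DIR")
  des <- sim_design(
    n = as.integer(fl$n %||% 300L), p = as.integer(fl$p %||% 200L),
    seed = as.integer(fl$seed %||% 1L))
  sim <- simulate_multimodal(des)
  dir.create(fl$out, recursive = TRUE, showWarnings = FALSE)
  for (m in sim$data$modalities)
    write_matrix(m$X, file.path(fl$out, paste0(m$name, ".tsv")))
  utils::write.table(
    data.frame(sample_id = names(sim$truth$labels),
               group = sim$truth$labels),
    file.path(fl$out, "truth_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$truth$signal_features,
             file.path(fl$out, "signal_features.txt"))
  gs <- simulate_graphset(sim, seed = des$seed)
  write_edge_lists(gs, sim$data, file.path(fl$out, "graphs.tsv"))
  writeLines(c(paste("seed:", des$seed), paste("n:", des$n),
               paste("p:", des$p)),
             file.path(fl$out, "manifest.txt"))
  invisible(NULL)
}

cli_load_data <- function(fl) {
  mats <- list(); kinds <- character()
  if (!is.null(fl$normal)) {
    mats$expr <- read_matrix(fl$normal,
                             orientation = fl$orientation %||%
                               "features_in_rows")
    kinds <- c(kinds, "normal")
  }
  if (!is.null(fl$bernoulli)) {
    mats$alt <- read_matrix(fl$bernoulli,
                            orientation = fl$orientation %||%
                              "features_in_rows")
    kinds <- c(kinds, "bernoulli")
  }
  if (!length(mats)) stop("need --normal and/or --bernoulli inputs")
  align_modalities(mats, kinds,
                   policy = if (isTRUE(fl$intersect)) "intersect"
                   else "strict")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_fit <- function(fl) {
  if (is.null(fl$out)) stop("fit needs --out DIR")
  data <- cli_load_data(fl)
  graphs <- if (!is.null(fl$graphs)) read_edge_lists(fl$graphs, data)
    else NULL
  hyper <- netdpm_hyper(
    alpha0 = as.numeric(fl$alpha0 %||% 1),
    eta = if (!is.null(fl$eta)) num_list(fl$eta) else 10,
    nu = if (!is.null(fl$nu)) num_list(fl$nu) else 1,
    nu_cross = as.numeric(fl[["nu-cross"]] %||% 1),
    H = as.integer(fl$H %||% 30L))
  control <- netdpm_control(
    seed = as.integer(fl$seed %||% 1L),
    standardize = !isTRUE(fl[["no-standardize"]]))
  fit <- netdpm(data, graphs, hyper, control)
  write_fit(fit, fl$out)
  if (isTRUE(fl$gibbs)) {
    g <- netdpm_gibbs(data, graphs, hyper,
                      gibbs_config(seed = control$seed, H = hyper$H))
    ps <- posterior_similarity(g)
    utils::write.table(
      data.frame(sample_id = names(ps$partition),
                 cluster = ps$partition),
      file.path(fl$out, "gibbs_labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

cli_select <- function(fl) {
  if (is.null(fl$out)) stop("select needs --out DIR")
  if (is.null(fl$covariates)) stop("select needs --covariates FILE")
  data <- cli_load_data(fl)
  graphs <- if (!is.null(fl$graphs)) read_edge_lists(fl$graphs, data)
    else NULL
  cov <- utils::read.table(fl$covariates, header = TRUE, sep = "\t")
  cov <- cov[match(data$sample_ids, cov$sample_id), , drop = FALSE]
  binary <- if (!is.null(fl$binary))
    strsplit(fl$binary, ",")[[1L]] else character()
  grid <- list()
  if (!is.null(fl[["alpha0-grid"]]))
    grid$alpha0 <- num_list(fl[["alpha0-grid"]])
  for (m in 1:2) {
    key <- paste0("eta", m, "-grid")
    if (!is.null(fl[[key]])) grid[[paste0("eta", m)]] <- num_list(fl[[key]])
  }
  if (!length(grid)) stop("select needs at least one *-grid flag")
  control <- netdpm_control(seed = as.integer(fl$seed %||% 1L),
                            standardize = !isTRUE(fl[["no-standardize"]]))
  res <- netdpm_grid(data, graphs, cov, grid,
                     hyper = netdpm_hyper(H = as.integer(fl$H %||% 30L)),
                     control = control, binary = binary)
  dir.create(fl$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$table, file.path(fl$out, "grid_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fit(res$best, file.path(fl$out, "best"))
  invisible(NULL)
}

cli_evaluate <- function(fl) {
  if (is.null(fl[["labels-a"]]) || is.null(fl[["labels-b"]]))
    stop("evaluate needs --labels-a and --labels-b files")
  a <- utils::read.table(fl[["labels-a"]], header = TRUE, sep = "\t")
  b <- utils::read.table(fl[["labels-b"]], header = TRUE, sep = "\t")
  merged <- merge(a, b, by = 1L)
  ri <- rand_index(merged[[2L]], merged[[3L]])
  cat(sprintf("rand_index\t%.6f\nadjusted_rand\t%.6f\n",
              ri$rand, ri$adjusted))
  invisible(NULL)
}
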