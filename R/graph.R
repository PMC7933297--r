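#' Build a set of biological graphs over registered features
#'
#' Stores undirected within-modality graphs and cross-modality bipartite
#' graphs whose nodes are the features of a [mm_dataset()].  Edges are
#' unweighted; self-loops are dropped and duplicated (or reversed) pairs are
#' collapsed.
#'
#' @param data A `"netdpm_data"` object supplying the feature registry.
#' @param within Named list (names = modality names); each element a
#'   two-column matrix or data frame of feature-id pairs inside that
#'   modality.
#' @param cross Named list with names of the form `"modA:modB"`; each element
#'   a two-column matrix of (feature in modA, feature in modB) pairs.
#' @return An object of class `"netdpm_graphs"` with integer edge matrices in
#'   local (per-modality) column indices and the total edge count `e`.
#' @examples
#' d <- mm_dataset(list(expr = matrix(rnorm(12), 3,
#'                      dimnames = list(NULL, c("a", "b", "c", "d")))),
#'                 kinds = "normal")
#' g <- graph_set(d, within = list(expr = rbind(c("a","b"), c("b","a"))))
#' g$e  # 1: the reversed duplicate is collapsed
#' @export
graph_set <- function(data, within = list(), cross = list()) {
  stopifnot(inherits(data, "netdpm_data"))
  modnames <- vapply(data$modalities, function(m) m$name, "")
  w_out <- list()
  for (nm in names(within)) {
    m <- match(nm, modnames)
    if (is.na(m)) stop("unknown modality in `within`: ", nm, call. = FALSE)
    ed <- resolve_edges(within[[nm]], colnames(data$modalities[[m]]$X),
                        colnames(data$modalities[[m]]$X), nm, nm)
    # unordered: sort each pair, drop self-loops, dedupe
    if (nrow(ed)) {
      ed <- t(apply(ed, 1L, sort))
      ed <- ed[ed[, 1L] != ed[, 2L], , drop = FALSE]
      ed <- unique(ed)
    }
    w_out[[nm]] <- ed
  }
  c_out <- list()
  for (nm in names(cross)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("cross-graph names must be 'modA:modB', got: ", nm, call. = FALSE)
    ma <- match(parts[1L], modnames); mb <- match(parts[2L], modnames)
    if (is.na(ma) || is.na(mb))
      stop("unknown modality in cross graph '", nm, "'", call. = FALSE)
    if (ma == mb)
      stop("cross graph '", nm, "' names a single modality; ",
           "use `within` for intra-modality edges", call. = FALSE)
    ed <- resolve_edges(cross[[nm]], colnames(data$modalities[[ma]]$X),
                        colnames(data$modalities[[mb]]$X),
                        parts[1L], parts[2L])
    if (nrow(ed)) ed <- unique(ed)
    c_out[[nm]] <- ed
  }
  structure(
    list(within = w_out, cross = c_out, modalities = modnames,
         p_m = vapply(data$modalities, function(m) ncol(m$X), 0L),
         e = sum(vapply(w_out, nrow, 0L)) + sum(vapply(c_out, nrow, 0L))),
    class = "netdpm_graphs")
}

resolve_edges <- function(pairs, ids_a, ids_b, name_a, name_b) {
  if (is.null(pairs) || NROW(pairs) == 0L)
    return(matrix(integer(), 0L, 2L))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L)
    stop("edge lists must have two columns", call. = FALSE)
  a <- match(as.character(pairs[, 1L]), ids_a)
  b <- match(as.character(pairs[, 2L]), ids_b)
  bad <- unique(c(as.character(pairs[is.na(a), 1L]),
                  as.character(pairs[is.na(b), 2L])))
  if (length(bad))
    stop("unresolvable feature id(s) in graph ", name_a, "~", name_b, ": ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  cbind(a, b, deparse.level = 0L)
}

#' @export
print.netdpm_graphs <- function(x, ...) {
  cat("Graph set over", sum(x$p_m), "features:", x$e, "edges\n")
  for (nm in names(x$within))
    cat(sprintf("  within %s: %d\n", nm, nrow(x$within[[nm]])))
  for (nm in names(x$cross))
    cat(sprintf("  cross %s: %d\n", nm, nrow(x$cross[[nm]])))
  invisible(x)
}

#' Empty graph set
#'
#' Convenience constructor for fitting without network information: the
#' Ising prior then reduces to independent sparsity penalties.
#'
#' @inheritParams graph_set
#' @return A `"netdpm_graphs"` object with zero edges.
#' @export
empty_graphs <- function(data) graph_set(data)

#' Unnormalised log Ising prior of a selection configuration
#'
#' Computes `-sum_m eta_m * (active features in m) + sum_m nu_m * (within-m
#' edges whose endpoints agree) + nu_cross * (cross edges whose endpoints
#' agree)`.  The normalising constant of the Ising prior is intractable and
#' is not computed.
#'
#' @param gamma Named list (one binary 0/1 vector per modality, aligned with
#'   the modality's features) or a single vector for one modality.
#' @param graphs A `"netdpm_graphs"` object.
#' @param eta Nonnegative sparsity penalties, recycled across modalities.
#' @param nu Nonnegative within-modality smoothness rewards, recycled.
#' @param nu_cross Nonnegative cross-modality smoothness reward.
#' @return The unnormalised log prior (a single number).
#' @export
ising_log_potential <- function(gamma, graphs, eta, nu = 0, nu_cross = 0) {
  if (!is.list(gamma)) gamma <- list(gamma)
  M <- length(graphs$modalities)
  if (length(gamma) != M)
    stop("`gamma` must have one vector per modality", call. = FALSE)
  names(gamma) <- graphs$modalities
  eta <- rep_len(eta, M); nu <- rep_len(nu, M)
  if (any(eta < 0) || any(nu < 0) || nu_cross < 0)
    stop("Ising hyperparameters must be nonnegative", call. = FALSE)
  for (m in seq_len(M))
    if (length(gamma[[m]]) != graphs$p_m[m])
      stop("gamma length mismatch in modality ", graphs$modalities[m],
           call. = FALSE)
  val <- -sum(eta * vapply(gamma, sum, 0))
  for (nm in names(graphs$within)) {
    m <- match(nm, graphs$modalities)
    ed <- graphs$within[[nm]]
    if (nrow(ed))
      val <- val + nu[m] * sum(gamma[[m]][ed[, 1L]] == gamma[[m]][ed[, 2L]])
  }
  for (nm in names(graphs$cross)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    ma <- match(parts[1L], graphs$modalities)
    mb <- match(parts[2L], graphs$modalities)
    ed <- graphs$cross[[nm]]
    if (nrow(ed))
      val <- val + nu_cross *
        sum(gamma[[ma]][ed[, 1L]] == gamma[[mb]][ed[, 2L]])
  }
  val
}

#' Mean-field probability that two selection indicators agree
#'
#' Under independent variational Bernoullis with success probabilities
#' `q_j` and `q_k`, the edge-concordance indicator has expectation
#' `q_j q_k + (1 - q_j)(1 - q_k)`.
#'
#' @param q_j,q_k Probabilities in `[0, 1]` (vectorised).
#' @return Probabilities in `[0, 1]`.
#' @export
edge_concordance <- function(q_j, q_k) {
  if (any(q_j < 0 | q_j > 1 | q_k < 0 | q_k > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  q_j * q_k + (1 - q_j) * (1 - q_k)
}

# Global-index edge table used by the VB engine and Gibbs sampler:
# columns a, b (1..p global feature indices) and the smoothness weight of the
# edge (nu_m within modality m, nu_cross across).
global_edges <- function(graphs, nu, nu_cross) {
  M <- length(graphs$modalities)
  nu <- rep_len(nu, M)
  off <- c(0L, cumsum(graphs$p_m))[seq_len(M)]
  names(off) <- graphs$modalities
  ab <- matrix(integer(), 0L, 2L); w <- numeric()
  for (nm in names(graphs$within)) {
    ed <- graphs$within[[nm]]
    if (nrow(ed)) {
      ab <- rbind(ab, ed + off[[nm]])
      w <- c(w, rep(nu[match(nm, graphs$modalities)], nrow(ed)))
    }
  }
  for (nm in names(graphs$cross)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    ed <- graphs$cross[[nm]]
    if (nrow(ed)) {
      ab <- rbind(ab, cbind(ed[, 1L] + off[[parts[1L]]],
                            ed[, 2L] + off[[parts[2L]]]))
      w <- c(w, rep(nu_cross, nrow(ed)))
    }
  }
  list(ab = ab, w = w)
}

# adjacency list over global indices: for each feature that touches an edge,
# the neighbor indices and edge weights
adjacency_list <- function(edges, p) {
  adj <- vector("list", p)
  if (nrow(edges$ab)) {
    for (r in seq_len(nrow(edges$ab))) {
      a <- edges$ab[r, 1L]; b <- edges$ab[r, 2L]; w <- edges$w[r]
      adj[[a]] <- rbind(adj[[a]], c(b, w))
      adj[[b]] <- rbind(adj[[b]], c(a, w))
    }
  }
  adj
}

#' Ising neighbour field of the variational selection probabilities
#'
#' For every feature `j` and cluster `h`, returns the local difference in
#' expected Ising potential between selecting and not selecting the feature:
#' `-eta_m(j) + sum_{k ~ j} w_jk (2 q_kh - 1)`, where the sum runs over graph
#' neighbours of `j` (within- and cross-modality) and `w_jk` is `nu_m` or
#' `nu_cross`.  This is the prior contribution to the coordinate update of
#' each selection logit.
#'
#' @param sel_prob `p x H` matrix of current selection probabilities in
#'   global feature (registry) order.
#' @inheritParams ising_log_potential
#' @return A `p x H` matrix of field values.
#' @export
ising_field <- function(sel_prob, graphs, eta, nu = 0, nu_cross = 0) {
  sel_prob <- as.matrix(sel_prob)
  p <- sum(graphs$p_m)
  if (nrow(sel_prob) != p)
    stop("`sel_prob` must have one row per registered feature", call. = FALSE)
  if (any(sel_prob < 0 | sel_prob > 1))
    stop("selection probabilities must lie in [0, 1]", call. = FALSE)
  M <- length(graphs$modalities)
  eta <- rep_len(eta, M)
  fld <- matrix(-rep(rep(eta, graphs$p_m), ncol(sel_prob)),
                p, ncol(sel_prob))
  ed <- global_edges(graphs, nu, nu_cross)
  if (nrow(ed$ab)) {
    S <- 2 * sel_prob - 1
    for (r in seq_len(nrow(ed$ab))) {
      a <- ed$ab[r, 1L]; b <- ed$ab[r, 2L]
      fld[a, ] <- fld[a, ] + ed$w[r] * S[b, ]
      fld[b, ] <- fld[b, ] + ed$w[r] * S[a, ]
    }
  }
  fld
}
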