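# Agglomerative Ward clustering on correlation-derived distances.
#
# The shape distance is d = sqrt(1 - CC^2), so d = 0 for identical shapes
# and 1 for uncorrelated ones. Clustering follows ward.D semantics: the
# Lance-Williams Ward update is applied directly to the given distances,
# NOT to their squares (that variant is commonly called ward.D2). Exact
# ties merge the pair with the lowest indices, making dendrograms
# deterministic.

#' Convert a correlation coefficient to the clustering distance
#'
#' `d = sqrt(1 - CC^2)`.
#'
#' @param CC Correlation value(s) in `[-1, 1]`.
#' @return Distance(s) in `[0, 1]`.
#' @export
cc_to_distance <- function(CC) {
  if (any(abs(CC) > 1 + 1e-12)) {
    stop_shapesearch("|CC| > 1 is outside the correlation domain",
                     "shapesearch_domain_error")
  }
  out <- CC  # keep dim/dimnames: pmin/pmax would drop them
  out[] <- sqrt(1 - pmin(1, abs(CC))^2)
  out
}

#' Ward (ward.D) hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with the Lance-Williams Ward update applied to
#' unsquared distances:
#' `d(k, ij) = ((n_i + n_k) d(k,i) + (n_j + n_k) d(k,j) - n_k d(i,j)) / (n_i + n_j + n_k)`.
#' On exact ties the pair with the lowest indices merges first.
#'
#' @param D Symmetric nonnegative distance matrix (optionally with
#'   dimnames used as labels), or a `dist` object.
#' @return A `Dendrogram`: list with `merge` (hclust convention), `height`,
#'   `labels`, and the input distances (`dist`, as a matrix) retained for
#'   representative selection.
#' @export
ward_cluster <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 2) {
    stop_shapesearch("need at least 2 items to cluster",
                     "shapesearch_domain_error")
  }
  labels <- rownames(D) %||% as.character(seq_len(n))
  d <- D
  diag(d) <- Inf
  size <- rep(1, n)
  # cluster id per active slot: -i singleton, +step merged cluster
  id <- -seq_len(n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    act <- which(active)
    sub <- d[act, act, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    # lowest (i, j) pair on ties, i < j in original slot order
    pick <- best[order(pmin(best[, 1], best[, 2]),
                       pmax(best[, 1], best[, 2]))[1], ]
    i <- act[min(pick)]; j <- act[max(pick)]
    height[step] <- d[i, j]
    a <- c(id[i], id[j])
    # hclust row convention: singletons (negative) first, then by index
    a <- a[order(a >= 0, abs(a))]
    merge[step, ] <- a
    # Lance-Williams Ward update into slot i
    ni <- size[i]; nj <- size[j]
    for (k in act) {
      if (k == i || k == j) next
      nk <- size[k]
      d[i, k] <- d[k, i] <-
        ((ni + nk) * d[k, i] + (nj + nk) * d[k, j] - nk * d[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    id[i] <- step
    d[j, ] <- Inf; d[, j] <- Inf
  }
  structure(
    list(merge = merge, height = height, labels = labels, dist = D),
    class = "Dendrogram"
  )
}

#' @export
print.Dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram: %d leaves, merge heights %.3g .. %.3g (median %.3g)\n",
              length(x$labels), min(x$height), max(x$height),
              stats::median(x$height)))
  invisible(x)
}

#' Convert a `Dendrogram` to an `hclust` object
#' @param x A `Dendrogram`.
#' @param ... Unused.
#' @return An `hclust` object (for plotting or `cutree`).
#' @export
as.hclust.Dendrogram <- function(x, ...) {
  ord <- dendro_leaf_order(x)
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "ward.D",
                 call = match.call(), dist.method = "shape"),
            class = "hclust")
}

dendro_leaf_order <- function(tree) {
  n <- length(tree$labels)
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(tree$merge[node, 1]), walk(tree$merge[node, 2]))
  }
  walk(nrow(tree$merge))
}

# cluster membership after applying all merges with height <= cutoff
cut_dendrogram <- function(tree, cutoff) {
  n <- length(tree$labels)
  memb <- seq_len(n)
  node_members <- vector("list", nrow(tree$merge))
  for (s in seq_len(nrow(tree$merge))) {
    m1 <- tree$merge[s, 1]; m2 <- tree$merge[s, 2]
    mem <- c(if (m1 < 0) -m1 else node_members[[m1]],
             if (m2 < 0) -m2 else node_members[[m2]])
    node_members[[s]] <- mem
    if (tree$height[s] <= cutoff) {
      memb[mem] <- min(memb[mem])
    }
  }
  match(memb, unique(memb))
}

#' Select one representative model per cluster
#'
#' Cuts the dendrogram at `cutoff` (default: the median merge height, the
#' point at which half of the structures have clustered) and, within each
#' cluster, picks the medoid: the member minimizing the summed distance to
#' its co-members, lowest index on ties.
#'
#' @param tree A `Dendrogram` from [ward_cluster()].
#' @param cutoff Cut height; `NULL` for the median merge height.
#' @return Character vector of representative labels, attribute
#'   `clusters` giving the full membership.
#' @export
select_representatives <- function(tree, cutoff = NULL) {
  cutoff <- cutoff %||% stats::median(tree$height)
  if (cutoff < 0) {
    stop_shapesearch("cutoff must be nonnegative", "shapesearch_domain_error")
  }
  memb <- cut_dendrogram(tree, cutoff)
  D <- tree$dist
  reps <- integer(max(memb))
  for (cl in seq_len(max(memb))) {
    mem <- which(memb == cl)
    if (length(mem) == 1) {
      reps[cl] <- mem
    } else {
      tot <- rowSums(D[mem, mem, drop = FALSE])
      reps[cl] <- mem[which.min(tot)]  # which.min takes the lowest on ties
    }
  }
  structure(tree$labels[sort(reps)],
            clusters = stats::setNames(memb, tree$labels))
}
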