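# Diagnostics of image-space structure: per-model Pearson-correlation
# clustering of 2D similarity profiles, classical (Torgerson) MDS of image
# distances, and binning of the 2D embedding into 0.1 x 0.1 unit cells with
# per-cell representatives.

#' Per-model Pearson correlation matrix from an all-pairs image CC matrix
#'
#' Each model's similarity profile is the column-wise mean of its images'
#' rows: a vector over all library images. The Pearson correlation between
#' two models' profiles summarizes how similarly their projection sets
#' relate to the whole library.
#'
#' @param cc_full Square symmetric CC matrix over all images.
#' @param index Model identifier per image (row/column).
#' @return Symmetric model-by-model PCC matrix with unit diagonal.
#' @export
model_pcc_matrix <- function(cc_full, index) {
  cc_full <- as.matrix(cc_full)
  stopifnot(nrow(cc_full) == ncol(cc_full), length(index) == nrow(cc_full))
  models <- unique(index)
  profiles <- vapply(models, function(n) {
    colMeans(cc_full[index == n, , drop = FALSE])
  }, numeric(ncol(cc_full)))
  sds <- apply(profiles, 2, stats::sd)
  if (any(sds <= 0 | !is.finite(sds))) {
    stop_shapesearch(
      sprintf("degenerate (constant) profile for model(s): %s",
              paste(models[sds <= 0 | !is.finite(sds)], collapse = ", ")),
      "shapesearch_degenerate_error")
  }
  P <- stats::cor(profiles)
  diag(P) <- 1
  dimnames(P) <- list(models, models)
  P
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns the top-k
#' coordinates scaled by the square roots of the eigenvalues. Exact for
#' Euclidean input distances. Goodness of fit is the fraction of the
#' positive eigenvalue mass captured by the first k axes.
#'
#' @param D Distance matrix (or `dist`).
#' @param k Embedding dimension (default 2).
#' @return An `MDSEmbedding`: list with `points` (n x k, centered),
#'   `eigenvalues` (all, non-increasing), and `gof`.
#' @export
classical_mds <- function(D, k = 2) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(k >= 1, nrow(D) == ncol(D))
  n <- nrow(D)
  B <- -0.5 * D^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > 1e-12 * max(abs(e$values))
  if (!any(pos)) {
    stop_shapesearch("degenerate geometry: no positive eigenvalues",
                     "shapesearch_degenerate_error")
  }
  kk <- min(k, sum(pos))
  pts <- e$vectors[, seq_len(kk), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(kk)]), kk)
  if (kk < k) pts <- cbind(pts, matrix(0, n, k - kk))
  rownames(pts) <- rownames(D)
  structure(
    list(points = pts, eigenvalues = e$values,
         gof = sum(e$values[seq_len(kk)]) / sum(e$values[pos])),
    class = "MDSEmbedding"
  )
}

#' @export
print.MDSEmbedding <- function(x, ...) {
  cat(sprintf("MDSEmbedding: %d points in %d dims, GOF %.3f\n",
              nrow(x$points), ncol(x$points), x$gof))
  invisible(x)
}

#' Bin a 2D embedding into square cells and summarize each cell
#'
#' Cells are half-open squares `[m*cell, (m+1)*cell)` on both axes. Each
#' occupied cell reports its image count, the mean pairwise CC between the
#' images it contains (omitted as `NA` for singleton cells), and a
#' representative image drawn from the most frequent model in the cell
#' (lowest image id on ties). Empty cells are absent.
#'
#' @param emb An `MDSEmbedding` (2D).
#' @param cc_full All-pairs image CC matrix.
#' @param index Model identifier per image.
#' @param cell Cell pitch (default 0.1).
#' @return Data frame: `row`, `col`, `count`, `mean_cc`,
#'   `representative` (image id), `model_id`.
#' @export
grid_bin_embedding <- function(emb, cc_full, index, cell = 0.1) {
  stopifnot(cell > 0, ncol(emb$points) >= 2)
  pts <- emb$points[, 1:2, drop = FALSE]
  cc_full <- as.matrix(cc_full)
  r <- floor(pts[, 1] / cell)
  cl <- floor(pts[, 2] / cell)
  key <- paste(r, cl, sep = ":")
  out <- lapply(unique(key), function(kk) {
    mem <- which(key == kk)
    mean_cc <- if (length(mem) > 1) {
      sub <- cc_full[mem, mem, drop = FALSE]
      mean(sub[upper.tri(sub)])
    } else {
      NA_real_
    }
    tab <- table(index[mem])
    top_model <- names(tab)[tab == max(tab)]
    top_model <- sort(top_model)[1]
    rep_img <- min(mem[index[mem] == top_model])
    data.frame(row = r[mem[1]], col = cl[mem[1]], count = length(mem),
               mean_cc = mean_cc, representative = rep_img,
               model_id = top_model, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$row, res$col), , drop = FALSE]
}

#' Hierarchically cluster models from a similarity matrix
#'
#' Applies the distance transform `d = sqrt(1 - CC^2)` elementwise and
#' runs Ward (ward.D) clustering. Used both for 3D overlap CCs and for 2D
#' projection-profile PCCs; numerically equal inputs give identical trees.
#'
#' @param sim Symmetric model similarity matrix (CC or PCC, unit diagonal).
#' @return A `Dendrogram`.
#' @export
cluster_models <- function(sim) {
  sim <- as.matrix(sim)
  D <- cc_to_distance(sim)
  diag(D) <- 0
  ward_cluster(D)
}

#' Full all-pairs alignment CC matrix of an image stack
#'
#' Convenience wrapper computing `cc[i, j]` = maximum alignment CC of image
#' i against image j for a whole stack (used by the 2D clustering and MDS
#' diagnostics). Each row is one FFT stack scan.
#'
#' @param stack An `ImageStack`.
#' @param psi_step,max_shift Alignment parameters.
#' @return Symmetric-ish CC matrix (row scans; small search-grid asymmetry
#'   is symmetrized by averaging).
#' @export
allpairs_cc_matrix <- function(stack, psi_step = 6, max_shift = 10) {
  m <- n_images(stack)
  cc <- matrix(0, m, m)
  for (i in seq_len(m)) {
    cc[i, ] <- align_stack_to_reference(stack$pixels[, , i], stack,
                                        psi_step = psi_step,
                                        max_shift = max_shift)
  }
  (cc + t(cc)) / 2
}
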