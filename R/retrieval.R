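# Match retrieval scoring.
#
# Every query image i is aligned against the whole library, giving CC_{i,j}
# for library image j. Each CC row is standardized to Z-scores,
#   Z(i,j) = (CC_{i,j} - mu_i) / sigma_i,
# which equalizes the contribution of each query image regardless of its
# contrast or absolute correlation level. Per library model n, the top k
# (default 10) Z-scores of each row are summed to X_i^n; S_n = sum_i X_i^n
# over query images, and the final match score standardizes S over models,
#   T_n = (S_n - mu_S) / sigma_S.
# Population standard deviations (divide by N) are used throughout; a
# switch to sample SD is exposed for completeness.

pop_sd <- function(x, sample_sd = FALSE) {
  n <- length(x)
  if (sample_sd) stats::sd(x) else sqrt(sum((x - mean(x))^2) / n)
}

#' Row-standardize a query-by-library CC matrix
#'
#' @param cc Numeric matrix, rows = query images, columns = library images
#'   (at least 2 columns).
#' @param sample_sd Use the sample SD (divide by N-1) instead of the
#'   population SD. Default `FALSE`.
#' @return A `ZScoreMatrix`: the standardized matrix with attributes
#'   `row_means` and `row_sds`.
#' @export
zscore_rows <- function(cc, sample_sd = FALSE) {
  cc <- as.matrix(cc)
  stopifnot(ncol(cc) >= 2)
  mu <- rowMeans(cc)
  sd_ <- apply(cc, 1, pop_sd, sample_sd = sample_sd)
  bad <- which(sd_ <= 0 | !is.finite(sd_))
  if (length(bad)) {
    stop_shapesearch(
      sprintf("degenerate CC row (constant): query image %s",
              paste(bad, collapse = ", ")),
      "shapesearch_degenerate_error")
  }
  z <- (cc - mu) / sd_
  structure(z, row_means = mu, row_sds = sd_, class = c("ZScoreMatrix",
                                                        class(z)))
}

#' Per-model top-k Z-score sum for one query image
#'
#' For each model n, sums the k largest Z-scores among the columns mapped
#' to n. Models with fewer than k images contribute the sum of all their
#' Z-scores, with a warning.
#'
#' @param z_row Numeric vector of Z-scores for one query image.
#' @param index Model identifier per column (same length as `z_row`).
#' @param k Number of top scores to sum (default 10).
#' @return Named numeric vector `X_i^n`, one entry per model (in order of
#'   first appearance in `index`).
#' @export
per_model_topk_sum <- function(z_row, index, k = 10) {
  stopifnot(k >= 1, length(z_row) == length(index))
  models <- unique(index)
  out <- vapply(models, function(n) {
    zs <- z_row[index == n]
    if (length(zs) < k) {
      sum(zs)
    } else {
      # stable tie-break: sort by (-value, column position)
      sum(zs[order(-zs, seq_along(zs))][seq_len(k)])
    }
  }, numeric(1))
  short <- models[tabulate(match(index, models)) < k]
  if (length(short)) {
    warning(sprintf("model(s) with fewer than k=%d images: %s (summed all)",
                    k, paste(short, collapse = ", ")))
  }
  stats::setNames(out, models)
}

#' Sum per-image scores over query images
#'
#' `S_n = sum_i X_i^n` for x query images.
#'
#' @param X Matrix of per-image (rows) per-model (columns) top-k sums, or a
#'   vector for a single query image.
#' @return Named vector `S_n`.
#' @export
aggregate_scores <- function(X) {
  if (is.null(dim(X))) return(X)
  colSums(X)
}

#' Final match scores
#'
#' `T_n = (S_n - mu_S) / sigma_S` over models (population SD). If all
#' `S_n` are equal, every `T_n` is 0, with a warning.
#'
#' @param S Named vector of per-model aggregated scores (>= 2 models).
#' @param sample_sd Use sample SD instead of population SD.
#' @return Named vector `T_n`.
#' @export
final_scores <- function(S, sample_sd = FALSE) {
  if (length(S) < 2) {
    stop_shapesearch("insufficient library: need at least 2 models",
                     "shapesearch_insufficient_error")
  }
  s <- pop_sd(S, sample_sd = sample_sd)
  if (s <= 0) {
    warning("all model scores equal: T_n set to 0")
    return(stats::setNames(rep(0, length(S)), names(S)))
  }
  (S - mean(S)) / s
}

#' Search a projection library with a few query images
#'
#' (Named `search_library` to avoid masking base R's `search()`.)
#'
#' Aligns every query image against all library images, standardizes each
#' CC row to Z-scores, sums the top `k` per model and image, aggregates
#' over images, and ranks models by the final match score `T_n`
#' (descending; ties broken by model id). Query images whose CC row is
#' degenerate are dropped with a warning; the search proceeds while at
#' least one row is valid.
#'
#' @param queries An `ImageStack` (or 64 x 64 x M array) of 1-32 query
#'   images.
#' @param library A `ProjectionLibrary`.
#' @param k Top-k per model and image (default 10).
#' @param psi_step,max_shift Alignment search parameters.
#' @param sample_sd Use sample SD in the standardizations.
#' @return A `MatchReport`: list with `ranking` (data frame: rank,
#'   model_id, T_n, S_n, X_1..X_x), `zscores`, `cc`, `alignments` (best
#'   per-query-image alignment against each model's best library image),
#'   and `score_gaps` (consecutive T_n differences).
#' @export
search_library <- function(queries, library, k = 10, psi_step = 2, max_shift = 10,
                   sample_sd = FALSE) {
  qpix <- if (inherits(queries, "ImageStack")) queries$pixels else queries
  if (length(dim(qpix)) == 2) dim(qpix) <- c(dim(qpix), 1)
  x <- dim(qpix)[3]
  stopifnot(x >= 1, x <= 32)
  index <- library$stack$info$model_id
  cc <- matrix(NA_real_, x, n_images(library$stack))
  details <- vector("list", x)
  for (i in seq_len(x)) {
    det_i <- align_stack_to_reference(qpix[, , i], library$stack,
                                      psi_step = psi_step,
                                      max_shift = max_shift, details = TRUE)
    cc[i, ] <- det_i$cc
    details[[i]] <- det_i
  }
  valid <- apply(cc, 1, function(r) {
    !anyNA(r) && pop_sd(r) > 0
  })
  if (!any(valid)) {
    stop_shapesearch("no valid query rows", "shapesearch_degenerate_error")
  }
  if (!all(valid)) {
    warning(sprintf("dropping degenerate query image(s): %s",
                    paste(which(!valid), collapse = ", ")))
  }
  z <- zscore_rows(cc[valid, , drop = FALSE], sample_sd = sample_sd)
  X <- t(apply(z, 1, per_model_topk_sum, index = index, k = k))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  S <- aggregate_scores(X)
  T_n <- final_scores(S, sample_sd = sample_sd)
  models <- colnames(X) %||% unique(index)
  ord <- order(-T_n, models)
  ranking <- data.frame(rank = seq_along(models), model_id = models[ord],
                        T_n = T_n[ord], S_n = S[ord],
                        stringsAsFactors = FALSE, row.names = NULL)
  Xo <- t(X)[ord, , drop = FALSE]
  colnames(Xo) <- paste0("X_", seq_len(sum(valid)))
  ranking <- cbind(ranking, as.data.frame(Xo, row.names = FALSE))
  best_align <- lapply(seq_len(x), function(i) {
    d <- details[[i]]
    d$model_id <- index
    best <- d[order(d$model_id, -d$cc), ]
    best[!duplicated(best$model_id), ]
  })
  structure(
    list(ranking = ranking, zscores = z, cc = cc,
         alignments = best_align,
         score_gaps = c(-diff(ranking$T_n), NA_real_),
         k = k, valid_queries = which(valid)),
    class = "MatchReport"
  )
}

#' @export
print.MatchReport <- function(x, ...) {
  cat("MatchReport: top matches\n")
  print(utils::head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}

#' Write a match report as TSV and JSON
#'
#' `<path>.tsv` holds the ranked table (rank, model_id, T_n, S_n,
#' X_1..X_x); `<path>.json` adds per-image best alignments and score gaps.
#'
#' @param report A `MatchReport`.
#' @param path Output path prefix.
#' @export
write_match_report <- function(report, path) {
  utils::write.table(report$ranking, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(ranking = report$ranking, score_gaps = report$score_gaps,
         k = report$k, valid_queries = report$valid_queries,
         best_alignments = report$alignments),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
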