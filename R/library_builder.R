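# End-to-end construction of the searchable projection library:
# grid normalization -> GMM -> volume estimate -> common-volume resize ->
# refit -> pairwise superposed CC -> Ward clustering -> median-height cut ->
# medoid representatives -> projection images per representative.

#' Build a non-redundant projection library from density maps
#'
#' Each map is normalized to the standard grid, converted to a Gaussian
#' mixture, resized to the common particle volume, and refitted. Pairwise
#' superposed overlap CCs are converted to distances `sqrt(1 - CC^2)` and
#' clustered with Ward's method (ward.D); the tree is cut (default at the
#' median merge height) and the medoid of each cluster becomes a library
#' model, contributing one 64 x 64 projection image per sampled direction.
#'
#' Per-map failures are logged as warnings and the map skipped; building
#' aborts only if fewer than two maps survive.
#'
#' @param maps List of `DensityMap` objects with distinct names.
#' @param K Gaussian components per model (default 20; 40 suits large sets).
#' @param n_images Projection images per representative (default 91).
#' @param cutoff_policy `"median"` (cut at the median merge height) or
#'   `"none"` (keep every model).
#' @param seed Integer seed controlling GMM initialization and
#'   superposition starts.
#' @param n_starts Superposition starts per pair (default 12).
#' @return A `ProjectionLibrary`: list with `stack` (`ImageStack`), `gmms`
#'   (refitted mixtures of the representatives), `models`, `cc_matrix`,
#'   `tree` (`Dendrogram` over all surviving input models), and
#'   `provenance` (all parameters used).
#' @export
build_library <- function(maps, K = 20, n_images = 91,
                          cutoff_policy = c("median", "none"), seed = 1,
                          n_starts = 12) {
  cutoff_policy <- match.arg(cutoff_policy)
  stopifnot(length(maps) >= 2)
  nms <- vapply(maps, function(m) m$name, character(1))
  if (anyDuplicated(nms)) {
    stop_shapesearch("model names must be distinct", "shapesearch_domain_error")
  }
  prepared <- list()
  for (m in maps) {
    res <- tryCatch({
      norm <- normalize_grid(m)
      g0 <- fit_gmm(norm, K = K, seed = seed)
      V_old <- estimate_volume(g0)
      resized <- resize_to_common_volume(norm, V_old)
      g1 <- fit_gmm(resized, K = K, seed = seed)
      list(map = resized, gmm = g1, volume = V_old)
    }, shapesearch_error = function(e) {
      warning(sprintf("skipping model '%s': %s", m$name, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) prepared[[m$name]] <- res
  }
  if (length(prepared) < 2) {
    stop_shapesearch("fewer than 2 maps survived preparation",
                     "shapesearch_domain_error")
  }
  gmms <- lapply(prepared, function(p) p$gmm)
  if (cutoff_policy == "median") {
    cc <- pairwise_cc_matrix(unname(gmms), seed = seed, n_starts = n_starts)
    D <- cc_to_distance(cc)
    diag(D) <- 0
    tree <- ward_cluster(D)
    reps <- select_representatives(tree)
    cutoff <- stats::median(tree$height)
  } else {
    # keeping every model: the O(n^2) superposition matrix is not needed
    cc <- NULL
    tree <- NULL
    reps <- names(prepared)
    cutoff <- NA_real_
  }
  stacks <- lapply(reps, function(nm) {
    build_projection_set(prepared[[nm]]$map, n_images = n_images)
  })
  stack <- bind_stacks(stacks)
  reps <- as.character(reps)
  structure(
    list(stack = stack,
         gmms = gmms[reps],
         models = reps,
         cc_matrix = cc,
         tree = tree,
         provenance = list(
           K = K, n_images = n_images, cutoff_policy = cutoff_policy,
           cutoff = cutoff, seed = seed, n_starts = n_starts,
           image_size = IMG_SIZE, box_dim = BOX_DIM, D_ref = REF_DIM,
           pixel_size = PIXEL_SIZE,
           input_models = names(prepared),
           volumes = vapply(prepared, function(p) p$volume, numeric(1)))),
    class = "ProjectionLibrary"
  )
}

#' @export
print.ProjectionLibrary <- function(x, ...) {
  cat(sprintf(
    "ProjectionLibrary: %d models x %d images (%d total) [K=%d, cutoff=%s]\n",
    length(x$models), x$provenance$n_images, n_images(x$stack),
    x$provenance$K, x$provenance$cutoff_policy))
  invisible(x)
}

#' Persist a projection library to a directory
#'
#' Writes the image stack (`stack.mrcs` + `stack.tsv`), one mixture table
#' per model (`gmm_<model>.tsv`), the pairwise CC matrix, and
#' `provenance.json`.
#'
#' @param library A `ProjectionLibrary`.
#' @param dir Output directory (created if needed).
#' @export
save_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image_stack(library$stack, file.path(dir, "stack"))
  for (nm in names(library$gmms)) {
    write_gmm(library$gmms[[nm]], file.path(dir, paste0("gmm_", nm, ".tsv")))
  }
  if (!is.null(library$cc_matrix)) {
    utils::write.table(
      data.frame(model = rownames(library$cc_matrix), library$cc_matrix,
                 check.names = FALSE),
      file.path(dir, "cc_matrix.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  prov <- library$provenance
  prov$models <- library$models
  if (!is.null(library$tree)) {
    prov$tree <- list(merge = library$tree$merge,
                      height = library$tree$height,
                      labels = library$tree$labels)
  }
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a projection library saved by [save_library()]
#' @param dir Library directory.
#' @return A `ProjectionLibrary` (the full input dendrogram's distance
#'   matrix is restored from the CC matrix).
#' @export
load_library <- function(dir) {
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  stack <- read_image_stack(file.path(dir, "stack"))
  models <- prov$models
  gmms <- lapply(models, function(nm) {
    read_gmm(file.path(dir, paste0("gmm_", nm, ".tsv")))
  })
  names(gmms) <- models
  cc <- NULL
  tree <- NULL
  if (file.exists(file.path(dir, "cc_matrix.tsv"))) {
    cc_tab <- utils::read.table(file.path(dir, "cc_matrix.tsv"), sep = "\t",
                                header = TRUE, check.names = FALSE)
    cc <- as.matrix(cc_tab[, -1])
    rownames(cc) <- cc_tab$model
  }
  if (!is.null(prov$tree)) {
    tree <- structure(
      list(merge = matrix(unlist(prov$tree$merge), ncol = 2),
           height = prov$tree$height, labels = prov$tree$labels,
           dist = cc_to_distance(cc)),
      class = "Dendrogram")
  }
  prov$models <- NULL
  prov$tree <- NULL
  structure(
    list(stack = stack, gmms = gmms, models = models, cc_matrix = cc,
         tree = tree, provenance = prov),
    class = "ProjectionLibrary")
}
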