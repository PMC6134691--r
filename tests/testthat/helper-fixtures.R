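# Shared fixtures. Everything is generated in code; the expensive
# 20-model acceptance library is built once per test run and cached.
#
# Acceptance-scale parameters (stated once, scaled down from the full
# production settings of 91 images / 20-40 components to fit a 1-CPU test
# budget; the retrieval criteria explicitly allow a reduced library). The
# 20 library models are the curated, pairwise-distinct shape set -- the
# synthetic analog of a redundancy-reduced library (see the methods
# vignette); view density is halved from 91, not more, because the top-10
# scoring presumes an adequate own-view neighborhood per model.
ACC_SEED <- 101
ACC_N_IMAGES <- 48   # projections per model (production default: 91)
ACC_K <- 6           # Gaussian components (production default: 20/40)
ACC_N_STARTS <- 6    # superposition starts (production default: 24)
ACC_PSI_STEP <- 6    # degrees (production default: 2)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small single-shape maps reused across files
fix_map <- function(kind, ...) {
  key <- paste0("map_", kind, "_", paste(unlist(list(...)), collapse = "_"))
  cached(key, make_density(shape_spec(kind, ...)))
}

fix_projection <- function(kind, dir = c(0.5, 0.3, 0.81)) {
  key <- paste0("proj_", kind, "_", paste(signif(dir, 3), collapse = "_"))
  cached(key, unclass(project_map(fix_map(kind), dir)))
}

# the reduced 20-model acceptance library (no dedup: the curated set is
# non-redundant by construction and self-retrieval needs every model)
acceptance_fixture <- function() {
  cached("acc_lib", {
    specs <- distinct_shape_specs(seed = ACC_SEED)
    maps <- lapply(specs, make_density)
    lib <- suppressWarnings(
      build_library(maps, K = ACC_K, n_images = ACC_N_IMAGES,
                    cutoff_policy = "none", seed = ACC_SEED,
                    n_starts = ACC_N_STARTS))
    list(lib = lib, specs = specs)
  })
}
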