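# Shared synthetic fixtures, generated in code. The tiny lattice keeps unit
# tests fast; acceptance tests use the full 80x30x60 lattice.

tiny_grid <- c(24L, 22L, 22L)

tiny_spec <- function(n_areas = 4L, rng_seed = 1L, noise = noise_spec(),
                      gene_specs = list(), layout = NULL) {
  synthetic_spec(grid_shape = tiny_grid, shell_inner_radius = 4,
                 shell_thickness = 3, n_areas = n_areas,
                 area_seed_layout = layout, gene_specs = gene_specs,
                 noise = noise, rng_seed = rng_seed)
}

# A noiseless 4-area study with one planted marker per area plus filler
# genes; memoized because several test files reuse it.
.fixture_env <- new.env(parent = emptyenv())

tiny_clean_study <- function() {
  if (is.null(.fixture_env$clean)) {
    spec <- tiny_spec(rng_seed = 42L)
    ann <- generate_annotation(spec)
    panel <- c(
      default_gene_panel(ann$area_ids, n_genes = 10L, noise_sd = 0,
                         n_gradient = 2L))
    spec$gene_specs <- panel
    .fixture_env$clean <- generate_study(spec)
  }
  .fixture_env$clean
}

tiny_mapping <- function(kind = "flatmap") {
  key <- paste0("map_", kind)
  if (is.null(.fixture_env[[key]])) {
    st <- tiny_clean_study()
    cm <- cortex_mask(st$annotation, st$tree)
    .fixture_env[[key]] <- build_surface_mapping(cm, kind)
  }
  .fixture_env[[key]]
}

tiny_projections <- function(kind = "flatmap") {
  key <- paste0("proj_", kind)
  if (is.null(.fixture_env[[key]])) {
    st <- tiny_clean_study()
    cm <- cortex_mask(st$annotation, st$tree)
    map <- tiny_mapping(kind)
    .fixture_env[[key]] <- lapply(st$volumes, function(v)
      project_volume(mask_volume(v, cm), map))
  }
  .fixture_env[[key]]
}

tiny_area_masks <- function(kind = "flatmap") {
  key <- paste0("am_", kind)
  if (is.null(.fixture_env[[key]])) {
    st <- tiny_clean_study()
    map <- tiny_mapping(kind)
    am <- lapply(st$area_ids, function(a)
      project_area_mask(area_mask(st$annotation, st$tree, a), map,
                        area_id = a))
    names(am) <- st$area_ids
    .fixture_env[[key]] <- am
  }
  .fixture_env[[key]]
}

# Hand-built structure tree with a two-level area hierarchy, for
# mask-derivation tests: cortex(2) > {parent 10 > {11, 12}, leaf 13}.
nested_tree <- function() {
  structure_tree(data.frame(
    id = c(1L, 2L, 3L, 10L, 11L, 12L, 13L),
    name = c("brain", "cortex", "sub", "parent", "kidA", "kidB", "leaf"),
    parent_id = c(NA, 1L, 1L, 2L, 10L, 10L, 2L)),
    cortex_root_id = 2L)
}

random_nested_annotation <- function(seed = 1L, d = c(6L, 5L, 4L)) {
  set.seed(seed)
  annotation_volume(array(sample(c(0L, 3L, 11L, 12L, 13L), prod(d),
                                 replace = TRUE), dim = d))
}
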