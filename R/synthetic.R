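#' Specification of a synthetic cortical atlas
#'
#' The generator builds a cylindrical cortical shell (an annulus in each
#' coronal section, extruded along the anterior-posterior axis) embedded in a
#' subcortical disc, subdivides the shell into contiguous cortical areas
#' (angular x AP sectors), and renders one expression volume per gene with
#' additive Gaussian noise, per-section multiplicative banding and zeroed
#' (missing) coronal sections. Coronal sections are planes perpendicular to
#' the AP axis, so banding and missing data are whole-plane effects, as in
#' real section-based ISH data.
#'
#' @param grid_shape Integer vector (AP, DV, ML) of voxel counts.
#' @param shell_inner_radius Inner radius of the cortical annulus, voxels.
#' @param shell_thickness Radial thickness of the annulus, voxels (>= 2).
#' @param n_areas Number of cortical areas (>= 2 for a real screen; 1 is
#'   allowed for degenerate tests).
#' @param area_seed_layout Optional data.frame with columns `theta_lo`,
#'   `theta_hi` (radians in (-pi, pi], 0 = dorsal midline), `ap_lo`, `ap_hi`
#'   (fractions of the AP extent). Default: `n_areas` equal angular sectors
#'   spanning the full ring and full AP extent (see [sector_layout()]).
#' @param gene_specs List of [gene_spec()] objects.
#' @param noise A [noise_spec()].
#' @param rng_seed Integer seed governing all randomness of the study.
#' @param voxel_size_um Nominal voxel size (metadata only).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid_shape = c(80L, 30L, 60L),
                           shell_inner_radius = 8,
                           shell_thickness = 6,
                           n_areas = 4L,
                           area_seed_layout = NULL,
                           gene_specs = list(),
                           noise = noise_spec(),
                           rng_seed = 1L,
                           voxel_size_um = 200) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  if (shell_thickness < 2) stop("shell_thickness must be >= 2 voxels")
  if (n_areas < 1L) stop("n_areas must be >= 1")
  outer <- shell_inner_radius + shell_thickness
  # the annulus must fit inside the DV x ML cross-section with 1 voxel of
  # background margin so the exterior is identifiable
  if (2 * outer + 2 > grid_shape[2] || 2 * outer + 2 > grid_shape[3])
    stop("grid too small for shell: need > ", 2 * outer + 2,
         " voxels in DV and ML, have ", grid_shape[2], "x", grid_shape[3])
  if (is.null(area_seed_layout)) area_seed_layout <- sector_layout(n_areas)
  stopifnot(nrow(area_seed_layout) == n_areas)
  structure(list(grid_shape = grid_shape,
                 shell_inner_radius = shell_inner_radius,
                 shell_thickness = shell_thickness,
                 n_areas = as.integer(n_areas),
                 area_seed_layout = area_seed_layout,
                 gene_specs = gene_specs,
                 noise = noise,
                 rng_seed = as.integer(rng_seed),
                 voxel_size_um = voxel_size_um),
            class = "synthetic_spec")
}

#' Equal angular sectors for the synthetic area layout
#'
#' @param n_theta Number of angular sectors around the ring.
#' @param n_ap Number of AP blocks (areas = n_theta x n_ap sectors).
#' @return Layout data.frame accepted by [synthetic_spec()].
#' @export
sector_layout <- function(n_theta, n_ap = 1L) {
  th <- seq(-pi, pi, length.out = n_theta + 1L)
  ap <- seq(0, 1, length.out = n_ap + 1L)
  g <- expand.grid(it = seq_len(n_theta), ia = seq_len(n_ap))
  data.frame(theta_lo = th[g$it], theta_hi = th[g$it + 1L],
             ap_lo = ap[g$ia], ap_hi = ap[g$ia + 1L])
}

#' Per-gene generator specification
#'
#' @param gene_id Gene identifier.
#' @param kind One of `"border_marker"` (abrupt expression step at the
#'   borders of `target_area`), `"gradient"` (smooth linear ramp along an
#'   axis), `"uniform"` (flat expression) or `"noise_only"`.
#' @param target_area Area id marked by a border marker.
#' @param inside_level,outside_level Marker expression inside / outside the
#'   target area (must differ; both in \[0, 1\]).
#' @param axis Gradient axis: `"ap"`, `"dv"` or `"ml"`.
#' @param low,high Gradient end levels in \[0, 1\].
#' @param level Uniform expression level in \[0, 1\].
#' @param noise_sd Per-voxel additive Gaussian noise standard deviation.
#' @param hemisphere For border markers: `"both"` (default), `"left"` or
#'   `"right"` restricts the elevated expression to one hemisphere
#'   (ML below/above the grid midline), emulating hemisphere-asymmetric
#'   genes.
#' @return An object of class `gene_spec`.
#' @export
gene_spec <- function(gene_id,
                      kind = c("border_marker", "gradient", "uniform",
                               "noise_only"),
                      target_area = NULL,
                      inside_level = 0.9, outside_level = 0.1,
                      axis = c("ap", "dv", "ml"),
                      low = 0, high = 1,
                      level = 0.5,
                      noise_sd = 0,
                      hemisphere = c("both", "left", "right")) {
  kind <- match.arg(kind)
  hemisphere <- match.arg(hemisphere)
  chk01 <- function(x, nm) if (x < 0 || x > 1) stop(nm, " must be in [0, 1]")
  if (kind == "border_marker") {
    if (is.null(target_area)) stop("border_marker requires target_area")
    chk01(inside_level, "inside_level"); chk01(outside_level, "outside_level")
    if (inside_level == outside_level)
      stop("inside_level and outside_level must differ")
  }
  if (kind == "gradient") { chk01(low, "low"); chk01(high, "high") }
  if (kind == "uniform") chk01(level, "level")
  structure(list(gene_id = as.character(gene_id), kind = kind,
                 target_area = if (is.null(target_area)) NA_integer_
                               else as.integer(target_area),
                 inside_level = inside_level, outside_level = outside_level,
                 axis = match.arg(axis), low = low, high = high,
                 level = level, noise_sd = noise_sd,
                 hemisphere = hemisphere),
            class = "gene_spec")
}

#' Section-level noise model
#'
#' @param missing_band_probability Per-coronal-section probability that the
#'   whole section is zeroed (missing data).
#' @param banding_factor_range Interval for the per-section multiplicative
#'   luminance factor (section-to-section banding).
#' @param background_level Subcortical expression level.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(missing_band_probability = 0,
                       banding_factor_range = c(1, 1),
                       background_level = 0) {
  if (missing_band_probability < 0 || missing_band_probability > 1)
    stop("missing_band_probability must be in [0, 1]")
  if (any(banding_factor_range <= 0))
    stop("banding factors must be positive")
  stopifnot(length(banding_factor_range) == 2L,
            diff(banding_factor_range) >= 0)
  structure(list(missing_band_probability = missing_band_probability,
                 banding_factor_range = banding_factor_range,
                 background_level = background_level),
            class = "noise_spec")
}

# Shared geometry of the synthetic shell: per-voxel radius and angle in the
# coronal (DV, ML) plane. theta = 0 at the dorsal midline (minimal DV),
# increasing towards positive ML ("right"), range (-pi, pi].
.shell_geometry <- function(grid_shape) {
  d <- grid_shape
  c_dv <- (d[2] + 1) / 2
  c_ml <- (d[3] + 1) / 2
  dv <- rep(seq_len(d[2]) - c_dv, each = d[1])
  dv <- rep(dv, times = d[3])
  ml <- rep(seq_len(d[3]) - c_ml, each = d[1] * d[2])
  r <- sqrt(dv^2 + ml^2)
  theta <- atan2(ml, -dv)
  ap <- rep(seq_len(d[1]), times = d[2] * d[3])
  list(r = r, theta = theta, ap = ap, c_dv = c_dv, c_ml = c_ml)
}

#' Generate the synthetic annotation volume and structure tree
#'
#' The cortical shell is the annulus `inner <= r < inner + thickness` in each
#' coronal section; the interior disc is one subcortical structure; the rest
#' is background (label 0). Shell voxels are assigned to `n_areas` contiguous
#' angular x AP sectors whose ids are children of a single cortex node.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `annotation` ([annotation_volume()]),
#'   `tree` ([structure_tree()]) and `area_ids` (integer vector, one id per
#'   layout row).
#' @export
generate_annotation <- function(spec) {
  d <- spec$grid_shape
  geo <- .shell_geometry(d)
  inner <- spec$shell_inner_radius
  outer <- inner + spec$shell_thickness
  lab <- integer(prod(d))
  lab[geo$r < inner] <- 3L                       # subcortical disc
  shell <- geo$r >= inner & geo$r < outer
  layout <- spec$area_seed_layout
  area_ids <- 100L + seq_len(nrow(layout))
  ap_fr <- (geo$ap - 0.5) / d[1]
  for (k in seq_len(nrow(layout))) {
    # half-open sectors; the last sector in each dimension closes the range
    in_th <- geo$theta >= layout$theta_lo[k] &
      (geo$theta < layout$theta_hi[k] |
         (layout$theta_hi[k] >= pi - 1e-12 & geo$theta <= pi))
    in_ap <- ap_fr >= layout$ap_lo[k] &
      (ap_fr < layout$ap_hi[k] |
         (layout$ap_hi[k] >= 1 - 1e-12 & ap_fr <= 1))
    lab[shell & in_th & in_ap] <- area_ids[k]
  }
  if (any(shell & lab == 0L))
    stop("area layout does not cover the shell")
  nodes <- data.frame(
    id = c(1L, 2L, 3L, area_ids),
    name = c("brain", "cortex", "subcortical",
             paste0("AREA", seq_along(area_ids))),
    parent_id = c(NA_integer_, 1L, 1L, rep(2L, length(area_ids))))
  list(annotation = annotation_volume(array(lab, dim = d)),
       tree = structure_tree(nodes, cortex_root_id = 2L),
       area_ids = area_ids)
}

#' Render one synthetic gene volume
#'
#' Deterministic given `rng_seed`. Pipeline: deterministic expression
#' pattern, then per-voxel additive Gaussian noise (brain voxels), then one
#' multiplicative banding factor per coronal section drawn uniformly from
#' `noise$banding_factor_range`, then whole coronal sections zeroed with
#' probability `noise$missing_band_probability`, then clipping to \[0, 1\].
#'
#' @param gene A [gene_spec()].
#' @param annotation An [annotation_volume()] from [generate_annotation()].
#' @param noise A [noise_spec()].
#' @param rng_seed Integer seed.
#' @param voxel_size_um Metadata.
#' @return An [expression_volume()].
#' @export
generate_gene_volume <- function(gene, annotation, noise = noise_spec(),
                                 rng_seed = 1L, voxel_size_um = 200) {
  lab <- annotation$labels
  d <- dim(lab)
  geo <- .shell_geometry(d)
  brain <- as.vector(lab) > 0L
  shell <- as.vector(lab) > 3L
  v <- numeric(prod(d))
  v[as.vector(lab) == 3L] <- noise$background_level
  if (gene$kind == "uniform") {
    v[shell] <- gene$level
  } else if (gene$kind == "gradient") {
    ax <- match(gene$axis, c("ap", "dv", "ml"))
    coord <- switch(gene$axis,
      ap = rep(seq_len(d[1]), times = d[2] * d[3]),
      dv = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      ml = rep(seq_len(d[3]), each = d[1] * d[2]))
    fr <- (coord - 1) / max(d[ax] - 1L, 1L)
    v[shell] <- gene$low + (gene$high - gene$low) * fr[shell]
  } else if (gene$kind == "border_marker") {
    if (!any(lab == gene$target_area))
      stop("unknown target_area: ", gene$target_area)
    inside <- as.vector(lab) == gene$target_area
    if (gene$hemisphere == "left")  inside <- inside & geo$theta < 0
    if (gene$hemisphere == "right") inside <- inside & geo$theta >= 0
    v[shell] <- gene$outside_level
    v[inside] <- gene$inside_level
  }                                              # noise_only: zeros
  set.seed(rng_seed)
  if (gene$noise_sd > 0)
    v[brain] <- v[brain] + stats::rnorm(sum(brain), sd = gene$noise_sd)
  band <- stats::runif(d[1], noise$banding_factor_range[1],
                       noise$banding_factor_range[2])
  missing <- stats::runif(d[1]) < noise$missing_band_probability
  ap <- geo$ap
  v <- v * band[ap]
  v[missing[ap]] <- 0
  v <- pmin(1, pmax(0, v))
  expression_volume(array(v, dim = d), gene$gene_id, voxel_size_um)
}

#' Generate a full synthetic study
#'
#' Renders the annotation plus one expression volume per [gene_spec()], with
#' per-gene seeds derived deterministically from `spec$rng_seed`, and a
#' ground-truth map of planted border markers for parameter-recovery tests.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `volumes` (named list of [expression_volume()]),
#'   `annotation`, `tree`, `area_ids` and `truth` (data.frame `gene_id`,
#'   `kind`, `target_area`; one row per planted border marker).
#' @export
generate_study <- function(spec) {
  ann <- generate_annotation(spec)
  n <- length(spec$gene_specs)
  set.seed(spec$rng_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  volumes <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    g <- spec$gene_specs[[i]]
    volumes[[i]] <- generate_gene_volume(g, ann$annotation, spec$noise,
                                         rng_seed = seeds[i],
                                         voxel_size_um = spec$voxel_size_um)
    ids[i] <- g$gene_id
  }
  names(volumes) <- ids
  markers <- Filter(function(g) g$kind == "border_marker", spec$gene_specs)
  truth <- data.frame(
    gene_id = vapply(markers, `[[`, character(1), "gene_id"),
    kind = vapply(markers, `[[`, character(1), "kind"),
    target_area = vapply(markers, `[[`, integer(1), "target_area"),
    stringsAsFactors = FALSE)
  list(volumes = volumes, annotation = ann$annotation, tree = ann$tree,
       area_ids = ann$area_ids, truth = truth)
}

#' Stock gene panel for synthetic screens
#'
#' One planted border marker per area (step `inside_level` ->
#' `outside_level`), a few smooth gradients, and uniform / noise-only
#' filler genes up to `n_genes`.
#'
#' @param area_ids Integer area ids to mark.
#' @param n_genes Total panel size.
#' @param inside_level,outside_level Marker step levels.
#' @param noise_sd Additive noise for every gene.
#' @param n_gradient Number of gradient genes.
#' @return List of [gene_spec()] objects.
#' @export
default_gene_panel <- function(area_ids, n_genes = 50L,
                               inside_level = 0.9, outside_level = 0.1,
                               noise_sd = 0.05, n_gradient = 6L) {
  n_areas <- length(area_ids)
  if (n_genes < n_areas + n_gradient)
    stop("n_genes too small for the panel composition")
  specs <- list()
  for (i in seq_len(n_areas))
    specs[[length(specs) + 1L]] <- gene_spec(
      sprintf("marker_%03d", area_ids[i]), "border_marker",
      target_area = area_ids[i], inside_level = inside_level,
      outside_level = outside_level, noise_sd = noise_sd)
  axes <- rep(c("ap", "ml", "dv"), length.out = n_gradient)
  for (i in seq_len(n_gradient))
    specs[[length(specs) + 1L]] <- gene_spec(
      sprintf("gradient_%02d", i), "gradient", axis = axes[i],
      low = 0.1, high = 0.9, noise_sd = noise_sd)
  n_fill <- n_genes - length(specs)
  levels <- rep(c(0.2, 0.4, 0.6, 0.8), length.out = n_fill)
  for (i in seq_len(n_fill)) {
    if (i %% 2L == 0L)
      specs[[length(specs) + 1L]] <- gene_spec(
        sprintf("uniform_%02d", i), "uniform", level = levels[i],
        noise_sd = noise_sd)
    else
      specs[[length(specs) + 1L]] <- gene_spec(
        sprintf("noise_%02d", i), "noise_only", noise_sd = max(noise_sd, 0.05))
  }
  specs
}
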