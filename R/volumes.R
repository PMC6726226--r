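#' Per-gene expression volume
#'
#' A 3D grid of luminance values in \[0, 1\] on the shared voxel lattice.
#' Axis order is (AP, DV, ML): anterior-posterior, dorsal-ventral,
#' medial-lateral, 1-based R indexing. All volumes of a study share one
#' lattice; the nominal voxel size (default 200 micrometres) is metadata
#' only.
#'
#' @param values Numeric 3D array with values in \[0, 1\].
#' @param gene_id Gene identifier string.
#' @param voxel_size_um Nominal isotropic voxel size in micrometres.
#' @return An object of class `expression_volume`.
#' @export
expression_volume <- function(values, gene_id, voxel_size_um = 200) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (anyNA(values) || min(values) < 0 || max(values) > 1)
    stop("expression values must be finite and in [0, 1]")
  structure(list(gene_id = as.character(gene_id), values = values,
                 voxel_size_um = voxel_size_um),
            class = "expression_volume")
}

#' @export
print.expression_volume <- function(x, ...) {
  cat("<expression_volume> gene ", x$gene_id, ", ",
      paste(dim(x$values), collapse = "x"), " voxels @ ",
      x$voxel_size_um, " um\n", sep = "")
  invisible(x)
}

#' Annotation volume of structure labels
#'
#' @param labels Integer 3D array of non-negative structure ids; 0 is
#'   background.
#' @return An object of class `annotation_volume`.
#' @export
annotation_volume <- function(labels) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || min(labels) < 0L)
    stop("annotation labels must be non-negative integers")
  structure(list(labels = labels), class = "annotation_volume")
}

#' @export
print.annotation_volume <- function(x, ...) {
  cat("<annotation_volume> ", paste(dim(x$labels), collapse = "x"),
      " voxels, ", length(setdiff(unique(as.vector(x$labels)), 0L)),
      " labels\n", sep = "")
  invisible(x)
}

.vol_values <- function(x) {
  if (inherits(x, "expression_volume")) x$values
  else if (inherits(x, "annotation_volume")) x$labels
  else x
}

#' Binary cortex mask from an annotation volume
#'
#' A voxel belongs to cortex iff its label is the cortex root of the
#' structure tree or one of the root's descendants.
#'
#' @param annotation An [annotation_volume()].
#' @param tree A [structure_tree()].
#' @return Logical 3D array on the annotation lattice.
#' @export
cortex_mask <- function(annotation, tree) {
  ids <- tree_descendants(tree, tree$cortex_root_id)
  m <- array(annotation$labels %in% ids, dim = dim(annotation$labels))
  m
}

#' Binary 3D mask of one cortical area
#'
#' A voxel belongs to the area iff its label equals `area_id` or a descendant
#' of it (for leaf areas this is an exact label match). An area id that is
#' valid in the tree but absent from the volume yields an all-zero mask with
#' a warning.
#'
#' @param annotation An [annotation_volume()].
#' @param tree A [structure_tree()].
#' @param area_id Structure id of the area.
#' @return Logical 3D array.
#' @export
area_mask <- function(annotation, tree, area_id) {
  ids <- tree_descendants(tree, area_id)
  m <- array(annotation$labels %in% ids, dim = dim(annotation$labels))
  if (!any(m))
    warning("area ", area_id, " has no voxels in the annotation volume")
  m
}

#' Apply a binary mask to an expression volume
#'
#' Elementwise product: values outside the mask become exactly 0. Masking is
#' idempotent for binary masks.
#'
#' @param volume An [expression_volume()].
#' @param mask Logical (or 0/1 numeric) array of the same dimensions.
#' @return A masked [expression_volume()].
#' @export
mask_volume <- function(volume, mask) {
  vals <- volume$values
  if (!identical(dim(vals), dim(mask)))
    stop("mask dimensions ", paste(dim(mask), collapse = "x"),
         " do not match volume ", paste(dim(vals), collapse = "x"))
  out <- vals * as.numeric(mask)
  dim(out) <- dim(vals)
  expression_volume(out, volume$gene_id, volume$voxel_size_um)
}

#' Read / write an expression volume as NRRD
#'
#' The gene id is taken from (stored in) the file name, `<gene_id>.nrrd`.
#'
#' @param volume An [expression_volume()].
#' @param path File path.
#' @param gene_id Gene id override for the reader; defaults to the file
#'   base name.
#' @param encoding Passed to [write_nrrd()].
#' @return The reader returns an [expression_volume()].
#' @export
write_expression_volume <- function(volume, path, encoding = "raw") {
  write_nrrd(volume$values, path, encoding = encoding)
}

#' @rdname write_expression_volume
#' @export
read_expression_volume <- function(path, gene_id = NULL) {
  if (is.null(gene_id))
    gene_id <- sub("\\.nrrd$", "", basename(path))
  expression_volume(read_nrrd(path), gene_id)
}

#' Read / write an annotation volume as NRRD
#' @param annotation An [annotation_volume()].
#' @param path File path.
#' @return The reader returns an [annotation_volume()].
#' @export
write_annotation_volume <- function(annotation, path) {
  write_nrrd(annotation$labels, path, encoding = "raw")
}

#' @rdname write_annotation_volume
#' @export
read_annotation_volume <- function(path) {
  annotation_volume(read_nrrd(path))
}
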