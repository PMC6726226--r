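#' @useDynLib cortexscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Exterior background component of a 3D logical mask: complement voxels
# 6-connected to the grid corner (1,1,1). Distinguishes the outside world
# from cavities enclosed by the mask. Vectorized frontier BFS.
.flood_exterior <- function(mask) {
  d <- dim(mask)
  if (mask[1, 1, 1]) stop("mask touches the grid corner; no identifiable exterior")
  comp <- !mask
  visited <- array(FALSE, dim = d)
  visited[1, 1, 1] <- TRUE
  frontier <- 1L
  n12 <- d[1] * d[2]
  while (length(frontier)) {
    co <- arrayInd(frontier, d)
    nb <- c(frontier[co[, 1] > 1L] - 1L,
            frontier[co[, 1] < d[1]] + 1L,
            frontier[co[, 2] > 1L] - d[1],
            frontier[co[, 2] < d[2]] + d[1],
            frontier[co[, 3] > 1L] - n12,
            frontier[co[, 3] < d[3]] + n12)
    nb <- unique(nb[comp[nb] & !visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

# Logical array of mask voxels with at least one 6-neighbour in `where`.
.adjacent_to <- function(mask, where) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  shift_any <- function(w) {
    s <- array(FALSE, dim = d)
    s[2:d[1], , ] <- s[2:d[1], , ] | w[1:(d[1] - 1L), , ]
    s[1:(d[1] - 1L), , ] <- s[1:(d[1] - 1L), , ] | w[2:d[1], , ]
    s[, 2:d[2], ] <- s[, 2:d[2], ] | w[, 1:(d[2] - 1L), ]
    s[, 1:(d[2] - 1L), ] <- s[, 1:(d[2] - 1L), ] | w[, 2:d[2], ]
    s[, , 2:d[3]] <- s[, , 2:d[3]] | w[, , 1:(d[3] - 1L)]
    s[, , 1:(d[3] - 1L)] <- s[, , 1:(d[3] - 1L)] | w[, , 2:d[3]]
    s
  }
  mask & shift_any(where)
}

#' Build the pixel-to-column mapping from a cortex mask
#'
#' Identifies the pial (outer) surface of the cortical shell, estimates the
#' inward surface normal at every surface voxel from the gradient of the
#' Euclidean distance transform to the mask exterior, and traces a straight
#' unit-step path inward (nearest-voxel sampling) until it leaves the mask.
#' Each path is then assigned to one 2D output pixel:
#'
#' * `kind = "top"`: the pixel at the surface voxel's horizontal (AP, ML)
#'   coordinates; where several surface voxels share a horizontal position,
#'   the shallowest (most dorsal) one wins, mimicking a view from above.
#' * `kind = "flatmap"`: row = AP section index, column = signed arc length
#'   along the pial contour of that coronal section, measured from the
#'   dorsal midline and quantized to pixels.
#'
#' The mapping depends only on the mask, never on expression data, so one
#' mapping is shared by every gene and by the area masks.
#'
#' @param cortex_mask Logical 3D array (a shell with an identifiable outer
#'   surface that does not touch the grid corner).
#' @param kind `"top"` or `"flatmap"`.
#' @return An object of class `surface_mapping`: list with `kind`, `dims3`,
#'   `dims2`, `valid` (2D logical), `pixel_index` (per-path linear index
#'   into the 2D grid), `path_matrix` (paths as rows of linear voxel
#'   indices, NA-padded, surface first), `surface_voxel` (linear 3D index)
#'   and `midline_col`.
#' @export
build_surface_mapping <- function(cortex_mask, kind = c("top", "flatmap")) {
  kind <- match.arg(kind)
  d <- dim(cortex_mask)
  stopifnot(length(d) == 3L)
  if (!any(cortex_mask)) stop("empty cortex mask: no surface to map")
  ext <- .flood_exterior(cortex_mask)
  surf <- .adjacent_to(cortex_mask, ext)
  if (!any(surf)) stop("cortex mask has no outer surface adjacent to the exterior")
  Dt <- sqrt(.edt_sq_3d(as.vector(cortex_mask), as.integer(d)))
  dim(Dt) <- d

  sv <- which(surf)
  co <- arrayInd(sv, d)
  grad <- matrix(0, nrow = length(sv), ncol = 3L)
  for (a in 1:3) {
    up <- co; up[, a] <- pmin(up[, a] + 1L, d[a])
    dn <- co; dn[, a] <- pmax(dn[, a] - 1L, 1L)
    grad[, a] <- (Dt[up] - Dt[dn]) / 2
  }
  nrm <- sqrt(rowSums(grad^2))
  ok <- nrm > 1e-8
  grad[ok, ] <- grad[ok, , drop = FALSE] / nrm[ok]
  grad[!ok, ] <- 0                        # degenerate: path = surface voxel only

  # trace all paths simultaneously; stop permanently once a path exits
  max_steps <- sum(d)
  n <- length(sv)
  path_cols <- list()
  alive <- rep(TRUE, n)
  pos0 <- co
  prev_idx <- rep(NA_integer_, n)
  for (t in 0:max_steps) {
    if (!any(alive)) break
    p <- pos0 + t * grad
    v <- round(p)
    inside <- alive &
      v[, 1] >= 1 & v[, 1] <= d[1] &
      v[, 2] >= 1 & v[, 2] <= d[2] &
      v[, 3] >= 1 & v[, 3] <= d[3]
    idx <- rep(NA_integer_, n)
    w <- which(inside)
    if (length(w)) {
      li <- v[w, 1] + d[1] * (v[w, 2] - 1) + d[1] * d[2] * (v[w, 3] - 1)
      li <- as.integer(li)
      keep <- cortex_mask[li]
      idx[w[keep]] <- li[keep]
    }
    alive <- alive & !is.na(idx)
    idx[!alive] <- NA_integer_
    dup <- !is.na(idx) & !is.na(prev_idx) & idx == prev_idx
    store <- idx
    store[dup] <- NA_integer_
    path_cols[[length(path_cols) + 1L]] <- store
    prev_idx[!is.na(idx)] <- idx[!is.na(idx)]
    if (t > 0 && all(is.na(store))) break
  }
  pm <- do.call(cbind, path_cols)
  if (ncol(pm) > 1L) {
    # left-compact each row so paths are contiguous
    nc <- ncol(pm)
    pm <- t(vapply(seq_len(nrow(pm)), function(i) {
      r <- pm[i, ]
      r <- r[!is.na(r)]
      c(r, rep(NA_integer_, nc - length(r)))
    }, integer(nc)))
    pm <- pm[, colSums(!is.na(pm)) > 0L, drop = FALSE]
  }

  if (kind == "top") {
    rowpix <- co[, 1]
    colpix <- co[, 3]
    depth <- co[, 2]
    dims2 <- c(d[1], d[3])
    # dorsal ridge per AP row defines the midline column
    ridge <- tapply(seq_len(n), rowpix, function(ii) colpix[ii][which.min(depth[ii])])
    midline_col <- as.integer(round(stats::median(unlist(ridge))))
    pref <- depth                       # smaller = shallower wins
  } else {
    arc <- rep(NA_real_, n)
    for (apx in sort(unique(co[, 1]))) {
      ii <- which(co[, 1] == apx)
      slice_mask <- cortex_mask[apx, , ]
      cen_dv <- mean(row(slice_mask)[slice_mask])
      cen_ml <- mean(col(slice_mask)[slice_mask])
      dv <- co[ii, 2]; ml <- co[ii, 3]
      th <- atan2(ml - cen_ml, -(dv - cen_dv))
      anchor <- ii[order(dv, abs(ml - cen_ml), ml)][1L]
      th0 <- atan2(co[anchor, 3] - cen_ml, -(co[anchor, 2] - cen_dv))
      thr <- (th - th0 + pi) %% (2 * pi) - pi
      o <- order(thr)
      dvo <- dv[o]; mlo <- ml[o]
      step <- sqrt(diff(dvo)^2 + diff(mlo)^2)
      s <- c(0, cumsum(step))
      a0 <- s[which(ii[o] == anchor)]
      arc[ii[o]] <- s - a0
    }
    colq <- as.integer(round(arc))
    offset <- 1L - min(colq)
    rowpix <- co[, 1]
    colpix <- colq + offset
    dims2 <- c(d[1], max(colpix))
    midline_col <- offset               # column of arc length 0
    pref <- abs(arc - round(arc))       # closest-to-grid wins collisions
  }

  key <- rowpix + dims2[1] * (colpix - 1L)
  o <- order(key, pref)
  first <- !duplicated(key[o])
  keep <- o[first]
  valid <- array(FALSE, dim = dims2)
  valid[key[keep]] <- TRUE
  structure(list(kind = kind, dims3 = d, dims2 = dims2,
                 valid = valid,
                 pixel_index = as.integer(key[keep]),
                 path_matrix = pm[keep, , drop = FALSE],
                 surface_voxel = sv[keep],
                 midline_col = midline_col),
            class = "surface_mapping")
}

#' @export
print.surface_mapping <- function(x, ...) {
  cat("<surface_mapping> ", x$kind, ", ",
      paste(x$dims2, collapse = "x"), " pixels (",
      sum(x$valid), " valid), lattice ",
      paste(x$dims3, collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Maximum-intensity surface projection of a masked volume
#'
#' Each valid output pixel is the maximum of the volume values along its
#' projection path (cortical column); pixels with no path carry the `NA`
#' sentinel, which is distinct from a measured 0 (missing data).
#'
#' @param volume An [expression_volume()] (already cortex-masked) or a 3D
#'   numeric array.
#' @param mapping A [build_surface_mapping()] result on the same lattice.
#' @return An object of class `surface_projection`: list with `kind`,
#'   `values` (2D matrix, `NA` = invalid), `valid`, `gene_id`.
#' @export
project_volume <- function(volume, mapping) {
  v <- .vol_values(volume)
  if (!identical(dim(v), mapping$dims3))
    stop("volume lattice ", paste(dim(v), collapse = "x"),
         " does not match mapping lattice ",
         paste(mapping$dims3, collapse = "x"))
  pm <- mapping$path_matrix
  vals <- matrix(v[pm], nrow = nrow(pm))
  vals[is.na(pm)] <- -Inf
  px <- do.call(pmax, lapply(seq_len(ncol(vals)), function(j) vals[, j]))
  out <- matrix(NA_real_, mapping$dims2[1], mapping$dims2[2])
  out[mapping$pixel_index] <- px
  structure(list(kind = mapping$kind, values = out, valid = mapping$valid,
                 gene_id = if (inherits(volume, "expression_volume"))
                   volume$gene_id else NA_character_),
            class = "surface_projection")
}

#' @export
print.surface_projection <- function(x, ...) {
  cat("<surface_projection> ", x$kind,
      if (!is.na(x$gene_id)) paste0(", gene ", x$gene_id) else "", ", ",
      paste(dim(x$values), collapse = "x"), " pixels\n", sep = "")
  invisible(x)
}

#' Project a 3D area mask through a surface mapping
#'
#' A pixel belongs to the 2D area mask iff its path's surface voxel lies in
#' the 3D mask. Where the surface voxel carries no area label at all
#' (`labeled3d` provided and FALSE there), the majority of the path decides.
#' Projected with the same mapping as the expression data, so area borders
#' and expression steps stay aligned.
#'
#' @param area_mask3d Logical 3D array ([area_mask()]).
#' @param mapping A [build_surface_mapping()].
#' @param area_id Recorded in the result.
#' @param labeled3d Optional logical 3D array marking voxels that carry any
#'   area label (used only for the majority-of-path fallback).
#' @return An object of class `area_mask2d`: list with `area_id`, `mask`
#'   (2D logical), `pixel_count`.
#' @export
project_area_mask <- function(area_mask3d, mapping, area_id = NA_integer_,
                              labeled3d = NULL) {
  if (!identical(dim(area_mask3d), mapping$dims3))
    stop("mask lattice does not match mapping lattice")
  inside <- area_mask3d[mapping$surface_voxel]
  if (!is.null(labeled3d)) {
    unl <- !labeled3d[mapping$surface_voxel]
    if (any(unl)) {
      pm <- mapping$path_matrix[unl, , drop = FALSE]
      frac <- rowMeans(matrix(area_mask3d[pm], nrow = nrow(pm)), na.rm = TRUE)
      inside[unl] <- frac > 0.5
    }
  }
  m <- array(FALSE, dim = mapping$dims2)
  m[mapping$pixel_index[inside]] <- TRUE
  if (!any(m))
    warning("area ", area_id, " projects to an empty 2D mask (occluded or absent)")
  structure(list(area_id = area_id, mask = m,
                 pixel_count = sum(m)),
            class = "area_mask2d")
}

#' @export
print.area_mask2d <- function(x, ...) {
  cat("<area_mask2d> area ", x$area_id, ", ", x$pixel_count, " pixels\n",
      sep = "")
  invisible(x)
}

#' Save / load a projection as NRRD plus a JSON sidecar
#'
#' The sidecar records kind, lattice shape and the `NA` sentinel convention
#' so projections are self-describing on disk.
#'
#' @param projection A [project_volume()] result.
#' @param path Output `.nrrd` path (sidecar at `<path>.json`).
#' @return The reader returns a `surface_projection`.
#' @export
write_projection <- function(projection, path) {
  vals <- projection$values
  write_nrrd(vals, path, encoding = "raw")
  side <- list(kind = projection$kind, gene_id = projection$gene_id,
               dims = dim(vals), sentinel = "NA",
               valid_pixels = sum(projection$valid))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  vals <- read_nrrd(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(kind = side$kind, values = vals, valid = !is.na(vals),
                 gene_id = side$gene_id),
            class = "surface_projection")
}
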