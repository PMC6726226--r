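#' Dilate a 2D area mask into its border neighborhood
#'
#' Iterative binary dilation with the 4-connected cross structuring element
#' (each iteration grows the mask by one pixel of Manhattan distance). After
#' the iterations the result is intersected with the valid cortical
#' footprint, so the neighborhood never leaves the mapped surface. The
#' "surrounding region" of an area is `dilate_mask(...) & !mask`.
#'
#' @param mask2d Logical matrix (or an `area_mask2d`).
#' @param iterations Number of dilation iterations (default 30).
#' @param footprint Optional logical matrix of valid cortical pixels.
#' @return Logical matrix, a superset of the input mask (within the
#'   footprint).
#' @export
dilate_mask <- function(mask2d, iterations = 30L, footprint = NULL) {
  if (inherits(mask2d, "area_mask2d")) mask2d <- mask2d$mask
  stopifnot(is.matrix(mask2d) || length(dim(mask2d)) == 2L)
  m <- mask2d & TRUE
  dim(m) <- dim(mask2d)
  if (!any(m)) stop("empty mask: area absent from the projection")
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(iterations)) {
    g <- m
    g[-1, ] <- g[-1, ] | m[-nr, ]
    g[-nr, ] <- g[-nr, ] | m[-1, ]
    g[, -1] <- g[, -1] | m[, -nc]
    g[, -nc] <- g[, -nc] | m[, -1]
    m <- g
  }
  if (!is.null(footprint)) m <- m & footprint
  m
}

#' Assemble the pixel-by-gene dataset for one area
#'
#' Rows are the valid cortical pixels of the dilated neighborhood; columns
#' are genes, in the stable order of the `projections` list; each value is
#' the pixel's projected luminance. The label is 1 for pixels inside the
#' area mask and 0 for the surrounding region.
#'
#' @param projections Named list of [project_volume()] results sharing one
#'   mapping (all the same kind and dimensions).
#' @param area_mask2d An [project_area_mask()] result (or logical matrix).
#' @param neighborhood Logical matrix from [dilate_mask()].
#' @return An object of class `pixel_dataset`: list with `coords` (N x 2),
#'   `X` (N x G numeric matrix), `y` (integer 0/1), `gene_ids`, `area_id`.
#' @export
build_pixel_dataset <- function(projections, area_mask2d, neighborhood) {
  stopifnot(length(projections) >= 1L)
  kinds <- vapply(projections, `[[`, character(1), "kind")
  if (length(unique(kinds)) != 1L)
    stop("projections mix kinds: ", paste(unique(kinds), collapse = ", "))
  area_id <- NA_integer_
  if (inherits(area_mask2d, "area_mask2d")) {
    area_id <- area_mask2d$area_id
    area_mask2d <- area_mask2d$mask
  }
  valid <- projections[[1L]]$valid
  dims <- dim(projections[[1L]]$values)
  if (!identical(dim(area_mask2d), dims) || !identical(dim(neighborhood), dims))
    stop("mask / neighborhood dimensions do not match the projections")
  pix <- which(neighborhood & valid)
  if (!length(pix)) stop("no valid pixels in the neighborhood")
  X <- vapply(projections, function(p) p$values[pix], numeric(length(pix)))
  dim(X) <- c(length(pix), length(projections))
  colnames(X) <- names(projections)
  structure(list(coords = arrayInd(pix, dims),
                 X = X,
                 y = as.integer(area_mask2d[pix]),
                 gene_ids = names(projections),
                 area_id = area_id),
            class = "pixel_dataset")
}

#' @export
print.pixel_dataset <- function(x, ...) {
  cat("<pixel_dataset> area ", x$area_id, ": ", nrow(x$X), " pixels x ",
      ncol(x$X), " genes (", sum(x$y), " inside)\n", sep = "")
  invisible(x)
}

#' Random train/test split of a pixel dataset
#'
#' Test pixels are drawn uniformly without replacement and without
#' stratification, so the test set is representative of the neighborhood's
#' inside/outside mix. Deterministic given `seed`.
#'
#' @param dataset A [build_pixel_dataset()] result.
#' @param n_test Number of held-out test pixels (default 100).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(dataset, n_test = 100L, seed = 1L) {
  n <- nrow(dataset$X)
  if (n <= n_test)
    stop("dataset has ", n, " pixels but n_test = ", n_test,
         ": the area neighborhood is too small to hold out a test set")
  set.seed(seed)
  test <- sort(sample.int(n, n_test))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Random-forest configuration
#'
#' Defaults follow the screen's reference settings: 100 Gini-criterion
#' trees, random state 0, 100 held-out test pixels, bootstrap resampling on
#' and `floor(sqrt(G))` candidate features per node.
#'
#' @param n_trees Number of trees (>= 1).
#' @param random_state Integer seed for forest construction.
#' @param n_test_pixels Held-out test-set size.
#' @param mtry Features tried per node; `NULL` means `floor(sqrt(G))`.
#' @param bootstrap Bootstrap-resample training pixels per tree.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100L, random_state = 0L,
                          n_test_pixels = 100L, mtry = NULL,
                          bootstrap = TRUE) {
  stopifnot(n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 random_state = as.integer(random_state),
                 n_test_pixels = as.integer(n_test_pixels),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 bootstrap = isTRUE(bootstrap)),
            class = "forest_config")
}

#' Train the inside/outside random-forest classifier
#'
#' Grows an ensemble of Gini-criterion decision trees on the training
#' pixels (bootstrap resampling and per-node feature subsampling), fully
#' expanded until leaves are pure or unsplittable. Deterministic given
#' `config$random_state`.
#'
#' @param dataset A [build_pixel_dataset()] result.
#' @param train_idx Training row indices (from [split_train_test()]).
#' @param config A [forest_config()].
#' @return An object of class `border_forest`.
#' @export
train_forest <- function(dataset, train_idx = seq_len(nrow(dataset$X)),
                         config = forest_config()) {
  X <- dataset$X[train_idx, , drop = FALSE]
  y <- dataset$y[train_idx]
  if (length(unique(y)) < 2L)
    stop("training set contains a single class; cannot train")
  G <- ncol(X)
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(G))) else config$mtry
  set.seed(config$random_state)
  fit <- .rf_fit(X, y, config$n_trees, mtry, config$bootstrap)
  structure(list(trees = fit$trees,
                 importance_raw = as.numeric(fit$importance_raw),
                 gene_ids = dataset$gene_ids,
                 config = config,
                 n_train = length(train_idx),
                 area_id = dataset$area_id),
            class = "border_forest")
}

#' @export
print.border_forest <- function(x, ...) {
  cat("<border_forest> area ", x$area_id, ": ", length(x$trees),
      " trees, ", length(x$gene_ids), " genes, ", x$n_train,
      " training pixels\n", sep = "")
  invisible(x)
}

#' @param object A `border_forest`.
#' @param newdata Numeric matrix of pixels x genes.
#' @param type `"class"` (0/1) or `"prob"` (mean leaf class-1 fraction).
#' @param ... Unused.
#' @rdname train_forest
#' @export
predict.border_forest <- function(object, newdata, type = c("class", "prob"),
                                  ...) {
  type <- match.arg(type)
  prob <- .rf_predict_prob(object$trees, as.matrix(newdata))
  if (type == "prob") prob else as.integer(prob > 0.5)
}

#' Confusion matrix on held-out pixels
#'
#' @param tp,fn,fp,tn Counts (positive class = inside the area).
#' @return An object of class `confusion_matrix` with an `accuracy` field,
#'   `(tp + tn) / (tp + fn + fp + tn)`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  stopifnot(all(counts >= 0))
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 n = sum(counts),
                 accuracy = (tp + tn) / sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2,
              dimnames = list(truth = c("outside", "inside"),
                              predicted = c("outside", "inside")))
  print(m)
  cat(sprintf("accuracy: %.4f (n = %d)\n", x$accuracy, x$n))
  invisible(x)
}

#' Evaluate a fitted forest on held-out pixels
#'
#' @param forest A [train_forest()] result.
#' @param dataset The dataset the split came from.
#' @param test_idx Held-out row indices.
#' @return A [confusion_matrix()].
#' @export
evaluate_forest <- function(forest, dataset, test_idx) {
  if (!length(test_idx)) stop("empty test set")
  pred <- predict(forest, dataset$X[test_idx, , drop = FALSE])
  truth <- dataset$y[test_idx]
  confusion_matrix(tp = sum(pred == 1L & truth == 1L),
                   fn = sum(pred == 0L & truth == 1L),
                   fp = sum(pred == 1L & truth == 0L),
                   tn = sum(pred == 0L & truth == 0L))
}

#' Normalized Gini variable importance
#'
#' Each split's reduction in Gini impurity (weighted by the fraction of the
#' tree's samples reaching the node) is credited to the split variable,
#' summed per gene, averaged over trees and normalized so the total
#' importance across all genes sums to one. Ranks are by descending
#' importance with ties broken by the stable gene order.
#'
#' @param forest A [train_forest()] result.
#' @return An `importance_table` data.frame with columns `gene_id`,
#'   `importance`, `rank`, ordered by gene.
#' @export
importance_table <- function(forest) {
  imp <- forest$importance_raw
  total <- sum(imp)
  if (total <= 0) {
    warning("forest contains no splits; importances are all zero")
    norm <- rep(0, length(imp))
  } else {
    norm <- imp / total
  }
  ord <- order(-norm, seq_along(norm))
  rank <- integer(length(norm))
  rank[ord] <- seq_along(norm)
  out <- data.frame(gene_id = forest$gene_ids, importance = norm,
                    rank = rank, stringsAsFactors = FALSE)
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Log-binned histogram of importance values
#'
#' Descriptive report of the heavy-tailed importance distribution:
#' log-spaced bins over the positive importances, plus a leading bin
#' collecting exact zeros. Counts always sum to the number of genes.
#'
#' @param table An [importance_table()].
#' @param n_bins Number of log-spaced bins.
#' @return data.frame with columns `bin_lo`, `bin_hi`, `count`.
#' @export
importance_histogram <- function(table, n_bins = 20L) {
  stopifnot(nrow(table) >= 1L)
  imp <- table$importance
  pos <- imp[imp > 0]
  if (!length(pos))
    return(data.frame(bin_lo = 0, bin_hi = 0, count = length(imp)))
  lo <- min(pos); hi <- max(pos)
  if (lo == hi) {
    out <- data.frame(bin_lo = lo, bin_hi = hi, count = length(pos))
  } else {
    breaks <- 10^seq(log10(lo), log10(hi), length.out = n_bins + 1L)
    cnt <- table(cut(pos, breaks, include.lowest = TRUE))
    out <- data.frame(bin_lo = breaks[-length(breaks)],
                      bin_hi = breaks[-1L],
                      count = as.integer(cnt))
  }
  if (any(imp == 0))
    out <- rbind(data.frame(bin_lo = 0, bin_hi = 0, count = sum(imp == 0)),
                 out)
  rownames(out) <- NULL
  out
}
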