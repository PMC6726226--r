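#' Screen configuration
#'
#' @param top_k Candidate genes reported per area (default 10).
#' @param min_area_pixels Areas with fewer projected pixels are excluded
#'   from screening (default 1000).
#' @param dilation_iterations Border-neighborhood dilation (default 30).
#' @param forest A [forest_config()].
#' @param split_seed Seed of the train/test split (the forest seed is part
#'   of `forest`).
#' @param asymmetry_threshold Flag threshold for [asymmetry_score()].
#' @param gradient_threshold Flag threshold for [gradient_score()].
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(top_k = 10L, min_area_pixels = 1000L,
                          dilation_iterations = 30L,
                          forest = forest_config(), split_seed = 1L,
                          asymmetry_threshold = 0.5,
                          gradient_threshold = 0.5) {
  structure(list(top_k = as.integer(top_k),
                 min_area_pixels = as.integer(min_area_pixels),
                 dilation_iterations = as.integer(dilation_iterations),
                 forest = forest, split_seed = as.integer(split_seed),
                 asymmetry_threshold = asymmetry_threshold,
                 gradient_threshold = gradient_threshold),
            class = "screen_config")
}

#' Hemisphere-asymmetry score of a candidate gene
#'
#' Genes whose expression steps across the area border in only one
#' hemisphere are suspect as markers. The score compares the inside-vs-ring
#' luminance contrast between hemispheres (pixel columns left and right of
#' the mapping's dorsal midline):
#' `score = |contrast_L - contrast_R| / max(|contrast_L|, |contrast_R|)`.
#' 0 means perfectly mirrored contrast, 1 means the step exists in one
#' hemisphere only. Flags annotate candidates; they never remove them.
#'
#' @param projection A [project_volume()] result for the gene.
#' @param area_mask2d The area's [project_area_mask()] result (or matrix).
#' @param neighborhood Dilated neighborhood from [dilate_mask()].
#' @param midline_col Midline pixel column (from the `surface_mapping`).
#' @param threshold Flag threshold.
#' @return List with `score`, `flag` and `applicable` (`FALSE` when the
#'   area or ring does not straddle the midline, e.g. single-hemisphere
#'   mappings; then `score` is `NA` and `flag` is `FALSE`).
#' @export
asymmetry_score <- function(projection, area_mask2d, neighborhood,
                            midline_col, threshold = 0.5) {
  if (inherits(area_mask2d, "area_mask2d")) area_mask2d <- area_mask2d$mask
  v <- projection$values
  inside <- area_mask2d & projection$valid
  ring <- neighborhood & !area_mask2d & projection$valid
  hemi <- col(v) < midline_col
  contrast <- function(h) {
    i <- inside & h; r <- ring & h
    if (!any(i) || !any(r)) return(NA_real_)
    mean(v[i]) - mean(v[r])
  }
  cl <- contrast(hemi)
  cr <- contrast(!hemi)
  if (is.na(cl) || is.na(cr))
    return(list(score = NA_real_, flag = FALSE, applicable = FALSE))
  denom <- max(abs(cl), abs(cr))
  score <- if (denom == 0) 0 else abs(cl - cr) / denom
  list(score = score, flag = score > threshold, applicable = TRUE)
}

#' Within-area expression-gradient score
#'
#' Genes with a smooth gradient across the area (rather than a step at the
#' border) score highly. The score is the fraction of within-area luminance
#' variance explained by a least-squares plane in the pixel coordinates
#' (R-squared of `value ~ row + col`). Constant expression scores 0; a pure
#' noiseless ramp scores 1.
#'
#' @param projection A [project_volume()] result.
#' @param area_mask2d The area's 2D mask.
#' @param threshold Flag threshold.
#' @param min_pixels Minimum number of area pixels required (default 100).
#' @return List with `score` and `flag`.
#' @export
gradient_score <- function(projection, area_mask2d, threshold = 0.5,
                           min_pixels = 100L) {
  if (inherits(area_mask2d, "area_mask2d")) area_mask2d <- area_mask2d$mask
  inside <- which(area_mask2d & projection$valid & !is.na(projection$values))
  if (length(inside) < min_pixels)
    stop("area has ", length(inside), " usable pixels; need >= ", min_pixels)
  co <- arrayInd(inside, dim(projection$values))
  z <- projection$values[inside]
  M <- cbind(1, co[, 1], co[, 2])
  if (qr(M)$rank < 3L)
    stop("degenerate (collinear) pixel set; cannot fit a plane")
  fit <- stats::lm.fit(M, z)
  tss <- sum((z - mean(z))^2)
  if (tss < 1e-24) return(list(score = 0, flag = FALSE))
  score <- 1 - sum(fit$residuals^2) / tss
  score <- min(1, max(0, score))
  list(score = score, flag = score > threshold)
}

#' Run the marker screen across cortical areas
#'
#' Applies the projected-pixel-count filter, then for every surviving area
#' runs the full border-classification pipeline (dilated neighborhood,
#' pixel dataset, train/test split, random forest, confusion matrix, Gini
#' importances) and reports the `top_k` genes with asymmetry and gradient
#' flags attached. Flags annotate; they never drop a gene, so the length of
#' the candidate list is independent of the flag thresholds.
#'
#' @param projections Named list of per-gene [project_volume()] results
#'   sharing one mapping.
#' @param area_masks Named list of [project_area_mask()] results.
#' @param mapping The shared [build_surface_mapping()].
#' @param config A [screen_config()].
#' @return List of `candidate_report` objects (one per screened area) with
#'   an `excluded` attribute naming areas dropped by the size filter.
#' @export
run_screen <- function(projections, area_masks, mapping,
                       config = screen_config()) {
  sizes <- vapply(area_masks, `[[`, numeric(1), "pixel_count")
  keep <- sizes >= config$min_area_pixels
  excluded <- data.frame(
    area_id = vapply(area_masks[!keep], `[[`, integer(1), "area_id"),
    pixel_count = unname(sizes[!keep]),
    reason = rep(sprintf("fewer than %d projected pixels",
                         config$min_area_pixels), sum(!keep)))
  if (nrow(excluded))
    message("excluding ", nrow(excluded), " area(s) below ",
            config$min_area_pixels, " pixels: ",
            paste(excluded$area_id, collapse = ", "))
  if (!any(keep)) stop("no areas survive the size filter")
  reports <- lapply(area_masks[keep], function(am) {
    nb <- dilate_mask(am$mask, config$dilation_iterations,
                      footprint = mapping$valid)
    ds <- build_pixel_dataset(projections, am, nb)
    sp <- split_train_test(ds, config$forest$n_test_pixels,
                           seed = config$split_seed)
    forest <- train_forest(ds, sp$train, config$forest)
    cm <- evaluate_forest(forest, ds, sp$test)
    imp <- importance_table(forest)
    top <- imp[order(imp$rank), ][seq_len(min(config$top_k, nrow(imp))), ]
    flags <- lapply(top$gene_id, function(g) {
      a <- asymmetry_score(projections[[g]], am, nb, mapping$midline_col,
                           config$asymmetry_threshold)
      gr <- gradient_score(projections[[g]], am,
                           config$gradient_threshold)
      data.frame(asymmetry_score = a$score, asymmetry_flag = a$flag,
                 gradient_score = gr$score, gradient_flag = gr$flag)
    })
    top <- cbind(top, do.call(rbind, flags))
    rownames(top) <- NULL
    structure(list(area_id = am$area_id, pixel_count = am$pixel_count,
                   top = top, accuracy = cm$accuracy, confusion = cm,
                   importance = imp),
              class = "candidate_report")
  })
  attr(reports, "excluded") <- excluded
  reports
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("<candidate_report> area ", x$area_id, " (", x$pixel_count,
      " px), accuracy ", sprintf("%.3f", x$accuracy), "\n", sep = "")
  print(x$top[c("gene_id", "rank", "importance",
                "asymmetry_flag", "gradient_flag")])
  invisible(x)
}

#' Accuracy versus area size report
#'
#' Collects `(pixel_count, accuracy)` pairs across screened areas for
#' plotting; purely descriptive (no trend is asserted).
#'
#' @param reports List of reports from [run_screen()].
#' @return data.frame with columns `area_id`, `pixel_count`, `accuracy`.
#' @export
accuracy_vs_size_report <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 reports")
  data.frame(
    area_id = unname(vapply(reports, `[[`, integer(1), "area_id")),
    pixel_count = unname(vapply(reports, `[[`, numeric(1), "pixel_count")),
    accuracy = unname(vapply(reports, `[[`, numeric(1), "accuracy")),
    row.names = NULL)
}

#' Write candidate reports to CSV and JSON
#'
#' @param reports [run_screen()] output.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_top <- do.call(rbind, lapply(reports, function(r)
    cbind(area_id = r$area_id, accuracy = r$accuracy,
          pixel_count = r$pixel_count, r$top)))
  utils::write.csv(all_top, file.path(dir, "candidates.csv"),
                   row.names = FALSE)
  js <- lapply(reports, function(r)
    list(area_id = r$area_id, pixel_count = r$pixel_count,
         accuracy = r$accuracy,
         confusion = r$confusion[c("tp", "fn", "fp", "tn")],
         top = r$top))
  jsonlite::write_json(js, file.path(dir, "candidates.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
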