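# small screen configuration for the tiny fixture lattice
tiny_screen_config <- function(...) {
  screen_config(top_k = 5L, min_area_pixels = 100L,
                dilation_iterations = 8L,
                forest = forest_config(n_trees = 30L, n_test_pixels = 50L),
                split_seed = 2L, ...)
}

test_that("run_screen applies the size filter and recovers planted markers", {
  projs <- tiny_projections("flatmap")
  amasks <- tiny_area_masks("flatmap")
  map <- tiny_mapping("flatmap")
  st <- tiny_clean_study()

  reports <- suppressMessages(
    run_screen(projs, amasks, map, tiny_screen_config()))
  expect_length(reports, 4L)
  for (r in reports) {
    planted <- st$truth$gene_id[st$truth$target_area == r$area_id]
    expect_identical(r$top$gene_id[1L], planted)
    expect_gte(r$accuracy, 0.9)
    expect_identical(nrow(r$top), 5L)
  }

  # an area shrunk below the threshold is excluded with a logged reason
  small <- amasks
  small[[3L]]$pixel_count <- 99L
  cfg <- tiny_screen_config()
  reports2 <- suppressMessages(run_screen(projs, small, map, cfg))
  excl <- attr(reports2, "excluded")
  expect_length(reports2, 3L)
  expect_identical(excl$area_id, small[[3L]]$area_id)
  expect_match(excl$reason[1], "fewer than")

  cfg$min_area_pixels <- 100000L
  expect_error(suppressMessages(run_screen(projs, amasks, map, cfg)),
               "no areas survive")
})

test_that("flags annotate but never remove; screen is deterministic end to end", {
  projs <- tiny_projections("flatmap")
  amasks <- tiny_area_masks("flatmap")
  map <- tiny_mapping("flatmap")

  loose <- tiny_screen_config(asymmetry_threshold = 0.99,
                              gradient_threshold = 0.99)
  strict <- tiny_screen_config(asymmetry_threshold = 1e-6,
                               gradient_threshold = 1e-6)
  r1 <- suppressMessages(run_screen(projs, amasks[1], map, loose))
  r2 <- suppressMessages(run_screen(projs, amasks[1], map, strict))
  expect_identical(r1[[1]]$top$gene_id, r2[[1]]$top$gene_id)
  expect_identical(r1[[1]]$top$importance, r2[[1]]$top$importance)

  r3 <- suppressMessages(run_screen(projs, amasks[1], map, loose))
  expect_identical(r1[[1]]$top, r3[[1]]$top)
  expect_identical(r1[[1]]$accuracy, r3[[1]]$accuracy)
})

test_that("asymmetry score: mirrored 0, one-sided 1, intermediate formula", {
  # hand-built projection on a 20 x 21 grid; midline at column 11
  vals <- matrix(0.1, 20, 21)
  valid <- matrix(TRUE, 20, 21)
  inside <- matrix(FALSE, 20, 21)
  inside[6:15, c(3:6, 16:19)] <- TRUE             # mirrored area halves
  nb <- oracle_dilate(inside, 2L)
  proj <- function(v) structure(list(values = v, valid = valid,
                                     kind = "flatmap"),
                                class = "surface_projection")
  vsym <- vals; vsym[inside] <- 0.9
  s <- asymmetry_score(proj(vsym), inside, nb, midline_col = 11L)
  expect_identical(s$score, 0)
  expect_false(s$flag)

  vone <- vals; vone[inside & col(vals) < 11] <- 0.9
  s1 <- asymmetry_score(proj(vone), inside, nb, midline_col = 11L)
  expect_identical(s1$score, 1)
  expect_true(s1$flag)

  # intermediate: left step 0.8, right step 0.4 over a 0.1 ring
  vmid <- vals
  vmid[inside & col(vals) < 11] <- 0.9
  vmid[inside & col(vals) >= 11] <- 0.5
  s2 <- asymmetry_score(proj(vmid), inside, nb, midline_col = 11L)
  ring <- nb & !inside
  left <- col(vals) < 11
  cl <- mean(vmid[inside & left]) - mean(vmid[ring & left])
  cr <- mean(vmid[inside & !left]) - mean(vmid[ring & !left])
  expect_identical(s2$score, abs(cl - cr) / max(abs(cl), abs(cr)))
  expect_equal(s2$score, 0.5)

  # single-hemisphere area: not applicable
  one_sided <- matrix(FALSE, 20, 21); one_sided[6:15, 3:6] <- TRUE
  sna <- asymmetry_score(proj(vsym), one_sided,
                         oracle_dilate(one_sided, 2L), midline_col = 11L)
  expect_false(sna$applicable)
  expect_true(is.na(sna$score))
})

test_that("gradient score: constant 0, pure ramp 1, noisy ramp matches lm", {
  vals <- matrix(0.5, 30, 30)
  valid <- matrix(TRUE, 30, 30)
  inside <- matrix(FALSE, 30, 30); inside[5:26, 5:26] <- TRUE
  proj <- function(v) structure(list(values = v, valid = valid,
                                     kind = "top"),
                                class = "surface_projection")
  expect_identical(gradient_score(proj(vals), inside)$score, 0)

  ramp <- matrix(rep(seq(0, 1, length.out = 30), each = 30), 30, 30)
  g1 <- gradient_score(proj(ramp), inside)
  expect_equal(g1$score, 1)
  expect_true(g1$flag)

  set.seed(5)
  noisy <- ramp + matrix(rnorm(900, sd = 0.05), 30, 30)
  g2 <- gradient_score(proj(noisy), inside)
  idx <- which(inside)
  co <- arrayInd(idx, dim(noisy))
  orc <- summary(stats::lm(noisy[idx] ~ co[, 1] + co[, 2]))$r.squared
  expect_equal(g2$score, orc, tolerance = 1e-12)

  expect_error(gradient_score(proj(vals), inside[, 1:30] & col(vals) == 5),
               "usable pixels")
})

test_that("accuracy-vs-size report is pure bookkeeping", {
  projs <- tiny_projections("flatmap")
  amasks <- tiny_area_masks("flatmap")
  map <- tiny_mapping("flatmap")
  reports <- suppressMessages(
    run_screen(projs, amasks[1:2], map, tiny_screen_config()))
  tab <- accuracy_vs_size_report(reports)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$accuracy,
                   unname(vapply(reports, `[[`, numeric(1), "accuracy")))
  expect_identical(tab$pixel_count,
                   unname(vapply(reports, `[[`, numeric(1), "pixel_count")))
  expect_error(accuracy_vs_size_report(reports[1]), "at least 2")
})

test_that("asymmetric synthetic markers are flagged, clean markers are not", {
  # area straddling the dorsal midline, marker expressed in one hemisphere
  layout <- data.frame(theta_lo = c(-pi, -pi / 3, pi / 3),
                       theta_hi = c(-pi / 3, pi / 3, pi),
                       ap_lo = 0, ap_hi = 1)
  sp <- tiny_spec(n_areas = 3L, layout = layout)
  sp$gene_specs <- list(
    gene_spec("sym", "border_marker", target_area = 102L),
    gene_spec("asym", "border_marker", target_area = 102L,
              hemisphere = "left"),
    gene_spec("grad", "gradient", axis = "ap", low = 0.1, high = 0.9))
  st <- generate_study(sp)
  cm <- cortex_mask(st$annotation, st$tree)
  map <- build_surface_mapping(cm, "flatmap")
  projs <- lapply(st$volumes, function(v) project_volume(mask_volume(v, cm), map))
  am <- project_area_mask(area_mask(st$annotation, st$tree, 102L), map, 102L)
  nb <- dilate_mask(am$mask, 8L, footprint = map$valid)

  s_sym <- asymmetry_score(projs$sym, am, nb, map$midline_col)
  s_asym <- asymmetry_score(projs$asym, am, nb, map$midline_col)
  expect_false(s_sym$flag)
  expect_true(s_asym$flag)
  expect_gt(s_asym$score, s_sym$score)

  g_grad <- gradient_score(projs$grad, am)
  g_sym <- gradient_score(projs$sym, am)
  expect_true(g_grad$flag)
  expect_false(g_sym$flag)
})
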