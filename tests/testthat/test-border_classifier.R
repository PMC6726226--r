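test_that("dilation: identity, diamond, oracle match, monotone growth", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_identical(dilate_mask(m, 0L), m)
  d2 <- dilate_mask(m, 2L)
  expect_identical(sum(d2), 13L)                  # 2-step Manhattan diamond
  expect_identical(d2, oracle_dilate(m, 2L))

  set.seed(4)
  r <- matrix(runif(30 * 25) < 0.04, 30, 25)
  r[1, 1] <- TRUE
  prev <- r
  for (k in c(1L, 3L, 7L)) {
    dk <- dilate_mask(r, k)
    expect_identical(dk, oracle_dilate(r, k))
    expect_true(all(dk[prev]))                    # superset, monotone
    prev <- dk
  }
  # footprint intersection clips the result
  fp <- matrix(TRUE, 9, 9); fp[, 8:9] <- FALSE
  expect_true(all(!dilate_mask(m, 5L, footprint = fp)[, 8:9]))
  expect_error(dilate_mask(matrix(FALSE, 3, 3)), "empty mask")
})

test_that("pixel dataset: size, labels, stable gene order", {
  projs <- tiny_projections("flatmap")
  amasks <- tiny_area_masks("flatmap")
  map <- tiny_mapping("flatmap")
  am <- amasks[[1L]]
  nb <- dilate_mask(am$mask, 5L, footprint = map$valid)

  ds <- build_pixel_dataset(projs, am, nb)
  expect_identical(nrow(ds$X), sum(nb & map$valid))  # direct pixel count
  expect_identical(ds$gene_ids, names(projs))
  expect_identical(sum(ds$y), am$pixel_count)
  # labels match the area mask exactly at the stored coordinates
  expect_identical(ds$y,
                   as.integer(am$mask[cbind(ds$coords[, 1], ds$coords[, 2])]))

  # neighborhood == area mask: all labels 1
  ds1 <- build_pixel_dataset(projs, am, am$mask)
  expect_true(all(ds1$y == 1L))

  # single uniform gene gives a constant feature column
  dsu <- build_pixel_dataset(projs["uniform_02"], am, nb)
  expect_identical(ncol(dsu$X), 1L)
  expect_true(diff(range(dsu$X)) < 1e-12)

  ptop <- tiny_projections("top")
  expect_error(build_pixel_dataset(c(projs[1], ptop[2]), am, nb), "kinds")
})

test_that("train/test split: disjoint, exhaustive, deterministic, representative", {
  projs <- tiny_projections("flatmap")
  amasks <- tiny_area_masks("flatmap")
  map <- tiny_mapping("flatmap")
  nb <- dilate_mask(amasks[[2L]]$mask, 6L, footprint = map$valid)
  ds <- build_pixel_dataset(projs, amasks[[2L]], nb)
  n <- nrow(ds$X)

  sp <- split_train_test(ds, 100L, seed = 3L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_len(n))
  expect_identical(split_train_test(ds, 100L, seed = 3L), sp)

  # boundary: one training pixel left
  ds101 <- ds
  keep <- seq_len(101L)
  ds101$X <- ds$X[keep, , drop = FALSE]; ds101$y <- ds$y[keep]
  sp101 <- split_train_test(ds101, 100L, seed = 1L)
  expect_length(sp101$train, 1L)
  expect_error(split_train_test(ds101, 101L), "too small")

  # unstratified draw is representative: mean inside-fraction over many
  # seeds approaches the dataset fraction within binomial tolerance
  f <- mean(ds$y)
  fracs <- vapply(1:1000, function(s)
    mean(ds$y[split_train_test(ds, 100L, seed = s)$test]), numeric(1))
  tol <- 5 * sqrt(f * (1 - f) / (100 * 1000))
  expect_lt(abs(mean(fracs) - f), tol)
})

test_that("forest training: separable data, degenerate features, determinism", {
  set.seed(10)
  n <- 120L
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(inf = y + runif(n, -0.2, 0.2), n1 = runif(n), n2 = runif(n))
  ds <- structure(list(X = X, y = y, gene_ids = colnames(X),
                       coords = cbind(seq_len(n), 1L), area_id = 1L),
                  class = "pixel_dataset")
  cfg <- forest_config(n_trees = 25L, random_state = 0L)
  f <- train_forest(ds, seq_len(n), cfg)
  expect_identical(predict(f, X), y)              # separable: perfect fit

  f2 <- train_forest(ds, seq_len(n), cfg)
  expect_identical(predict(f2, X, type = "prob"), predict(f, X, type = "prob"))

  # all-constant features: majority-class prediction, zero importances
  dsc <- ds; dsc$X[] <- 0.5
  dsc$y <- c(rep(0L, 80L), rep(1L, 40L))
  fc <- train_forest(dsc, seq_len(n), cfg)
  expect_true(all(predict(fc, dsc$X) == 0L))
  expect_warning(it <- importance_table(fc), "no splits")
  expect_true(all(it$importance == 0))
  expect_identical(sort(it$rank), seq_len(3L))

  dss <- ds; dss$y <- rep(1L, n)
  expect_error(train_forest(dss, seq_len(n), cfg), "single class")
})

test_that("confusion matrix counts and accuracy", {
  cm <- confusion_matrix(tp = 52, fn = 2, fp = 2, tn = 44)
  expect_identical(cm$accuracy, 0.96)
  expect_identical(cm$n, 100)

  set.seed(11)
  n <- 160L
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(a = y + runif(n, -0.3, 0.3), b = runif(n))
  ds <- structure(list(X = X, y = y, gene_ids = colnames(X),
                       coords = cbind(seq_len(n), 1L), area_id = 1L),
                  class = "pixel_dataset")
  sp <- split_train_test(ds, 40L, seed = 2L)
  f <- train_forest(ds, sp$train, forest_config(n_trees = 25L))
  cm2 <- evaluate_forest(f, ds, sp$test)
  expect_identical(cm2$n, 40L)
  expect_identical(cm2$tp + cm2$fn, sum(ds$y[sp$test] == 1L))
  expect_true(cm2$accuracy >= 0 && cm2$accuracy <= 1)
  expect_error(evaluate_forest(f, ds, integer(0)), "empty test set")
})

test_that("importance: normalization, planted-gene rank 1, zero for unused genes", {
  set.seed(12)
  n <- 200L
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(marker = 0.1 + 0.8 * y + rnorm(n, sd = 0.05),
             matrix(runif(n * 4), n, 4,
                    dimnames = list(NULL, paste0("noise", 1:4))))
  ds <- structure(list(X = X, y = y, gene_ids = colnames(X),
                       coords = cbind(seq_len(n), 1L), area_id = 1L),
                  class = "pixel_dataset")
  f <- train_forest(ds, seq_len(n), forest_config(n_trees = 50L))
  it <- importance_table(f)
  expect_lt(abs(sum(it$importance) - 1), 1e-9)
  expect_true(all(it$importance >= 0))
  expect_identical(sort(it$rank), 1:5)
  expect_identical(it$gene_id[it$rank == 1L], "marker")

  # an exhaustive single tree splits only on the separable feature;
  # never-split genes carry importance 0
  Xs <- cbind(sep = y, cons = rep(0.3, n), cons2 = rep(0.7, n))
  dss <- ds; dss$X <- Xs; dss$gene_ids <- colnames(Xs)
  fs <- train_forest(dss, seq_len(n),
                     forest_config(n_trees = 1L, mtry = 3L,
                                   bootstrap = FALSE))
  its <- importance_table(fs)
  expect_identical(its$importance, c(1, 0, 0))
})

test_that("single exhaustive tree matches the brute-force Gini oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 150L
    y <- as.integer(runif(n) < 0.5)
    X <- matrix(runif(n * 5), n, 5,
                dimnames = list(NULL, paste0("g", 1:5)))
    X[, 1] <- X[, 1] + 0.6 * y          # one informative gene
    ds <- structure(list(X = X, y = y, gene_ids = colnames(X),
                         coords = cbind(seq_len(n), 1L), area_id = 1L),
                    class = "pixel_dataset")
    f <- train_forest(ds, seq_len(n),
                      forest_config(n_trees = 1L, mtry = 5L,
                                    bootstrap = FALSE))
    oracle <- oracle_gini_importance(X, y)
    expect_lt(max(abs(f$importance_raw - oracle)), 1e-9)
    it <- importance_table(f)
    expect_lt(max(abs(it$importance - oracle / sum(oracle))), 1e-9)
  }
})

test_that("importance histogram conserves counts", {
  it <- data.frame(gene_id = paste0("g", 1:20),
                   importance = c(rep(0, 5), 10^seq(-4, -1, length.out = 15)),
                   rank = c(20:16, 15:1))
  h <- importance_histogram(it, n_bins = 6L)
  expect_identical(sum(h$count), 20L)
  expect_identical(h$count[1L], 5L)               # zero bin

  flat <- data.frame(gene_id = paste0("g", 1:8),
                     importance = rep(1 / 8, 8), rank = 1:8)
  hf <- importance_histogram(flat)
  expect_identical(nrow(hf), 1L)
  expect_identical(hf$count, 8L)
})
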