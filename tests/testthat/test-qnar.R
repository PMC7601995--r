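make_plain_table <- function(df, nominal = character()) {
  df$material_id <- sprintf("r%02d", seq_len(nrow(df)))
  df$viability <- df$viability %||% rnorm(nrow(df))
  modeling_table(df, id = "material_id", endpoint = "viability",
                 nominal = nominal)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("redundancy filter drops duplicated and constant columns", {
  set.seed(1)
  df <- data.frame(a = rnorm(10), b = rnorm(10))
  df$dup <- df$a                       # duplicate: later copy dropped
  df$const <- 5                        # zero variance
  df$near <- df$b; df$near[1] <- 99    # 9/10 equal -> 0.9 >= 0.2, dropped
  df$ok <- rnorm(10)
  df$ok[1] <- df$a[1]                  # 1/10 equal -> 0.1 < 0.2, kept
  tab <- make_plain_table(cbind(df, viability = rnorm(10)))
  out <- redundancy_filter(tab, criterion = 0.2)
  expect_setequal(out$dropped$column, c("dup", "const", "near"))
  expect_true(all(c("a", "b", "ok") %in% names(out$table)))

  ## planted duplicate pairs are dropped exactly, later copy each time
  spec <- synthetic_table_spec(n_rows = 50, n_features = 10,
                               n_duplicate_pairs = 3, seed = 4)
  tab2 <- make_synthetic_table(spec)
  out2 <- redundancy_filter(tab2)
  expect_equal(sort(out2$dropped$column), c("dup1", "dup2", "dup3"))
})

test_that("Z-score normalisation uses train statistics only", {
  tr <- make_plain_table(data.frame(x = c(1, 2, 3), y = c(10, 20, 60),
                                    viability = c(0, 1, 2)))
  st <- fit_normalizer(tr)
  expect_equal(unname(st$mean["x"]), 2)
  expect_equal(unname(st$sd["x"]), sqrt(2 / 3))   # population sd 0.8165
  norm <- apply_normalizer(st, tr)
  for (cn in c("x", "y", "viability")) {
    expect_equal(mean(norm[[cn]]), 0, tolerance = 1e-10)
    expect_equal(nanoqnar:::sd_pop(norm[[cn]]), 1, tolerance = 1e-10)
  }
  ## out-of-range test values map to finite z-scores, no clipping
  te <- make_plain_table(data.frame(x = 100, y = -5, viability = 9))
  nt <- apply_normalizer(st, te)
  expect_equal(nt$x, (100 - 2) / sqrt(2 / 3))
  expect_true(all(is.finite(c(nt$x, nt$y, nt$viability))))
})

test_that("train/test split is a reproducible 70/30 partition", {
  tab <- make_synthetic_table(synthetic_table_spec(n_rows = 100, seed = 2))
  sp <- split_train_test(tab, 0.7, seed = 42)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  expect_setequal(c(sp$train$material_id, sp$test$material_id),
                  tab$material_id)
  sp2 <- split_train_test(tab, 0.7, seed = 42)
  expect_identical(sp$train$material_id, sp2$train$material_id)
  sp3 <- split_train_test(tab, 0.7, seed = 43)
  expect_false(identical(sp$train$material_id, sp3$train$material_id))
})

test_that("CFS merit matches its closed forms", {
  n <- 400
  set.seed(9)
  y <- rnorm(n)
  ## construct features with controlled correlations
  f1 <- y + rnorm(n, 0, sqrt(3))       # cor(f1, y) ~ 0.5
  tab <- make_plain_table(data.frame(f1 = f1, f2 = 2 * f1 + 3, f3 = 1,
                                     viability = y))
  r1 <- abs(cor(f1, y))
  expect_equal(cfs_merit("f1", tab), r1)
  ## two identical (perfectly correlated) features: merit = 2 r / sqrt(4)
  expect_equal(cfs_merit(c("f1", "f2"), tab), 2 * r1 / sqrt(2 + 2 * 1))
  ## constant feature contributes zero correlation
  expect_equal(cfs_merit("f3", tab), 0)

  ## synthetic uncorrelated pair: merit ~ 2 r / sqrt(2)
  set.seed(10)
  a <- rnorm(n); b <- rnorm(n); yy <- a + b
  tab2 <- make_plain_table(data.frame(a = a, b = b, viability = yy))
  got <- cfs_merit(c("a", "b"), tab2)
  rcf <- mean(abs(c(cor(a, yy), cor(b, yy))))
  rff <- abs(cor(a, b))
  expect_equal(got, 2 * rcf / sqrt(2 + 2 * rff))
})

test_that("best-first selection equals exhaustive CFS search on small sets", {
  for (seed in c(3, 7, 21, 33)) {
    tab <- make_synthetic_table(synthetic_table_spec(
      n_rows = 60, n_features = 8, informative = c(1, 3),
      weights = c(5, -4), noise_sd = 1, seed = seed))
    sel <- best_first_select(tab)
    feats <- setdiff(names(tab), c("material_id", "viability"))
    subsets <- unlist(lapply(seq_along(feats), function(k)
      combn(feats, k, simplify = FALSE)), recursive = FALSE)
    merits <- vapply(subsets, cfs_merit, numeric(1), train = tab)
    expect_equal(cfs_merit(sel, tab), max(merits), tolerance = 1e-10)
  }
})

test_that("best-first recovers a planted informative feature among noise", {
  tab <- make_synthetic_table(synthetic_table_spec(
    n_rows = 200, n_features = 30, informative = 5, weights = 10,
    noise_sd = 1, seed = 12))
  sel <- best_first_select(tab)
  expect_true("d5" %in% sel)

  ## identical features collapse to a single selection
  set.seed(5)
  x <- rnorm(80)
  tab2 <- make_plain_table(data.frame(a = x, b = x, c = x,
                                      viability = x + rnorm(80, 0, 0.5)))
  expect_length(best_first_select(tab2), 1)
})

test_that("kNN predictions match a brute-force distance oracle", {
  spec <- synthetic_table_spec(n_rows = 50, n_features = 6, seed = 8)
  tab <- make_synthetic_table(spec)
  norm <- fit_normalizer(tab)
  tabn <- apply_normalizer(norm, tab)
  feats <- c("d1", "d2", "d3", "assay")
  model <- knn_fit(tabn, feats, n_neighbors = 3)
  q <- tabn[sample(50, 20), ]
  got <- knn_predict(model, q)

  ## independent O(n^2) oracle with explicit mixed distance
  for (i in seq_len(nrow(q))) {
    d2 <- numeric(50)
    for (j in 1:50) {
      s <- 0
      for (f in c("d1", "d2", "d3"))
        s <- s + (q[[f]][i] - tabn[[f]][j])^2
      s <- s + as.numeric(q$assay[i] != tabn$assay[j])
      d2[j] <- s
    }
    ord <- order(sqrt(d2), seq_len(50))
    expect_equal(got$prediction[i], mean(tabn$viability[ord[1:3]]))
    expect_equal(got$neighbor_distances[i, ], sqrt(d2)[ord[1:4]])
    expect_equal(got$neighbor_ids[i, ], tabn$material_id[ord[1:4]])
  }

  ## neighbour distances are reported in non-decreasing order
  expect_true(all(apply(got$neighbor_distances, 1, function(r)
    all(diff(r) >= 0))))

  ## a query identical to a training row with k = 1 returns its endpoint
  m1 <- knn_fit(tabn, feats, n_neighbors = 1)
  self <- knn_predict(m1, tabn[7, ])
  expect_equal(self$prediction, tabn$viability[7])
  expect_equal(self$neighbor_distances[1, 1], 0)
})

test_that("kNN guards its preconditions", {
  tab <- make_synthetic_table(synthetic_table_spec(n_rows = 20, seed = 1))
  norm <- apply_normalizer(fit_normalizer(tab), tab)
  expect_error(knn_fit(norm, "d1", n_neighbors = 21), "n_neighbors")
  model <- knn_fit(norm, c("d1", "d2"), 3)
  expect_error(knn_predict(model, norm[, "d1", drop = FALSE]),
               "lacks feature")
})

test_that("pipeline is deterministic and affine-invariant", {
  tab <- make_synthetic_table(synthetic_table_spec(
    n_rows = 120, n_features = 15, seed = 6))
  f1 <- qnar_train(tab, split_seed = 3)
  f2 <- qnar_train(tab, split_seed = 3)
  expect_identical(f1$features, f2$features)
  expect_equal(f1$test_predictions$predicted, f2$test_predictions$predicted)
  expect_identical(f1$dropped$column, f2$dropped$column)

  ## rescaling a raw numeric column is absorbed by the train-fitted z-score
  tab2 <- tab
  tab2$d1 <- 100 * tab2$d1 - 7
  tab2 <- modeling_table(as.data.frame(tab2), id = "material_id",
                         endpoint = "viability", nominal = "assay")
  f3 <- qnar_train(tab2, split_seed = 3)
  expect_identical(f3$features, f1$features)
  expect_equal(f3$test_predictions$predicted, f1$test_predictions$predicted,
               tolerance = 1e-10)
})

test_that("bundles survive a JSON round-trip", {
  tab <- make_service_table(seed = 5)
  fit <- qnar_train(tab, split_seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  save_bundle(fit, path)
  back <- load_bundle(path)
  req <- parse_requests(paste0(
    '[{"id":"X1","coreSize":30,"hydroSize":60,"ecEv":-4,"assay":"ATP",',
    '"exposureDose":5,"des306":5,"des606":-0.2}]'))
  expect_equal(predict_batch(back, req), predict_batch(fit, req))
})
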