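#' Train the full read-across pipeline
#'
#' Runs the complete modelling chain on a raw table: redundancy filter
#' (criterion 0.2), random 70/30 train/test split, Z-score normalisation
#' fitted on the training set and applied to both sets, CFS + best-first
#' feature selection on the training set, kNN fit, applicability-domain fit
#' and Tropsha external validation on the held-out test set (on the raw
#' viability scale).
#'
#' @param table a raw [modeling_table()].
#' @param split_seed seed for the random split (default 1).
#' @param train_fraction training fraction (default 0.7).
#' @param criterion redundancy-filter threshold (default 0.2).
#' @param n_neighbors kNN neighbour count (default 3; the four nearest are
#'   always reported for diagnostics).
#' @param features optional fixed feature list, bypassing selection.
#' @param apd_Z applicability-domain multiplier (default 0.5).
#' @return A `qnar_bundle`: list with `model` (the `knn_model`),
#'   `normalizer`, `apd`, `features`, `dropped`, `report` (the
#'   [tropsha_suite()] on the test set), `test_predictions`, and metadata.
#' @export
#' @examples
#' tab <- make_synthetic_table(synthetic_table_spec(n_rows = 60, seed = 7))
#' fit <- qnar_train(tab, split_seed = 7)
#' fit$report
qnar_train <- function(table, split_seed = 1, train_fraction = 0.7,
                       criterion = 0.2, n_neighbors = 3, features = NULL,
                       apd_Z = 0.5) {
  filt <- redundancy_filter(table, criterion)
  sp <- split_train_test(filt$table, train_fraction, split_seed)
  norm <- fit_normalizer(sp$train)
  tr_n <- apply_normalizer(norm, sp$train)
  te_n <- apply_normalizer(norm, sp$test)
  if (is.null(features)) features <- best_first_select(tr_n)
  if (!length(features))
    stop("feature selection returned an empty set")
  model <- knn_fit(tr_n, features, n_neighbors)
  apd <- apd_fit(model, Z = apd_Z)

  ep <- endpoint_column(table)
  pred <- knn_predict(model, te_n)
  y_pred_raw <- denormalize_endpoint(norm, pred$prediction, ep)
  y_true_raw <- sp$test[[ep]]
  report <- tropsha_suite(y_true_raw, y_pred_raw, mean(sp$train[[ep]]))

  structure(list(
    model = model, normalizer = norm, apd = apd, features = features,
    dropped = filt$dropped, report = report,
    test_predictions = data.frame(
      id = sp$test[[id_column(table)]],
      observed = y_true_raw, predicted = y_pred_raw,
      apd = apd_classify(apd, pred$mean_knn_distance)),
    endpoint = ep,
    n_neighbors = n_neighbors, split_seed = split_seed,
    version = "nanoqnar-bundle-1"), class = "qnar_bundle")
}

#' @export
print.qnar_bundle <- function(x, ...) {
  cat("QNAR read-across bundle (", x$version, ")\n", sep = "")
  cat("Selected features:", paste(x$features, collapse = ", "), "\n")
  cat("Training rows:", nrow(x$model$X), "; neighbours:", x$n_neighbors,
      "\n")
  cat(sprintf("APD threshold: %.4f (Z = %g)\n", x$apd$threshold, x$apd$Z))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Save / load a trained bundle
#'
#' The bundle is serialised as a single versioned JSON document holding the
#' normalisation state, selected features, training matrix, nominal
#' registry, neighbour count and applicability-domain state.
#'
#' @param bundle a `qnar_bundle` from [qnar_train()].
#' @param path file path for the JSON bundle.
#' @return `save_bundle` returns `path` invisibly; `load_bundle` returns
#'   the restored `qnar_bundle` (training-time diagnostics such as the
#'   validation report are not round-tripped).
#' @export
save_bundle <- function(bundle, path) {
  payload <- list(
    version = bundle$version,
    endpoint = bundle$endpoint,
    n_neighbors = bundle$n_neighbors,
    features = bundle$features,
    nominal = bundle$model$nominal,
    ids = bundle$model$ids,
    y = bundle$model$y,
    X = bundle$model$X,
    normalizer = list(mean = as.list(bundle$normalizer$mean),
                      sd = as.list(bundle$normalizer$sd),
                      dropped = bundle$normalizer$dropped),
    apd = unclass(bundle$apd))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$version, "nanoqnar-bundle-1"))
    stop("unsupported bundle version: ", p$version)
  X <- as.data.frame(p$X)
  model <- structure(list(
    X = X, nominal = as.character(p$nominal), y = as.numeric(p$y),
    ids = as.character(p$ids), features = as.character(p$features),
    n_neighbors = as.integer(p$n_neighbors)), class = "knn_model")
  norm <- structure(list(mean = unlist(p$normalizer$mean),
                         sd = unlist(p$normalizer$sd),
                         dropped = as.character(p$normalizer$dropped)),
                    class = "preprocess_state")
  apd <- structure(p$apd[c("mean_distance", "sd_distance", "Z",
                           "threshold", "refined")], class = "apd_state")
  structure(list(model = model, normalizer = norm, apd = apd,
                 features = model$features, dropped = NULL, report = NULL,
                 endpoint = p$endpoint, n_neighbors = model$n_neighbors,
                 version = p$version), class = "qnar_bundle")
}
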