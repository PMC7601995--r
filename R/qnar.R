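## Read-across modelling pipeline: redundancy filter, Z-score normalisation,
## 70/30 split, CFS + best-first feature selection and the kNN regressor
## with mixed numeric/nominal Euclidean distances.

#' Declare a modelling table
#'
#' Attaches column roles to a data frame of experiment records: one `id`
#' column, one numeric `endpoint` column (percent cell viability), any number
#' of `nominal` columns (e.g. the assay label) and numeric descriptor
#' columns (everything else).
#'
#' @param df data frame with no missing values.
#' @param id name of the identifier column.
#' @param endpoint name of the endpoint column.
#' @param nominal character vector of nominal column names.
#' @return `df` with a `roles` attribute and class `modeling_table`.
#' @export
modeling_table <- function(df, id = "material_id", endpoint = "viability",
                           nominal = character()) {
  stopifnot(is.data.frame(df), id %in% names(df), endpoint %in% names(df))
  if (anyNA(df)) stop("modelling table must have no data gaps")
  roles <- setNames(rep("numeric", ncol(df)), names(df))
  roles[id] <- "id"
  roles[endpoint] <- "endpoint"
  roles[nominal] <- "nominal"
  attr(df, "roles") <- roles
  class(df) <- c("modeling_table", "data.frame")
  df
}

table_roles <- function(table) attr(table, "roles")

feature_columns <- function(table, kind = c("numeric", "nominal")) {
  roles <- table_roles(table)
  names(roles)[roles %in% kind]
}

endpoint_column <- function(table) {
  roles <- table_roles(table)
  names(roles)[roles == "endpoint"]
}

id_column <- function(table) {
  roles <- table_roles(table)
  names(roles)[roles == "id"]
}

## preserve roles when subsetting rows/columns
reroled <- function(df, table) {
  roles <- table_roles(table)[names(df)]
  attr(df, "roles") <- roles
  class(df) <- c("modeling_table", "data.frame")
  df
}

## 0/1 (or integer-level) encoding of nominal columns for correlations
encode_numeric <- function(table, columns) {
  roles <- table_roles(table)
  out <- lapply(columns, function(cn) {
    x <- table[[cn]]
    if (roles[cn] == "nominal") as.numeric(factor(x)) - 1 else as.numeric(x)
  })
  names(out) <- columns
  as.data.frame(out)
}

#' Remove redundant descriptor columns
#'
#' For every ordered pair of numeric descriptor columns, the later column is
#' dropped when the fraction of rows on which the two agree (within 1e-12)
#' reaches `criterion` (default 0.2, i.e. 20%% or more shared values).
#' Zero-variance columns are dropped first.
#'
#' @param table a [modeling_table()].
#' @param criterion equal-fraction removal threshold in `(0, 1]`.
#' @return list with `table` (filtered) and `dropped` (data frame of column
#'   names and reasons).
#' @export
redundancy_filter <- function(table, criterion = 0.2) {
  if (criterion <= 0 || criterion > 1) stop("criterion must be in (0, 1]")
  num <- feature_columns(table, "numeric")
  dropped <- data.frame(column = character(), reason = character(),
                        stringsAsFactors = FALSE)
  keep <- character()
  for (cn in num) {
    if (sd_pop(table[[cn]]) == 0) {
      dropped <- rbind(dropped, data.frame(column = cn,
                                           reason = "zero variance"))
      next
    }
    dup <- FALSE
    for (kn in keep) {
      frac <- mean(abs(table[[cn]] - table[[kn]]) <= 1e-12)
      if (frac >= criterion) {
        dropped <- rbind(dropped, data.frame(
          column = cn,
          reason = sprintf("%.0f%% of values equal to '%s'", 100 * frac, kn)))
        dup <- TRUE
        break
      }
    }
    if (!dup) keep <- c(keep, cn)
  }
  cols <- names(table)[!(names(table) %in% dropped$column)]
  list(table = reroled(table[, cols, drop = FALSE], table),
       dropped = dropped)
}

#' Z-score normalisation fitted on the training set
#'
#' `fit_normalizer` records the per-column mean and population standard
#' deviation of every numeric column (descriptors and endpoint) of the
#' training table; `apply_normalizer` transforms any table with those
#' training statistics, so a transformed training column has mean 0 and
#' standard deviation 1, and test values keep finite z-scores with no
#' clipping.  Nominal and id columns are untouched.
#'
#' @param train a [modeling_table()].
#' @return For `fit_normalizer`, a `preprocess_state` with `mean`, `sd` and
#'   `dropped` (zero-spread columns); for `apply_normalizer`, the
#'   transformed table.
#' @export
fit_normalizer <- function(train) {
  num <- c(feature_columns(train, "numeric"), endpoint_column(train))
  mu <- vapply(num, function(cn) mean(train[[cn]]), numeric(1))
  sg <- vapply(num, function(cn) sd_pop(train[[cn]]), numeric(1))
  dropped <- num[sg == 0]
  if (length(dropped))
    warning("zero-spread column(s) dropped from normalisation: ",
            paste(dropped, collapse = ", "))
  keep <- sg > 0
  structure(list(mean = mu[keep], sd = sg[keep], dropped = dropped),
            class = "preprocess_state")
}

#' @rdname fit_normalizer
#' @param state a `preprocess_state` from `fit_normalizer`.
#' @param table table to transform with the training statistics.
#' @export
apply_normalizer <- function(state, table) {
  for (cn in names(state$mean)) {
    if (cn %in% names(table))
      table[[cn]] <- (table[[cn]] - state$mean[[cn]]) / state$sd[[cn]]
  }
  drop <- intersect(state$dropped, names(table))
  if (length(drop)) {
    keep <- setdiff(names(table), drop)
    table <- reroled(as.data.frame(table)[, keep, drop = FALSE], table)
  }
  table
}

## invert the endpoint transform for reporting on the raw viability scale
denormalize_endpoint <- function(state, y, endpoint) {
  if (!endpoint %in% names(state$mean)) return(y)
  y * state$sd[[endpoint]] + state$mean[[endpoint]]
}

#' Random 70/30 train/test split
#'
#' @param table a [modeling_table()] with at least 10 rows.
#' @param fraction training fraction (default 0.7); the training size is
#'   `round(fraction * n)`.
#' @param seed integer seed making the partition reproducible.
#' @return list with `train` and `test` tables (disjoint, exhaustive).
#' @export
split_train_test <- function(table, fraction = 0.7, seed = 1) {
  n <- nrow(table)
  if (n < 10) stop("need at least 10 rows to split")
  ntr <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, ntr))
  list(train = reroled(table[sort(idx), , drop = FALSE], table),
       test = reroled(table[setdiff(seq_len(n), idx), , drop = FALSE],
                      table))
}

#' Correlation-based feature-subset merit
#'
#' CFS merit of a candidate subset:
#' `merit = k * rcf / sqrt(k + k (k - 1) * rff)` where `k` is the subset
#' size, `rcf` the mean absolute Pearson correlation between the features
#' and the endpoint and `rff` the mean absolute pairwise feature
#' correlation.  Nominal features enter through a 0/1 encoding; a constant
#' feature contributes correlation 0.
#'
#' @param subset character vector of feature column names.
#' @param train a [modeling_table()].
#' @return the merit score (scalar).
#' @export
cfs_merit <- function(subset, train) {
  if (!length(subset)) stop("subset must be non-empty")
  enc <- encode_numeric(train, subset)
  y <- train[[endpoint_column(train)]]
  safe_cor <- function(a, b) {
    if (sd_pop(a) == 0 || sd_pop(b) == 0) return(0)
    cor(a, b)
  }
  rcf <- mean(vapply(enc, function(x) abs(safe_cor(x, y)), numeric(1)))
  k <- length(subset)
  rff <- if (k > 1) {
    cm <- abs(cor(as.matrix(enc)))
    cm[!is.finite(cm)] <- 0
    mean(cm[upper.tri(cm)])
  } else 0
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Forward best-first CFS feature selection
#'
#' Greedy best-first search over feature subsets maximising [cfs_merit()],
#' expanding the best open subset and terminating after `stale_limit`
#' consecutive expansions that fail to improve the best merit found.  Ties
#' are broken deterministically by column order.
#'
#' @param train a [modeling_table()].
#' @param stale_limit consecutive non-improving expansions tolerated
#'   (default 5, the conventional best-first termination).
#' @return character vector of selected feature names (in column order).
#' @export
best_first_select <- function(train, stale_limit = 5) {
  feats <- feature_columns(train, c("numeric", "nominal"))
  if (length(feats) < 2) return(feats)
  enc <- encode_numeric(train, feats)
  y <- train[[endpoint_column(train)]]
  sds <- vapply(enc, sd_pop, numeric(1))
  M <- cbind(as.matrix(enc), .y = y)
  CM <- suppressWarnings(abs(cor(M)))
  CM[!is.finite(CM)] <- 0
  CM[sds == 0, ] <- 0; CM[, c(sds == 0, FALSE)] <- 0
  rcf_all <- CM[seq_along(feats), ".y"]
  FF <- CM[seq_along(feats), seq_along(feats)]

  merit_of <- function(sel) {           # sel: integer feature indices
    k <- length(sel)
    rcf <- mean(rcf_all[sel])
    rff <- if (k > 1) mean(FF[sel, sel][upper.tri(FF[sel, sel])]) else 0
    k * rcf / sqrt(k + k * (k - 1) * rff)
  }

  key <- function(sel) paste(sort(sel), collapse = ",")
  open <- list(list(sel = integer(), merit = 0))
  seen <- new.env(hash = TRUE)
  best_sel <- integer(); best_merit <- 0
  stale <- 0
  while (length(open) && stale < stale_limit) {
    merits <- vapply(open, `[[`, numeric(1), "merit")
    i <- which.max(merits)              # first max: deterministic tie-break
    node <- open[[i]]; open[[i]] <- NULL
    improved <- FALSE
    for (f in setdiff(seq_along(feats), node$sel)) {
      child <- c(node$sel, f)
      k <- key(child)
      if (!is.null(seen[[k]])) next
      assign(k, TRUE, envir = seen)
      m <- merit_of(child)
      open[[length(open) + 1]] <- list(sel = child, merit = m)
      if (m > best_merit + 1e-12) {
        best_merit <- m; best_sel <- child; improved <- TRUE
      }
    }
    stale <- if (improved) 0 else stale + 1
  }
  feats[sort(best_sel)]
}

#' Fit the kNN read-across model
#'
#' Stores the (already normalised) training matrix restricted to the
#' selected features, the endpoints and the nominal-column registry.
#' Distances are mixed Euclidean: squared numeric z-score differences plus a
#' 0/1 mismatch indicator per nominal feature.
#'
#' @param train a normalised [modeling_table()].
#' @param features selected feature names.
#' @param n_neighbors neighbours averaged for a prediction (default 3).
#' @return a `knn_model`.
#' @export
knn_fit <- function(train, features, n_neighbors = 3) {
  if (n_neighbors < 1 || n_neighbors > nrow(train))
    stop("n_neighbors must be in [1, training size]")
  roles <- table_roles(train)
  miss <- setdiff(features, names(train))
  if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
  structure(list(
    X = train[, features, drop = FALSE],
    nominal = features[roles[features] == "nominal"],
    y = train[[endpoint_column(train)]],
    ids = as.character(train[[id_column(train)]]),
    features = features,
    n_neighbors = n_neighbors), class = "knn_model")
}

knn_distances <- function(model, query) {
  ## query: data frame with the model's feature columns; returns a
  ## n_query x n_train matrix of mixed Euclidean distances
  nq <- nrow(query); nt <- nrow(model$X)
  D2 <- matrix(0, nq, nt)
  for (f in model$features) {
    qv <- query[[f]]; tv <- model$X[[f]]
    if (f %in% model$nominal) {
      D2 <- D2 + outer(as.character(qv), as.character(tv), "!=")
    } else {
      D2 <- D2 + outer(as.numeric(qv), as.numeric(tv), "-")^2
    }
  }
  sqrt(D2)
}

#' Predict with the kNN read-across model
#'
#' The prediction is the unweighted mean endpoint of the `n_neighbors`
#' nearest training rows (ties broken by training-row order).  The four
#' nearest neighbours' ids and distances are always reported for
#' diagnostics, regardless of `n_neighbors`.
#'
#' @param model a `knn_model` from [knn_fit()].
#' @param query data frame carrying the model's feature columns.
#' @return list with `prediction` (numeric), `neighbor_ids` (n x 4
#'   character), `neighbor_distances` (n x 4, non-decreasing left to right)
#'   and `mean_knn_distance` (mean distance to the `n_neighbors` nearest,
#'   the applicability-domain statistic).
#' @export
knn_predict <- function(model, query) {
  miss <- setdiff(model$features, names(query))
  if (length(miss))
    stop("query lacks feature(s): ", paste(miss, collapse = ", "))
  D <- knn_distances(model, query)
  nt <- ncol(D)
  nrep <- min(4, nt)
  pred <- numeric(nrow(D))
  mknn <- numeric(nrow(D))
  nid <- matrix(NA_character_, nrow(D), 4)
  ndist <- matrix(NA_real_, nrow(D), 4)
  for (i in seq_len(nrow(D))) {
    ord <- order(D[i, ], seq_len(nt))    # stable: row order breaks ties
    nn <- ord[seq_len(model$n_neighbors)]
    pred[i] <- mean(model$y[nn])
    mknn[i] <- mean(D[i, nn])
    nid[i, seq_len(nrep)] <- model$ids[ord[seq_len(nrep)]]
    ndist[i, seq_len(nrep)] <- D[i, ord[seq_len(nrep)]]
  }
  list(prediction = pred, neighbor_ids = nid, neighbor_distances = ndist,
       mean_knn_distance = mknn)
}
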