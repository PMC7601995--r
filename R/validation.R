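#' Tropsha external-validation statistics
#'
#' Computes the external-validation suite for a continuous QSAR/QNAR model:
#' \itemize{
#'   \item `r2_pred`: squared Pearson correlation of observed vs predicted
#'     on the test set;
#'   \item `r2_cvext = 1 - sum((y - yhat)^2) / sum((y - ybar_train)^2)`;
#'   \item regression-through-origin slopes `k = sum(y yhat) / sum(yhat^2)`
#'     and `k' = sum(y yhat) / sum(y^2)`;
#'   \item through-origin determination coefficients
#'     `r0sq = 1 - sum((yhat - k y)^2) / sum((yhat - mean(yhat))^2)` and its
#'     mirrored counterpart `r0sq_prime` with the roles of observation and
#'     prediction exchanged.
#' }
#' The model is flagged predictive when `r2_cvext > 0.5`, `r2_pred > 0.6`,
#' `(r2_pred - r0sq)/r2_pred < 0.1` (both directions),
#' `0.85 <= k <= 1.15` (both slopes) and `|r0sq - r0sq_prime| < 0.3`.
#'
#' @param y_true observed endpoint values on the test set (length >= 3,
#'   non-constant).
#' @param y_pred predicted values, same length.
#' @param y_train_mean mean endpoint of the training set.
#' @return An object of class `tropsha_report`: a list of the statistics and
#'   a logical `checks` vector with an overall `pass` flag.
#' @export
#' @examples
#' y <- c(10, 30, 50, 70, 90)
#' tropsha_suite(y, y, mean(y))$pass  # perfect predictions pass
tropsha_suite <- function(y_true, y_pred, y_train_mean) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3)
  if (sd_pop(y_true) == 0)
    stop("undefined statistic: test endpoints are constant")
  ss_ref <- sum((y_true - y_train_mean)^2)
  if (ss_ref == 0) stop("undefined statistic: zero reference sum of squares")
  r2_cvext <- 1 - sum((y_true - y_pred)^2) / ss_ref

  r2_pred <- if (sd_pop(y_pred) == 0) 0 else cor(y_true, y_pred)^2

  if (sum(y_pred^2) == 0 || sum(y_true^2) == 0)
    stop("undefined statistic: zero through-origin denominator")
  k <- sum(y_true * y_pred) / sum(y_pred^2)
  k_prime <- sum(y_true * y_pred) / sum(y_true^2)

  r0_den <- sum((y_pred - mean(y_pred))^2)
  r0p_den <- sum((y_true - mean(y_true))^2)
  if (r0_den == 0 || r0p_den == 0)
    stop("undefined statistic: constant predictions or observations")
  r0sq <- 1 - sum((y_pred - k * y_true)^2) / r0_den
  r0sq_prime <- 1 - sum((y_true - k_prime * y_pred)^2) / r0p_den

  checks <- c(
    r2_cvext_gt_0.5 = r2_cvext > 0.5,
    r2_pred_gt_0.6 = r2_pred > 0.6,
    r0sq_close = r2_pred != 0 && (r2_pred - r0sq) / r2_pred < 0.1,
    r0sq_prime_close = r2_pred != 0 && (r2_pred - r0sq_prime) / r2_pred < 0.1,
    r0sq_gap_lt_0.3 = abs(r0sq - r0sq_prime) < 0.3,
    k_in_band = k >= 0.85 && k <= 1.15,
    k_prime_in_band = k_prime >= 0.85 && k_prime <= 1.15)

  structure(list(r2_pred = r2_pred, r2_cvext = r2_cvext,
                 k = k, k_prime = k_prime,
                 r0sq = r0sq, r0sq_prime = r0sq_prime,
                 checks = checks, pass = all(checks)),
            class = "tropsha_report")
}

#' @export
print.tropsha_report <- function(x, ...) {
  cat(sprintf("Tropsha validation: R2_pred=%.4f R2_cvext=%.4f", x$r2_pred,
              x$r2_cvext),
      sprintf("k=%.4f k'=%.4f R0^2=%.4f R0'^2=%.4f", x$k, x$k_prime,
              x$r0sq, x$r0sq_prime),
      if (x$pass) "-> predictive (all criteria pass)" else
        paste("-> FAILS:", paste(names(x$checks)[!x$checks],
                                 collapse = ", ")),
      sep = "\n")
  invisible(x)
}

#' Applicability domain from training-set distances
#'
#' Fits the distance-based applicability domain threshold
#' `APD = <d> + Z * sigma` (default `Z = 0.5`).  Following the Enalos
#' convention, `<d>` and `sigma` are by default taken over the subset of
#' pairwise training distances lying below their grand mean (falling back to
#' all pairs when that subset is empty); `refine = FALSE` switches to the
#' plain all-pairs statistics.
#'
#' @param model a `knn_model` from [knn_fit()] (supplies the training matrix
#'   and the distance metric).
#' @param Z empirical multiplier on the distance spread (default 0.5).
#' @param refine keep only sub-mean pairwise distances before taking the
#'   mean and standard deviation (default `TRUE`).
#' @return An `apd_state` with `mean_distance`, `sd_distance`, `Z` and
#'   `threshold`.
#' @export
apd_fit <- function(model, Z = 0.5, refine = TRUE) {
  nt <- nrow(model$X)
  if (nt < 2) stop("need at least 2 training rows")
  D <- knn_distances(model, model$X)
  d <- D[upper.tri(D)]
  if (refine) {
    kept <- d[d < mean(d)]
    if (length(kept)) d <- kept
  }
  m <- mean(d); s <- sd_pop(d)
  structure(list(mean_distance = m, sd_distance = s, Z = Z,
                 threshold = m + Z * s, refined = refine),
            class = "apd_state")
}

#' @rdname apd_fit
#' @param state an `apd_state`.
#' @param query_distance mean distance of each query to its `n_neighbors`
#'   nearest training rows (the `mean_knn_distance` from [knn_predict()]).
#' @return For `apd_classify`, a character vector `"reliable"` /
#'   `"unreliable"`.
#' @export
apd_classify <- function(state, query_distance) {
  ifelse(query_distance <= state$threshold, "reliable", "unreliable")
}

#' Y-randomisation robustness test
#'
#' Rebuilds the full modelling pipeline after randomly permuting the
#' endpoint column (descriptors untouched) and collects the external
#' statistics per round.  A real structure-activity relationship should
#' degrade markedly under shuffling.
#'
#' @param table the raw [modeling_table()].
#' @param n_rounds number of shuffled datasets (default 10).
#' @param seed integer seed controlling the permutations.
#' @param ... arguments forwarded to [qnar_train()] (e.g. `split_seed`,
#'   `n_neighbors`).
#' @return list with `original` (the unshuffled [tropsha_suite()] report)
#'   and `rounds`, a data frame of per-round `r2_pred` and `r2_cvext`.
#' @export
y_randomization <- function(table, n_rounds = 10, seed = 1, ...) {
  original <- qnar_train(table, ...)
  ep <- endpoint_column(table)
  rounds <- data.frame(round = seq_len(n_rounds), r2_pred = NA_real_,
                       r2_cvext = NA_real_)
  perms <- with_seed(seed, lapply(seq_len(n_rounds), function(i)
    sample.int(nrow(table))))
  for (i in seq_len(n_rounds)) {
    shuffled <- table
    shuffled[[ep]] <- table[[ep]][perms[[i]]]
    shuffled <- reroled(shuffled, table)
    fit <- qnar_train(shuffled, ...)
    rounds$r2_pred[i] <- fit$report$r2_pred
    rounds$r2_cvext[i] <- fit$report$r2_cvext
  }
  list(original = original$report, rounds = rounds)
}
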