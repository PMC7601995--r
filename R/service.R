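## Batch prediction interface: JSON/CSV requests carrying the seven selected
## cytotoxicity descriptors, and structured prediction records mirroring the
## deployed webservice response schema.

REQUEST_FIELDS <- c("id", "coreSize", "hydroSize", "ecEv", "assay",
                    "exposureDose", "des306", "des606")
REQUEST_NUMERIC <- setdiff(REQUEST_FIELDS, c("id", "assay"))
ASSAY_LEVELS <- c("ATP", "LDH")

#' Parse batch prediction requests
#'
#' Accepts a JSON array of request tuples (as a file path or a literal JSON
#' string) or a CSV file with identical column names.  Every tuple must
#' carry exactly the fields `id`, `coreSize` (nm), `hydroSize` (nm), `ecEv`
#' (eV), `assay` (`"ATP"` or `"LDH"`), `exposureDose` (ug/mL), `des306`
#' (average coordination number of surface metal atoms) and `des606`
#' (surface-normal force component of surface metal atoms, eV/A).  Unknown
#' fields are rejected and validation failures name the offending field and
#' record.
#'
#' @param payload path to a `.json`/`.csv` file, or a JSON string.
#' @return data frame of validated requests (possibly zero rows).
#' @export
#' @examples
#' parse_requests(paste0('[{"id":"CuO","coreSize":25,"hydroSize":45,',
#'   '"ecEv":-5.17,"assay":"ATP","exposureDose":3.2,',
#'   '"des306":3.579,"des606":-0.243}]'))
parse_requests <- function(payload) {
  recs <- if (length(payload) == 1 && file.exists(payload) &&
              grepl("\\.csv$", payload, ignore.case = TRUE)) {
    df <- read.csv(payload, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  } else {
    txt <- if (length(payload) == 1 && file.exists(payload))
      paste(readLines(payload, warn = FALSE), collapse = "\n") else payload
    out <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
    if (!is.null(names(out))) out <- list(out)   # single tuple
    out
  }
  if (!length(recs))
    return(as.data.frame(setNames(
      c(list(character()),
        rep(list(numeric()), 3), list(character()),
        rep(list(numeric()), 3)), REQUEST_FIELDS)))

  parsed <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    unknown <- setdiff(names(r), REQUEST_FIELDS)
    if (length(unknown))
      stop(sprintf("request %d: unknown field(s) %s", i,
                   paste(unknown, collapse = ", ")))
    missing <- setdiff(REQUEST_FIELDS, names(r))
    if (length(missing))
      stop(sprintf("request %d: missing field(s) %s", i,
                   paste(missing, collapse = ", ")))
    if (!r$assay %in% ASSAY_LEVELS)
      stop(sprintf("request %d: field assay must be one of %s (got '%s')",
                   i, paste(ASSAY_LEVELS, collapse = "/"), r$assay))
    for (f in REQUEST_NUMERIC) {
      v <- suppressWarnings(as.numeric(r[[f]]))
      if (length(v) != 1 || !is.finite(v))
        stop(sprintf("request %d: field %s must be a finite number", i, f))
      r[[f]] <- v
    }
    r$id <- as.character(r$id)
    as.data.frame(r[REQUEST_FIELDS], stringsAsFactors = FALSE)
  })
  do.call(rbind, parsed)
}

#' Serialise prediction requests to JSON
#'
#' Inverse of [parse_requests()]; values round-trip at full precision.
#'
#' @param requests data frame of requests.
#' @param path optional output file; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
serialize_requests <- function(requests, path = NULL) {
  txt <- jsonlite::toJSON(requests[, REQUEST_FIELDS, drop = FALSE],
                          dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Batch prediction with a trained bundle
#'
#' Normalises each request with the bundle's training statistics, finds the
#' nearest training neighbours, and emits one record per request with the
#' response schema of the deployed service: `id`, `assay`, `apdPrediction`,
#' `nn1ID..nn4ID`, the six normalised numeric inputs, `nn1Distance..
#' nn4Distance` (non-decreasing) and `knnprediction` on the normalised
#' endpoint scale.  The additional `viabilityPercent` column carries the
#' denormalised prediction in percent cell viability.
#'
#' @param bundle a `qnar_bundle` trained on the seven-descriptor service
#'   schema (features `coreSize`, `hydroSize`, `assay`, `exposureDose`,
#'   `ecEv`, `des306`, `des606`).
#' @param requests data frame from [parse_requests()].
#' @return data frame of prediction records in input order.
#' @export
predict_batch <- function(bundle, requests) {
  need <- setdiff(bundle$features, REQUEST_FIELDS)
  if (length(need))
    stop("bundle was not trained on the service schema; its features ",
         "include: ", paste(need, collapse = ", "))
  if (!nrow(requests)) return(data.frame())
  q <- requests
  for (cn in intersect(names(bundle$normalizer$mean), names(q)))
    q[[cn]] <- (q[[cn]] - bundle$normalizer$mean[[cn]]) /
      bundle$normalizer$sd[[cn]]
  pred <- knn_predict(bundle$model, q)
  apd <- apd_classify(bundle$apd, pred$mean_knn_distance)
  ## knnprediction is reported on the normalised endpoint scale; convert to
  ## percent viability when the bundle holds raw-scale endpoints instead
  ep <- bundle$endpoint
  norm_scale <- ep %in% names(bundle$normalizer$mean)
  knnpred <- pred$prediction
  viability <- if (norm_scale)
    denormalize_endpoint(bundle$normalizer, knnpred, ep) else knnpred
  out <- data.frame(
    id = requests$id, assay = requests$assay, apdPrediction = apd,
    nn1ID = pred$neighbor_ids[, 1], nn2ID = pred$neighbor_ids[, 2],
    nn3ID = pred$neighbor_ids[, 3], nn4ID = pred$neighbor_ids[, 4],
    coreSize = q$coreSize, hydroSize = q$hydroSize, ecEv = q$ecEv,
    exposureDose = q$exposureDose, des306 = q$des306, des606 = q$des606,
    nn1Distance = pred$neighbor_distances[, 1],
    nn2Distance = pred$neighbor_distances[, 2],
    nn3Distance = pred$neighbor_distances[, 3],
    nn4Distance = pred$neighbor_distances[, 4],
    knnprediction = knnpred,
    viabilityPercent = viability,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname predict_batch
#' @param records prediction records from `predict_batch`.
#' @param path optional output file.
#' @return For `serialize_predictions`, JSON text.
#' @export
serialize_predictions <- function(records, path = NULL) {
  txt <- jsonlite::toJSON(records, dataframe = "rows", auto_unbox = TRUE,
                          digits = NA)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
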