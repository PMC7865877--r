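# End-to-end analysis pipeline: clean -> delineate -> measure -> diagnose ->
# score, producing one JSON-serialisable result per recording.

#' A fixed-output stand-in for a trained network
#'
#' Useful for pipeline tests and for wiring the scoring stage without a
#' trained model: it always emits probability 1 for `items` and 0 elsewhere.
#'
#' @param items character vector of item abbreviations to call.
#' @export
stub_model <- function(items = "SN") {
  bad <- setdiff(items, diagnosis_items()$abbr)
  if (length(bad)) stop("unknown item(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(items = items), class = "ecg_stub_model")
}

#' Pipeline configuration
#'
#' @param filter a [filter_config()].
#' @param model optional trained `ecg_network` (or [stub_model()]); when
#'   absent the diagnosis and scoring stages are skipped with a notice.
#' @param risk_table risk table for scoring.
#' @param call_threshold probability threshold for diagnosis calls.
#' @param seed integer seed recorded in the output for provenance.
#' @export
pipeline_config <- function(filter = filter_config(), model = NULL,
                            risk_table = default_risk_table(),
                            call_threshold = 0.5, seed = 1L) {
  structure(list(filter = filter, model = model, risk_table = risk_table,
                 call_threshold = call_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_predict <- function(model, record, threshold) {
  if (inherits(model, "ecg_stub_model")) {
    items <- diagnosis_items()$abbr
    p <- stats::setNames(as.numeric(items %in% model$items), items)
    structure(list(probabilities = p, calls = p >= threshold,
                   threshold = threshold),
              class = "diagnosis_result")
  } else {
    predict_diagnosis(model, record, threshold)
  }
}

#' Run the full analysis pipeline on one recording
#'
#' Cleans the record, stops early with status `"empty"` for lead-off input,
#' otherwise delineates, measures, runs the diagnosis model (if provided) and
#' scores the detected items.
#'
#' @param record an [ecg_record()] or a path readable by [read_record()].
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` (JSON-serialisable via
#'   [pipeline_to_json()]).
#' @export
run_pipeline <- function(record, config = pipeline_config()) {
  if (is.character(record)) record <- read_record(record)
  assert_record(record)
  res <- list(schema_version = 1L, record_id = record$record_id,
              seed = config$seed, status = "ok")
  stage <- "clean"
  out <- tryCatch({
    cleaned <- clean_record(record, config$filter)
    res$provenance <- cleaned$provenance
    if (has_flag(cleaned, "empty")) {
      res$status <- "empty"
      return(structure(res, class = "pipeline_result"))
    }
    stage <- "delineate"
    peaks <- detect_qrs(cleaned)
    ann <- delineate_waves(cleaned, peaks)
    stage <- "measure"
    meas <- compute_measurements(ann)
    res$measurements <- as.list(meas$summary)
    res$n_beats <- nrow(ann)
    if (length(peaks) >= 3L) {
      h <- compute_hrv(peaks, cleaned$sampling_rate)
      res$hrv <- list(mean_rr = h$mean_rr, sdnn = h$sdnn, rmssd = h$rmssd,
                      pnn50 = h$pnn50, n_intervals = h$n_intervals)
    }
    stage <- "diagnose"
    if (!is.null(config$model)) {
      dg <- pipeline_predict(config$model, cleaned, config$call_threshold)
      res$diagnosis <- list(probabilities = as.list(dg$probabilities),
                            calls = names(dg$calls)[dg$calls])
      stage <- "score"
      hs <- score_from_items(names(dg$calls)[dg$calls], config$risk_table)
      res$score <- hs$score
      res$deductions <- as.list(hs$deductions)
    } else {
      res$diagnosis <- NULL
      res$notice <- "no model configured; diagnosis and scoring skipped"
    }
    structure(res, class = "pipeline_result")
  }, error = function(e) {
    structure(list(schema_version = 1L, record_id = record$record_id,
                   seed = config$seed, status = "error", stage = stage,
                   message = conditionMessage(e)),
              class = "pipeline_result")
  })
  out
}

#' Serialise a pipeline result to JSON (stable key order)
#' @param result a `pipeline_result`.
#' @param path optional output file.
#' @export
pipeline_to_json <- function(result, path = NULL) {
  js <- jsonlite::toJSON(unclass(result), auto_unbox = TRUE, digits = 10,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else js
}
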