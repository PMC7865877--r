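# Rule-based cardiovascular health layer: risk table, 0-100 health score,
# passive alert conditions, retrospective report.

#' Built-in risk table
#'
#' Risk category and critical value (score deduction) for each of the 20
#' diagnostic items.  Sinus rhythm deducts nothing; deductions grow with risk
#' category up to 50 for the life-threatening tachycardias and third-degree
#' block.
#'
#' @return data.frame with columns `item`, `category`, `critical_value`.
#' @export
default_risk_table <- function() {
  tab <- data.frame(
    item = c("SN",
             "SNA", "SNT", "SNB",
             "LBBB", "PVC", "PJC", "PAC", "RBBB",
             "WPW", "VE", "AE", "JE", "AVBI", "AFL", "AF", "AVBII",
             "VT", "SVT", "AVBIII"),
    category = c("No Risk",
                 rep("Medium-low Risk", 3),
                 rep("Medium Risk", 5),
                 rep("Medium-high Risk", 8),
                 rep("High Risk", 3)),
    critical_value = c(0,
                       2, 5, 5,
                       9, 12, 12, 12, 15,
                       16, 16, 16, 16, 16, 25, 25, 25,
                       50, 50, 50),
    stringsAsFactors = FALSE
  )
  tab[match(diagnosis_items()$abbr, tab$item), , drop = FALSE]
}

#' Read a risk table from CSV
#'
#' The CSV must have columns `item,category,critical_value` and cover all 20
#' items exactly once.
#'
#' @param path CSV file path.
#' @export
read_risk_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_risk_table(tab)
  tab
}

validate_risk_table <- function(tab) {
  need <- c("item", "category", "critical_value")
  if (!all(need %in% names(tab))) {
    stop("risk table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  items <- diagnosis_items()$abbr
  if (!setequal(tab$item, items) || anyDuplicated(tab$item)) {
    stop("risk table must cover the 20 diagnostic items exactly once", call. = FALSE)
  }
  if (any(tab$critical_value < 0)) stop("critical values must be >= 0", call. = FALSE)
  invisible(tab)
}

#' Risk category of a diagnostic item
#'
#' @param item item abbreviation (e.g. `"AF"`).
#' @param table a risk table; default [default_risk_table()].
#' @export
risk_category <- function(item, table = default_risk_table()) {
  i <- match(item, table$item)
  if (any(is.na(i))) {
    stop("unknown diagnostic item: ", paste(item[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  table$category[i]
}

#' Cardiovascular health score from detected items
#'
#' The score starts at 100 and each detected abnormal item subtracts its
#' critical value; sinus rhythm (critical value 0) never deducts.  With
#' `combine = "sum"` (default) deductions add up; `"max"` applies only the
#' largest.  The score is floored at 0.
#'
#' @param detected character vector of detected item abbreviations (may be
#'   empty).
#' @param table a risk table.
#' @param combine `"sum"` or `"max"`.
#' @return list of class `health_score`: `score` (integer), `detected_items`,
#'   `deductions` (named), `timestamp`.
#' @export
score_from_items <- function(detected, table = default_risk_table(),
                             combine = c("sum", "max")) {
  combine <- match.arg(combine)
  validate_risk_table(table)
  detected <- unique(as.character(detected))
  i <- match(detected, table$item)
  if (any(is.na(i))) {
    stop("unknown diagnostic item: ", paste(detected[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  ded <- table$critical_value[i]
  names(ded) <- detected
  total <- if (length(ded) == 0) 0 else switch(combine, sum = sum(ded), max = max(ded))
  structure(list(score = as.integer(max(0, 100 - total)),
                 detected_items = detected,
                 deductions = ded,
                 timestamp = Sys.time()),
            class = "health_score")
}

#' @export
print.health_score <- function(x, ...) {
  cat(sprintf("<health_score> %d/100 (detected: %s)\n", x$score,
              if (length(x$detected_items)) paste(x$detected_items, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Evaluate the passive alert conditions on a score history
#'
#' Two conditions require a doctor's attention: (1) the last two scores are
#' both strictly below 85; (2) at least three of the most recent five scores
#' are strictly below 90.  With fewer than five measurements the second rule
#' is evaluated over what is available (it cannot fire with fewer than three).
#' When both fire, the first rule is reported.
#'
#' @param history numeric vector of scores, oldest first.
#' @return list of class `alert_decision`: `triggered` (logical), `rule`
#'   (`"none"`, `"two_consecutive_below_85"` or `"three_of_last_five_below_90"`),
#'   `window` (the scores examined).
#' @export
evaluate_alert <- function(history) {
  if (length(history) == 0) stop("empty score history", call. = FALSE)
  history <- as.numeric(history)
  n <- length(history)
  rule <- "none"
  if (n >= 2 && all(history[(n - 1):n] < 85)) {
    rule <- "two_consecutive_below_85"
  } else {
    recent <- history[max(1, n - 4):n]
    if (sum(recent < 90) >= 3) rule <- "three_of_last_five_below_90"
  }
  structure(list(triggered = rule != "none", rule = rule,
                 window = history[max(1, n - 4):n]),
            class = "alert_decision")
}

#' Retrospective (weekly) report
#'
#' Summarises a period of recordings: per-item detection counts, measurement
#' summaries, HRV, RR-scatter data, the score trajectory, and the alert
#' status.
#'
#' @param diagnoses list of detected-item character vectors (one per
#'   recording) or of `diagnosis_result` objects.
#' @param measurements optional list of `measurement_report`s.
#' @param hrv optional list of `hrv_summary`s.
#' @param scores optional numeric score trajectory (oldest first).
#' @param rr optional list of RR-scatter data.frames.
#' @param average_beat optional `average_beat` template.
#' @param period label for the reporting period.
#' @return list of class `retrospective_report`; serialise with
#'   [report_to_json()].
#' @export
build_retrospective_report <- function(diagnoses, measurements = NULL,
                                       hrv = NULL, scores = NULL, rr = NULL,
                                       average_beat = NULL, period = "week") {
  if (length(diagnoses) == 0) {
    return(structure(list(empty = TRUE, period = period),
                     class = "retrospective_report"))
  }
  detected <- lapply(diagnoses, function(d) {
    if (inherits(d, "diagnosis_result")) names(d$calls)[d$calls] else as.character(d)
  })
  items <- diagnosis_items()$abbr
  counts <- vapply(items, function(it) sum(vapply(detected, function(d) it %in% d,
                                                  logical(1))), integer(1))
  meas_summary <- if (!is.null(measurements)) {
    m <- do.call(rbind, lapply(measurements, function(r) r$summary))
    apply(m, 2, stats::median, na.rm = TRUE)
  } else NULL
  hrv_summary <- if (!is.null(hrv)) {
    list(mean_rr = stats::median(vapply(hrv, `[[`, numeric(1), "mean_rr")),
         sdnn = stats::median(vapply(hrv, `[[`, numeric(1), "sdnn")),
         rmssd = stats::median(vapply(hrv, `[[`, numeric(1), "rmssd")),
         pnn50 = stats::median(vapply(hrv, `[[`, numeric(1), "pnn50")))
  } else NULL
  alert <- if (!is.null(scores)) evaluate_alert(scores) else NULL
  structure(list(empty = FALSE, period = period, n_recordings = length(diagnoses),
                 item_counts = as.list(counts), measurements = meas_summary,
                 hrv = hrv_summary, scores = scores,
                 rr_points = if (!is.null(rr)) do.call(rbind, rr) else NULL,
                 average_beat = average_beat,
                 alert = if (!is.null(alert)) {
                   list(triggered = alert$triggered, rule = alert$rule)
                 } else NULL),
            class = "retrospective_report")
}

#' Serialise a retrospective report to JSON
#' @param report a `retrospective_report`.
#' @param path optional output file; when omitted the JSON string is returned.
#' @export
report_to_json <- function(report, path = NULL) {
  x <- unclass(report)
  x$schema_version <- 1L
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else {
    js
  }
}

#' Parse a retrospective report from JSON
#' @param json JSON string or file path.
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(x, class = "retrospective_report")
}
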