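# Human-readable alert rendering shared by the engines.

#' Render an engine alert event as a message
#'
#' Deterministic template per alert kind. Irrigation events come from
#' [irrigation_alerts()], disease events from [disease_alerts()], and
#' phenology events from a [forecast_stage_dates()] row.
#'
#' @param event One event: a one-row data frame (or list). Must carry
#'   `kind` (`"irrigation"`, `"disease"` or `"phenology"`) and the fields
#'   of its engine's event schema.
#' @return Object of class `alert_message`: list with site_id, parcel_id,
#'   kind, date, severity, body and a machine-readable payload holding the
#'   triggering value and threshold.
#' @export
render_alert <- function(event) {
  event <- as.list(event)
  kind <- event$kind %||% stop("alert event has no kind", call. = FALSE)
  msg <- switch(
    kind,
    irrigation = list(
      severity = "warning",
      body = sprintf(
        paste0("Irrigation alert %s: Dryness Index %.1f mm is below the ",
               "%.0f mm threshold. Irrigation of the parcel is recommended."),
        format(as.Date(event$date)), event$value, event$threshold),
      payload = list(di_mm = event$value, threshold_mm = event$threshold)),
    disease = list(
      severity = "warning",
      body = sprintf(
        paste0("Downy-mildew alert %s: Goidanich index %.1f%% exceeds the ",
               "%.0f%% threshold. Timely treatment application is ",
               "recommended."),
        format(as.Date(event$date)), event$value, event$threshold),
      payload = list(gi_pct = event$value, threshold_pct = event$threshold)),
    phenology = list(
      severity = "info",
      body = sprintf(
        paste0("Phenology update: BBCH %02d expected on %s under the %s ",
               "scenario (cumulative GDD %.0f)."),
        event$bbch, format(as.Date(event$predicted_date %||% event$date)),
        event$scenario, event$gdd_at_forecast %||% event$value),
      payload = list(bbch = event$bbch, scenario = event$scenario,
                     gdd = event$gdd_at_forecast %||% event$value)),
    stop("unknown alert kind: ", kind, call. = FALSE)
  )
  structure(list(site_id = event$site_id %||% NA_character_,
                 parcel_id = event$parcel_id %||% NA_character_,
                 kind = kind,
                 date = as.Date(event$date %||% event$predicted_date),
                 severity = msg$severity, body = msg$body,
                 payload = msg$payload),
            class = "alert_message")
}

#' @export
print.alert_message <- function(x, ...) {
  cat(sprintf("[%s] %s\n", toupper(x$severity), x$body))
  invisible(x)
}

#' @export
format.alert_message <- function(x, ...) x$body
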