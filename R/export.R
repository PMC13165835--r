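# Tabular export of phenology and management records.

#' Export records for a date window
#'
#' Filters the records to the window and writes CSV or XLSX. CSV round-trips
#' losslessly through [utils::read.csv()]. XLSX is written through the
#' system Python's openpyxl (single sheet named after the record type); CSV
#' is the primary format.
#'
#' @param records Data frame with a `date` column (phenology or management
#'   records).
#' @param window Length-2 date vector `c(start, end)`.
#' @param path Output file.
#' @param format `"csv"` or `"xlsx"`.
#' @param sheet Sheet name for XLSX (defaults to `"records"`).
#' @return The path, invisibly. An empty window yields a header-only file
#'   with a warning.
#' @export
export_records <- function(records, window, path, format = c("csv", "xlsx"),
                           sheet = "records") {
  format <- match.arg(format)
  window <- as.Date(window)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  records$date <- as.Date(records$date)
  sel <- records[records$date >= window[1] & records$date <= window[2], ,
                 drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no records in the export window", call. = FALSE)
  }
  sel$date <- format(sel$date)
  if (format == "csv") {
    utils::write.csv(sel, path, row.names = FALSE, na = "")
  } else {
    write_xlsx_sheet(sel, path, sheet)
  }
  invisible(path)
}

# Write one sheet of an XLSX workbook via the system Python + openpyxl
# (no R xlsx writer is used by this package).
write_xlsx_sheet <- function(df, path, sheet = "records") {
  python <- Sys.which("python")
  if (python == "") python <- Sys.which("python3")
  if (python == "") {
    stop("XLSX export needs a python interpreter with openpyxl on PATH",
         call. = FALSE)
  }
  tmp_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp_csv))
  utils::write.csv(df, tmp_csv, row.names = FALSE, na = "")
  script <- sprintf(
    "import csv, sys\nfrom openpyxl import Workbook\nwb = Workbook()\nws = wb.active\nws.title = %s\nwith open(sys.argv[1], newline='') as fh:\n    for row in csv.reader(fh):\n        ws.append(row)\nwb.save(sys.argv[2])\n",
    deparse(sheet))
  tmp_py <- tempfile(fileext = ".py")
  on.exit(unlink(tmp_py), add = TRUE)
  writeLines(script, tmp_py)
  status <- system2(python, c(tmp_py, tmp_csv, path),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("XLSX export failed (openpyxl)", call. = FALSE)
  invisible(path)
}

# Read back the first sheet of an XLSX workbook (name + rows) for
# verification; returns list(sheet, data).
read_xlsx_sheet <- function(path) {
  python <- Sys.which("python")
  if (python == "") python <- Sys.which("python3")
  tmp_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp_csv))
  script <- "import csv, sys\nfrom openpyxl import load_workbook\nwb = load_workbook(sys.argv[1], read_only=True)\nws = wb.active\nwith open(sys.argv[2], 'w', newline='') as fh:\n    w = csv.writer(fh)\n    for row in ws.iter_rows(values_only=True):\n        w.writerow(['' if v is None else v for v in row])\nprint(ws.title)\n"
  tmp_py <- tempfile(fileext = ".py")
  on.exit(unlink(tmp_py), add = TRUE)
  writeLines(script, tmp_py)
  title <- system2(python, c(tmp_py, path, tmp_csv), stdout = TRUE)
  list(sheet = title[1],
       data = utils::read.csv(tmp_csv, stringsAsFactors = FALSE))
}
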