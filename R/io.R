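## Delimited recording I/O. Each channel group is a tab-separated file with
## a small '#'-prefixed header (rate, units, channel labels) followed by
## one column per channel; the protocol marker stream and a JSON truth
## sidecar live alongside. (EDF is not supported in this environment: no
## EDF codec is available; the delimited format is the interchange format.)

write_trace_file <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate=%.10g", trace$rate),
               sprintf("# units=%s", trace$units),
               sprintf("# channels=%s", paste(trace$channels, collapse = "\t"))),
             con)
  utils::write.table(
    matrix(sprintf("%.17g", trace$samples), nrow = nrow(trace$samples)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_trace_file <- function(path) {
  hdr <- readLines(path, n = 3)
  get <- function(key) sub(paste0("^# ", key, "="), "", hdr[grepl(paste0("^# ", key, "="), hdr)])
  rate <- as.numeric(get("rate"))
  units <- get("units")
  channels <- strsplit(get("channels"), "\t", fixed = TRUE)[[1]]
  d <- utils::read.table(path, sep = "\t", comment.char = "#",
                         colClasses = "numeric")
  signal_trace(as.matrix(d), rate, units = units, channels = channels)
}

TRACE_ROLES <- c("gsr", "ecg", "bvp", "eeg", "pupil_left", "pupil_right")

#' Write a multimodal recording to a directory
#'
#' One delimited file per channel role (`gsr.tsv`, `ecg.tsv`, ...), the
#' protocol marker file (`markers.tsv`) and a JSON sidecar with the
#' ground-truth records when present (`truth.json`).
#'
#' @param rec a `multimodal_recording`.
#' @param dir output directory (created if needed).
#' @param format only `"delimited"` is supported (`"edf"` errors: no EDF
#'   codec is available in this environment).
#' @export
save_recording <- function(rec, dir, format = c("delimited", "edf")) {
  format <- match.arg(format)
  if (format == "edf")
    stop("EDF output is not supported (no EDF codec available); use 'delimited'")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (role in TRACE_ROLES) {
    if (!is.null(rec[[role]]))
      write_trace_file(rec[[role]], file.path(dir, paste0(role, ".tsv")))
  }
  write_markers(rec$schedule, file.path(dir, "markers.tsv"))
  if (!is.null(rec$truth)) {
    truth <- rapply(rec$truth, unclass, how = "replace",
                    classes = c("rr_ground_truth", "scr_ground_truth",
                                "bvp_ground_truth", "eeg_ground_truth",
                                "pupil_ground_truth", "rr_series"))
    truth <- lapply(truth, function(x) if (is.list(x)) unclass(x) else x)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  }
  invisible(dir)
}

#' Load a multimodal recording from a directory
#'
#' Reads back what [save_recording()] wrote. A `channel_map` can rename
#' files to roles, e.g. `list(ecg = "ekg.tsv")`; missing roles are simply
#' absent from the result, but roles named in `require` must resolve.
#'
#' @param dir recording directory.
#' @param format only `"delimited"` is supported.
#' @param channel_map optional named list role -> file name.
#' @param require character vector of roles that must be present.
#' @return a `multimodal_recording` (without ground truth unless
#'   `truth.json` exists, in which case it is attached as plain lists).
#' @export
load_recording <- function(dir, format = c("delimited", "edf"),
                           channel_map = NULL, require = character(0)) {
  format <- match.arg(format)
  if (format == "edf")
    stop("EDF input is not supported (no EDF codec available); use 'delimited'")
  rec <- list()
  for (role in TRACE_ROLES) {
    fname <- channel_map[[role]] %||% paste0(role, ".tsv")
    p <- file.path(dir, fname)
    if (file.exists(p)) rec[[role]] <- read_trace_file(p)
  }
  missing <- setdiff(require, names(rec))
  if (length(missing))
    stop(sprintf("missing channel role(s): %s", paste(missing, collapse = ", ")))
  mpath <- file.path(dir, "markers.tsv")
  if (!file.exists(mpath)) stop("marker file markers.tsv not found")
  rec$schedule <- read_markers(mpath)
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath))
    rec$truth <- jsonlite::read_json(tpath, simplifyVector = TRUE)
  class(rec) <- "multimodal_recording"
  rec
}
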