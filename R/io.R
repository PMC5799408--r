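#' Read lick events from a CSV table
#'
#' Expects one row per lick with subject, session day, concentration and
#' timestamp columns, and returns one \code{\link{lick_train}} per
#' (subject, day). Column names are remapped through \code{columns}, so
#' tables exported from acquisition software with different headers can be
#' read without editing the file.
#'
#' Rows are never silently dropped: out-of-order timestamps are sorted with
#' a warning, and a negative timestamp is an error naming the offending row.
#'
#' @param path CSV file with one row per lick.
#' @param columns named character vector mapping the required fields
#'   (\code{subject_id}, \code{session_day}, \code{concentration},
#'   \code{timestamp}) to the file's column names.
#' @param sessions optional data.frame (\code{subject_id},
#'   \code{session_day}, \code{concentration}) enumerating sessions that
#'   must be present; sessions with no lick rows yield empty trains rather
#'   than being absent.
#' @param session_duration seconds (default 900).
#' @return list of \code{lick_train} objects, ordered by subject then day.
#' @export
read_lick_csv <- function(path,
                          columns = c(subject_id = "subject_id",
                                      session_day = "session_day",
                                      concentration = "concentration",
                                      timestamp = "time_s"),
                          sessions = NULL,
                          session_duration = 900) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session_day", "concentration", "timestamp")
  miss <- setdiff(need, names(columns))
  if (length(miss)) stop("column mapping missing field(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(unname(columns[need]), names(df))
  if (length(absent)) stop("lick CSV missing column(s): ", paste(absent, collapse = ", "))
  ts <- as.numeric(df[[columns[["timestamp"]]]])
  if (any(ts < 0, na.rm = TRUE)) {
    stop("negative timestamp at row ", which(ts < 0)[1L])
  }
  sub <- as.character(df[[columns[["subject_id"]]]])
  day <- as.integer(df[[columns[["session_day"]]]])
  conc <- as.numeric(df[[columns[["concentration"]]]])

  grid <- unique(data.frame(subject_id = sub, session_day = day,
                            concentration = conc, stringsAsFactors = FALSE))
  if (!is.null(sessions)) {
    sess <- data.frame(subject_id = as.character(sessions$subject_id),
                       session_day = as.integer(sessions$session_day),
                       concentration = as.numeric(sessions$concentration),
                       stringsAsFactors = FALSE)
    grid <- unique(rbind(grid, sess))
  }
  grid <- grid[order(grid$subject_id, grid$session_day), , drop = FALSE]

  key <- paste(sub, day, sep = "\r")
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    k <- paste(grid$subject_id[i], grid$session_day[i], sep = "\r")
    tsi <- ts[key == k]
    if (length(tsi) && is.unsorted(tsi)) {
      warning("timestamps out of order for subject ", grid$subject_id[i],
              " day ", grid$session_day[i], "; sorting")
      tsi <- sort(tsi)
    }
    out[[i]] <- lick_train(grid$subject_id[i], tsi,
                           session_day = grid$session_day[i],
                           concentration = grid$concentration[i],
                           session_duration = session_duration)
  }
  out
}

#' Write lick trains to a CSV table
#'
#' Inverse of \code{\link{read_lick_csv}}: one row per lick, UTF-8, header
#' row, "." decimal separator, timestamps rounded to the device resolution.
#' Empty trains contribute no rows (re-reading needs the \code{sessions}
#' argument to restore them).
#'
#' @param trains list of \code{lick_train} objects.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_lick_csv <- function(trains, path) {
  rows <- lapply(trains, function(tr) {
    if (!n_licks(tr)) return(NULL)
    data.frame(subject_id = tr$subject_id,
               session_day = tr$session_day,
               concentration = tr$concentration,
               time_s = round(tr$timestamps, 2),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(subject_id = character(0), session_day = integer(0),
                     concentration = numeric(0), time_s = numeric(0))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Header fields accepted in MED-PC text data files.
.medpc_headers <- c("File", "Start Date", "End Date", "Subject", "Experiment",
                    "Group", "Box", "Start Time", "End Time", "MSN")

#' Read a MED-PC text data file
#'
#' Parses the common single-session MED-PC text layout: header lines
#' (\code{Start Date:}, \code{Subject:}, \code{Box:}, ...) followed by named
#' numeric arrays, printed five elements per line behind a leading index
#' field (\code{"     0:"}). Files holding several sessions back to back are
#' split on repeated \code{Start Date:} headers.
#'
#' The acquisition configuration decides which array letter holds lick
#' times and the tick size; neither is knowable from the file itself, so
#' both are arguments with documented defaults (first array, 0.01 s/tick).
#'
#' @param path MED-PC text data file.
#' @param array single letter naming the timestamp array; \code{NULL}
#'   (default) takes the first array in each session block.
#' @param tick seconds per tick used to convert array values to seconds
#'   (default 0.01).
#' @param session_duration seconds (default 900).
#' @return list of \code{lick_train}, one per session block.
#' @export
read_medpc_file <- function(path, array = NULL, tick = 0.01,
                            session_duration = 900) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  starts <- nonblank[grepl("^Start Date:", lines[nonblank])]
  if (!length(starts)) stop("no 'Start Date:' header found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))

  lapply(seq_along(starts), function(b) {
    block <- lines[starts[b]:ends[b]]
    meta <- list()
    arrays <- list()
    cur <- NULL
    for (i in seq_along(block)) {
      ln <- block[i]
      if (trimws(ln) == "") next
      if (grepl("^[A-Za-z][A-Za-z ]*:", ln) && !grepl("^\\s", ln)) {
        fld <- sub(":.*$", "", ln)
        val <- trimws(sub("^[^:]*:", "", ln))
        if (grepl("^[A-Z]$", fld)) {          # array header or scalar variable
          cur <- fld
          arrays[[cur]] <- numeric(0)
          if (nzchar(val)) {                   # scalar form "A:   5.000"
            v <- suppressWarnings(as.numeric(val))
            if (is.na(v)) stop("non-numeric value for variable ", fld,
                               " at line ", starts[b] + i - 1L)
            arrays[[cur]] <- v
            cur <- NULL
          }
        } else if (fld %in% .medpc_headers) {
          meta[[fld]] <- val
          cur <- NULL
        } else {
          stop("unrecognized header '", fld, "' at line ", starts[b] + i - 1L)
        }
      } else if (grepl("^\\s+\\d+:", ln)) {    # element line "     0:  10  20"
        if (is.null(cur)) stop("array element line outside an array at line ",
                               starts[b] + i - 1L)
        vals <- strsplit(trimws(sub("^\\s+\\d+:", "", ln)), "\\s+")[[1L]]
        vals <- vals[nzchar(vals)]
        num <- suppressWarnings(as.numeric(vals))
        if (anyNA(num)) stop("non-numeric array element at line ", starts[b] + i - 1L)
        arrays[[cur]] <- c(arrays[[cur]], num)
      } else {
        stop("unparseable line ", starts[b] + i - 1L, ": ", ln)
      }
    }
    if (!length(arrays)) stop("no data arrays in session block ", b)
    sel <- if (is.null(array)) names(arrays)[1L] else array
    if (!sel %in% names(arrays)) {
      stop("array '", sel, "' not present (found: ",
           paste(names(arrays), collapse = ", "), ")")
    }
    ts <- sort(arrays[[sel]] * tick)
    lick_train(subject_id = if (!is.null(meta$Subject)) meta$Subject else "unknown",
               timestamps = round(ts, 10),
               session_duration = session_duration,
               resolution = tick)
  })
}

#' Write a MED-PC style text data file
#'
#' Emits the single-session layout \code{\link{read_medpc_file}} reads:
#' headers, then array \code{A} holding timestamps in ticks, five elements
#' per line. Mostly useful to build parser fixtures and round-trip tests.
#'
#' @param trains list of \code{lick_train}.
#' @param path output file.
#' @param tick seconds per tick (default 0.01).
#' @return \code{path}, invisibly.
#' @export
write_medpc_file <- function(trains, path, tick = 0.01) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in trains) {
    writeLines(c(sprintf("Start Date: %s", format(Sys.Date(), "%m/%d/%y")),
                 sprintf("Subject: %s", tr$subject_id),
                 "Box: 1",
                 "A:"), con)
    ticks <- round(tr$timestamps / tick)
    if (length(ticks)) {
      idx <- seq(0L, length(ticks) - 1L, by = 5L)
      for (i in idx) {
        chunk <- ticks[(i + 1L):min(i + 5L, length(ticks))]
        writeLines(sprintf("%8s%s", paste0(i, ":"),
                           paste(sprintf("%12d", as.integer(chunk)), collapse = "")),
                   con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read the subject metadata table
#'
#' @param path CSV with columns \code{subject_id}, \code{cage_id},
#'   \code{handling} and optionally \code{body_weight}, \code{testing_group}.
#'   A missing weight column is tolerated; weight-adjusted analyses then
#'   refuse those subjects downstream.
#' @return \code{\link{subject_records}} data.frame.
#' @export
read_metadata_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  subject_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read the consumption table
#'
#' @param path CSV with columns \code{subject_id}, \code{session_day},
#'   \code{concentration}, \code{mass_consumed}.
#' @return \code{\link{consumption_records}} data.frame.
#' @export
read_consumption_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  consumption_records(utils::read.csv(path, stringsAsFactors = FALSE))
}
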