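#' Construct a lick train
#'
#' A lick train holds the ordered lick timestamps of one subject-session
#' together with its metadata. Contact lickometers report the time of each
#' spout contact to the nearest 0.01 s; timestamps are stored in seconds as
#' doubles and the device resolution is validated rather than enforced by an
#' integer type, so synthetic and recorded data travel the same path.
#'
#' Duplicate timestamps (two contacts within the same 0.01 s tick) are kept
#' as two licks: the sensor reports discrete contacts and merging them would
#' bias cluster sizes downward.
#'
#' @param subject_id character scalar identifying the animal.
#' @param timestamps numeric vector of lick times in seconds, non-decreasing.
#' @param session_day integer study day.
#' @param concentration sucrose concentration, percent w/w (e.g. 4 or 16).
#' @param session_duration session length in seconds (default 900 = 15 min).
#' @param resolution device tick size in seconds (default 0.01).
#' @return An object of class \code{lick_train}.
#' @examples
#' tr <- lick_train("m01", c(0.10, 0.20, 0.35), session_day = 22,
#'                  concentration = 4)
#' n_licks(tr)
#' @export
lick_train <- function(subject_id, timestamps = numeric(0), session_day = NA_integer_,
                       concentration = NA_real_, session_duration = 900,
                       resolution = 0.01) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  timestamps <- as.numeric(timestamps)
  x <- structure(
    list(subject_id = subject_id,
         session_day = as.integer(session_day),
         concentration = as.numeric(concentration),
         timestamps = timestamps,
         session_duration = as.numeric(session_duration),
         resolution = as.numeric(resolution)),
    class = "lick_train")
  validate_lick_train(x)
}

#' Validate a lick train
#'
#' Checks the invariants: timestamps non-decreasing, inside
#' \code{[0, session_duration]}, and on the device resolution grid
#' (to a 1e-9 rounding tolerance).
#'
#' @param x a \code{lick_train}.
#' @return \code{x}, invisibly unchanged, or an error.
#' @export
validate_lick_train <- function(x) {
  ts <- x$timestamps
  if (length(ts)) {
    if (anyNA(ts)) stop("lick_train '", x$subject_id, "': NA timestamps")
    if (is.unsorted(ts)) {
      stop("lick_train '", x$subject_id, "': timestamps must be non-decreasing")
    }
    if (min(ts) < 0 || max(ts) > x$session_duration) {
      stop("lick_train '", x$subject_id, "': timestamps outside [0, ",
           x$session_duration, "]")
    }
    off <- abs(ts / x$resolution - round(ts / x$resolution))
    if (any(off > 1e-6)) {
      stop("lick_train '", x$subject_id, "': timestamps off the ",
           x$resolution, " s resolution grid")
    }
  }
  x
}

#' Number of licks in a train
#' @param x a \code{lick_train}.
#' @return integer lick count.
#' @export
n_licks <- function(x) length(x$timestamps)

#' @export
print.lick_train <- function(x, ...) {
  cat(sprintf("lick_train: subject %s, day %s, %s%% sucrose, %d licks / %g s\n",
              x$subject_id,
              ifelse(is.na(x$session_day), "?", x$session_day),
              ifelse(is.na(x$concentration), "?", format(x$concentration)),
              n_licks(x), x$session_duration))
  invisible(x)
}

#' Construct subject metadata records
#'
#' Validates the experiment metadata table: one row per mouse with cage,
#' handling group (\code{tail} or \code{tunnel}), body weight and testing
#' group. Both mice of a cage must share handling method and testing group
#' (cage-level random assignment).
#'
#' @param df data.frame with columns \code{subject_id}, \code{cage_id},
#'   \code{handling}, and optionally \code{body_weight} (grams) and
#'   \code{testing_group}.
#' @return validated data.frame of class \code{subject_records}.
#' @export
subject_records <- function(df) {
  need <- c("subject_id", "cage_id", "handling")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$cage_id <- as.character(df$cage_id)
  df$handling <- as.character(df$handling)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicated subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$handling), c("tail", "tunnel"))
  if (length(bad)) {
    stop("handling must be 'tail' or 'tunnel'; found: ", paste(bad, collapse = ", "))
  }
  if (!"body_weight" %in% names(df)) df$body_weight <- NA_real_
  if (!"testing_group" %in% names(df)) df$testing_group <- NA_integer_
  for (cg in unique(df$cage_id)) {
    sub <- df[df$cage_id == cg, ]
    if (length(unique(sub$handling)) > 1L) {
      stop("cage ", cg, " mixes handling methods: both mice of a cage share handling")
    }
    tg <- unique(sub$testing_group[!is.na(sub$testing_group)])
    if (length(tg) > 1L) stop("cage ", cg, " mixes testing groups")
  }
  class(df) <- c("subject_records", "data.frame")
  df
}

#' Construct consumption records
#'
#' One row per subject-session with the mass of sucrose solution consumed.
#'
#' @param df data.frame with columns \code{subject_id}, \code{session_day},
#'   \code{concentration}, \code{mass_consumed} (grams, >= 0).
#' @return validated data.frame of class \code{consumption_records}.
#' @export
consumption_records <- function(df) {
  need <- c("subject_id", "session_day", "concentration", "mass_consumed")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("consumption table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  m <- df$mass_consumed
  if (any(!is.finite(m)) || any(m < 0)) {
    bad <- which(!is.finite(m) | m < 0)
    stop("mass_consumed must be finite and non-negative; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  key <- paste(df$subject_id, df$session_day, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, day) consumption records")
  }
  class(df) <- c("consumption_records", "data.frame")
  df
}
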