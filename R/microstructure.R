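#' Segment a lick train into clusters
#'
#' Applies the interbout-interval rule: a gap of \code{interbout_interval}
#' seconds \emph{or longer} between two licks ends one cluster and starts
#' the next, so a gap exactly equal to the threshold splits. Every lick
#' belongs to exactly one cluster; an empty train yields zero clusters.
#'
#' Gaps are rounded to the device resolution (0.01 s) before comparison, so
#' floating-point noise of the order 1e-12 around the threshold cannot flip
#' a boundary decision.
#'
#' @param train a \code{\link{lick_train}}.
#' @param interbout_interval threshold in seconds (default 0.250).
#' @return data.frame of class \code{lick_clusters} with one row per
#'   cluster: \code{start_index}, \code{end_index} (inclusive), \code{size},
#'   \code{start_time}, \code{end_time}.
#' @examples
#' tr <- lick_train("m01", c(0.00, 0.10, 0.20, 0.60, 0.70))
#' segment_clusters(tr)$size   # 3 2
#' @export
segment_clusters <- function(train, interbout_interval = 0.250) {
  stopifnot(inherits(train, "lick_train"), interbout_interval > 0)
  ts <- train$timestamps
  if (is.unsorted(ts)) stop("timestamps must be sorted before segmentation")
  empty <- data.frame(start_index = integer(0), end_index = integer(0),
                      size = integer(0), start_time = numeric(0),
                      end_time = numeric(0))
  class(empty) <- c("lick_clusters", "data.frame")
  if (!length(ts)) return(empty)
  res <- train$resolution
  gaps <- round(diff(ts) / res) * res
  brk <- which(gaps >= interbout_interval - res * 1e-6)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(ts))
  out <- data.frame(start_index = starts, end_index = ends,
                    size = ends - starts + 1L,
                    start_time = ts[starts], end_time = ts[ends])
  class(out) <- c("lick_clusters", "data.frame")
  out
}

#' Summarize one session's lick microstructure
#'
#' Runs \code{\link{segment_clusters}} and collects the per-session
#' statistics used by the downstream analyses: total licks, cluster count,
#' cluster sizes and their mean. Sessions with zero licks are flagged, not
#' errors: their \code{mean_cluster_size} is \code{NA}.
#'
#' @param train a \code{\link{lick_train}}.
#' @param interbout_interval threshold in seconds (default 0.250).
#' @param min_cluster_size smallest cluster counted (default 1). The rule
#'   defines clusters purely by gaps, so singletons count by default; the
#'   common >=3-lick convention is available for sensitivity analysis.
#' @return object of class \code{microstructure_summary}: a list with
#'   \code{subject_id}, \code{session_day}, \code{concentration},
#'   \code{interbout_interval}, \code{total_licks}, \code{n_clusters},
#'   \code{cluster_sizes}, \code{mean_cluster_size}.
#' @export
summarize_session <- function(train, interbout_interval = 0.250,
                              min_cluster_size = 1L) {
  cl <- segment_clusters(train, interbout_interval)
  sizes <- cl$size[cl$size >= min_cluster_size]
  structure(
    list(subject_id = train$subject_id,
         session_day = train$session_day,
         concentration = train$concentration,
         interbout_interval = interbout_interval,
         total_licks = n_licks(train),
         n_clusters = length(sizes),
         cluster_sizes = sizes,
         mean_cluster_size = if (length(sizes)) mean(sizes) else NA_real_),
    class = "microstructure_summary")
}

#' @export
print.microstructure_summary <- function(x, ...) {
  cat(sprintf(
    "session %s day %s (%s%%): %d licks, %d clusters, mean size %s (ici %g s)\n",
    x$subject_id, ifelse(is.na(x$session_day), "?", x$session_day),
    ifelse(is.na(x$concentration), "?", format(x$concentration)),
    x$total_licks, x$n_clusters,
    ifelse(is.na(x$mean_cluster_size), "NA", sprintf("%.2f", x$mean_cluster_size)),
    x$interbout_interval))
  invisible(x)
}

#' Collect session summaries into a long data.frame
#'
#' @param summaries list of \code{microstructure_summary} objects.
#' @return data.frame with one row per session.
#' @export
summaries_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(subject_id = s$subject_id, session_day = s$session_day,
               concentration = s$concentration,
               interbout_interval = s$interbout_interval,
               total_licks = s$total_licks, n_clusters = s$n_clusters,
               mean_cluster_size = s$mean_cluster_size,
               stringsAsFactors = FALSE)
  }))
}

#' Engagement filter
#'
#' The training-phase engagement criterion keeps sessions in which the
#' animal was consistently drinking, defined as strictly more than
#' \code{min_licks} licks. Filtered sessions are flagged and reported, never
#' silently dropped.
#'
#' @param summaries list of \code{microstructure_summary} objects.
#' @param min_licks threshold; a session is kept iff
#'   \code{total_licks > min_licks} (default 100).
#' @return list with elements \code{kept} (list of summaries) and
#'   \code{flagged} (data.frame of subject, day, total_licks, reason).
#' @export
engagement_filter <- function(summaries, min_licks = 100L) {
  stopifnot(min_licks >= 0)
  keep <- vapply(summaries, function(s) s$total_licks > min_licks, logical(1))
  flagged <- do.call(rbind, lapply(summaries[!keep], function(s) {
    data.frame(subject_id = s$subject_id, session_day = s$session_day,
               total_licks = s$total_licks,
               reason = sprintf("total_licks <= %d", as.integer(min_licks)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(flagged)) {
    flagged <- data.frame(subject_id = character(0), session_day = integer(0),
                          total_licks = integer(0), reason = character(0))
  }
  list(kept = summaries[keep], flagged = flagged)
}

#' Per-animal means across sessions
#'
#' Aggregates daily session values to one value per (subject,
#' concentration): the unweighted mean of the daily per-session mean
#' cluster sizes across the five days at each concentration
#' (mean-of-session-means, not pooled licks). Sessions with no licks
#' (\code{NA} mean) are excluded from the mean with a message; a subject
#' with zero valid sessions at a concentration gets \code{NA} there and a
#' warning, so paired analyses can drop it explicitly.
#'
#' @param summaries list of \code{microstructure_summary} objects or a
#'   data.frame from \code{\link{summaries_table}}.
#' @param pooled if \code{TRUE}, pool all clusters across sessions instead
#'   of averaging session means (off by default; only available when
#'   summaries are passed as objects).
#' @return data.frame with \code{subject_id}, \code{concentration},
#'   \code{mean_cluster_size}, \code{mean_total_licks}, \code{n_sessions}.
#' @export
subject_means <- function(summaries, pooled = FALSE) {
  if (is.data.frame(summaries)) {
    if (pooled) stop("pooled aggregation needs summary objects, not a table")
    tab <- summaries
  } else {
    tab <- summaries_table(summaries)
  }
  key <- interaction(tab$subject_id, tab$concentration, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(tab)), key), function(idx) {
    sub <- tab[idx, ]
    ok <- !is.na(sub$mean_cluster_size)
    if (any(!ok)) {
      message("subject ", sub$subject_id[1], " at ", sub$concentration[1],
              "%: ", sum(!ok), " empty session(s) excluded from the mean")
    }
    if (!any(ok)) {
      warning("subject ", sub$subject_id[1], " has no valid session at ",
              sub$concentration[1], "%; value set NA")
    }
    mcs <- if (pooled && !is.data.frame(summaries)) {
      sizes <- unlist(lapply(summaries[idx], `[[`, "cluster_sizes"))
      if (length(sizes)) mean(sizes) else NA_real_
    } else if (any(ok)) mean(sub$mean_cluster_size[ok]) else NA_real_
    data.frame(subject_id = sub$subject_id[1],
               concentration = sub$concentration[1],
               mean_cluster_size = mcs,
               mean_total_licks = mean(sub$total_licks[ok]),
               n_sessions = sum(ok),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$subject_id, out$concentration), , drop = FALSE]
}

#' Interbout-interval robustness sweep
#'
#' Re-segments every train at each threshold and returns a long table, one
#' row per train per threshold, so the downstream ANOVA can be re-run
#' per threshold to check that conclusions do not hinge on the 250 ms
#' convention.
#'
#' @param trains list of \code{\link{lick_train}} objects.
#' @param thresholds numeric vector of interbout intervals in seconds
#'   (default \code{c(0.25, 0.5, 1)}).
#' @return long data.frame: subject, day, concentration, threshold,
#'   total_licks, n_clusters, mean_cluster_size.
#' @export
sweep_thresholds <- function(trains, thresholds = c(0.25, 0.5, 1)) {
  stopifnot(all(thresholds > 0))
  out <- do.call(rbind, lapply(thresholds, function(th) {
    tab <- summaries_table(lapply(trains, summarize_session,
                                  interbout_interval = th))
    names(tab)[names(tab) == "interbout_interval"] <- "threshold"
    tab
  }))
  rownames(out) <- NULL
  out
}
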