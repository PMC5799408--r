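#' Per-animal mean consumption
#'
#' Unweighted mean of the daily masses consumed across the sessions at each
#' concentration. A subject-concentration cell with fewer sessions than the
#' modal count triggers a warning (a missing day); all-zero masses are
#' flagged as a non-drinker.
#'
#' @param records \code{\link{consumption_records}} data.frame.
#' @return data.frame with \code{subject_id}, \code{concentration},
#'   \code{mean_mass} (g), \code{n_sessions}, \code{non_drinker}.
#' @export
mean_consumption <- function(records) {
  records <- consumption_records(as.data.frame(records))
  key <- interaction(records$subject_id, records$concentration, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(sub) {
    data.frame(subject_id = sub$subject_id[1],
               concentration = sub$concentration[1],
               mean_mass = mean(sub$mass_consumed),
               n_sessions = nrow(sub),
               non_drinker = all(sub$mass_consumed == 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  full <- max(out$n_sessions)
  short <- out$n_sessions < full
  if (any(short)) {
    warning(sum(short), " subject-concentration cell(s) have fewer than ",
            full, " sessions; means use the available days")
  }
  if (any(out$non_drinker)) {
    warning("non-drinker (all-zero masses): ",
            paste(out$subject_id[out$non_drinker], collapse = ", "))
  }
  out[order(out$subject_id, out$concentration), , drop = FALSE]
}

#' Body-weight-adjusted consumption
#'
#' Divides each subject's mean mass by its body weight, giving grams
#' consumed per gram of body weight. Subjects with missing or non-positive
#' weight are excluded with a warning. Because this is a per-subject
#' rescaling, re-running the mixed ANOVA on the per-gram variable controls
#' for body weight; when all weights are equal the F statistics are
#' identical to the raw analysis (F is invariant to a common scale factor).
#'
#' @param summaries output of \code{\link{mean_consumption}}.
#' @param subjects \code{\link{subject_records}} with \code{body_weight}.
#' @return \code{summaries} restricted to weighed subjects, with an added
#'   \code{mass_per_gram_bw} column (g consumed / g body weight).
#' @export
weight_adjusted <- function(summaries, subjects) {
  stopifnot(is.data.frame(summaries), is.data.frame(subjects))
  w <- subjects$body_weight[match(summaries$subject_id, subjects$subject_id)]
  usable <- !is.na(w) & w > 0
  if (any(!usable)) {
    warning("excluding ", length(unique(summaries$subject_id[!usable])),
            " subject(s) with missing or non-positive body weight; n = ",
            length(unique(summaries$subject_id[usable])), " remain")
  }
  out <- summaries[usable, , drop = FALSE]
  out$mass_per_gram_bw <- out$mean_mass / w[usable]
  out
}
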