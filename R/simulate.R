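#' Simulation configuration
#'
#' Full parameterization of the synthetic sucrose-drinking experiment: a
#' two-group (tail vs tunnel handling) by two-concentration (4 vs 16
#' percent w/w) counterbalanced crossover with \code{sessions_per_phase}
#' daily 15-minute sessions per phase. Lick trains are generated as an
#' alternating renewal process: a cluster of licks at the rodent lick
#' rhythm (within-cluster inter-lick interval around 0.125 s, about 8 Hz),
#' then a pause longer than the interbout-interval threshold, repeated
#' until the session's drinking-time budget is spent.
#'
#' Feasibility is enforced at construction: generated pauses are
#' \code{pause_shift + Exp(pause_mean)} with \code{pause_shift >=
#' interbout_interval}, so every pause splits clusters; within-cluster
#' intervals are truncated to \code{[ili_min, interbout_interval - 0.01]},
#' one device tick below the threshold, so that after 0.01 s quantization
#' a generated cluster can never split. Segmenting a synthetic train at
#' the configured threshold therefore recovers the generator's clusters
#' exactly.
#'
#' @param n_per_group mice per handling group (default 16; must be even
#'   for counterbalancing).
#' @param sessions_per_phase drinking sessions per concentration phase
#'   (default 5).
#' @param session_duration seconds (default 900).
#' @param interbout_interval cluster threshold the data are generated to
#'   respect, seconds (default 0.25).
#' @param ili_mean,ili_sd within-cluster inter-lick interval mean and sd,
#'   seconds (defaults 0.125 and 0.02).
#' @param ili_min lower truncation of the within-cluster interval
#'   (default 0.05).
#' @param pause_shift minimum pause between clusters, seconds (default
#'   0.25; must be >= \code{interbout_interval}).
#' @param pause_mean mean of the exponential pause excess, seconds
#'   (default 2).
#' @param cluster_size_mean 2x2 numeric matrix of mean cluster sizes,
#'   rows \code{tail}/\code{tunnel}, columns \code{"4"}/\code{"16"}.
#' @param cluster_size_dispersion negative-binomial size parameter of the
#'   shifted cluster-size distribution (default 8; smaller = longer tail;
#'   0 switches to degenerate clusters of exactly \code{round(mean)} licks,
#'   useful to verify that segmentation inverts the generator).
#' @param volume_per_lick grams of solution per lick (default 0.0015).
#' @param consumption_noise_sd measurement noise on session mass, grams
#'   (default 0.08).
#' @param drinking_fraction 2x2 matrix, expected fraction of the session
#'   spent in the lick/pause process, same dimnames as
#'   \code{cluster_size_mean}.
#' @param subject_cv coefficient of variation of stable between-animal
#'   multipliers (lognormal, mean 1) applied to an animal's cluster-size
#'   mean and drinking fraction across all its sessions (default 0.08).
#'   Real cohorts show stable animal-level differences in palatability
#'   response and task engagement; a common multiplier acts as a pure
#'   subject effect, absorbed by the subject stratum of the mixed ANOVA,
#'   and leaves condition means unbiased. Set 0 to disable.
#' @param body_weight_mean,body_weight_sd grams (defaults 24.6 and 1.6).
#' @param seed master seed; expanded into per-subject substreams so
#'   adding subjects never perturbs existing subjects' data.
#' @return object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_per_group = 16L,
                       sessions_per_phase = 5L,
                       session_duration = 900,
                       interbout_interval = 0.25,
                       ili_mean = 0.125, ili_sd = 0.02, ili_min = 0.05,
                       pause_shift = 0.25, pause_mean = 2,
                       cluster_size_mean = matrix(5, 2, 2,
                         dimnames = list(c("tail", "tunnel"), c("4", "16"))),
                       cluster_size_dispersion = 8,
                       volume_per_lick = 0.0015,
                       consumption_noise_sd = 0.08,
                       drinking_fraction = matrix(0.35, 2, 2,
                         dimnames = list(c("tail", "tunnel"), c("4", "16"))),
                       subject_cv = 0.08,
                       body_weight_mean = 24.6, body_weight_sd = 1.6,
                       seed = 1L) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              sessions_per_phase = as.integer(sessions_per_phase),
              session_duration = session_duration,
              interbout_interval = interbout_interval,
              ili_mean = ili_mean, ili_sd = ili_sd, ili_min = ili_min,
              pause_shift = pause_shift, pause_mean = pause_mean,
              cluster_size_mean = cluster_size_mean,
              cluster_size_dispersion = cluster_size_dispersion,
              volume_per_lick = volume_per_lick,
              consumption_noise_sd = consumption_noise_sd,
              drinking_fraction = drinking_fraction,
              subject_cv = subject_cv,
              body_weight_mean = body_weight_mean,
              body_weight_sd = body_weight_sd,
              seed = as.integer(seed))
  if (cfg$ili_mean >= cfg$interbout_interval) {
    stop("infeasible config: mean within-cluster interval (", cfg$ili_mean,
         " s) must be below the interbout interval (", cfg$interbout_interval, " s)")
  }
  if (cfg$pause_shift < cfg$interbout_interval) {
    stop("infeasible config: pause_shift must be >= interbout_interval, ",
         "otherwise generated pauses would not split clusters")
  }
  if (cfg$ili_min >= cfg$interbout_interval - 0.01) {
    stop("infeasible config: ili_min must be below interbout_interval - 0.01")
  }
  for (nm in c("cluster_size_mean", "drinking_fraction")) {
    m <- cfg[[nm]]
    if (!is.matrix(m) || !all(rownames(m) == c("tail", "tunnel")) ||
        !all(colnames(m) == c("4", "16"))) {
      stop(nm, " must be a 2x2 matrix with rows tail/tunnel and columns 4/16")
    }
    if (any(m <= 0)) stop(nm, " entries must be > 0")
  }
  if (any(cfg$drinking_fraction > 1)) stop("drinking_fraction must be <= 1")
  if (cfg$subject_cv < 0) stop("subject_cv must be >= 0")
  if (any(cfg$cluster_size_mean < 1)) stop("cluster_size_mean must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", 2 * x$n_per_group, "mice,", x$sessions_per_phase,
      "sessions/phase x 2 phases,", x$session_duration, "s sessions\n")
  cat("cluster size means (tail/tunnel x 4/16%):\n")
  print(x$cluster_size_mean)
  invisible(x)
}

#' Condition preset reproducing the published effect pattern
#'
#' Returns a \code{\link{sim_config}} whose condition means mirror the
#' qualitative findings of the sucrose drinking experiment: consumption
#' higher at 16 than 4 percent in both groups and higher in tunnel- than
#' tail-handled mice at both concentrations; lick cluster size higher at
#' 16 percent; and a handling gap in cluster size at 4 percent only (a
#' ceiling at 16 percent), which produces the handling-by-concentration
#' interaction. The 4 percent drinking fractions are calibrated so that
#' tail-handled consumption is about 27 percent below tunnel-handled
#' consumption at that concentration.
#'
#' @param seed master seed (default 1).
#' @return a \code{sim_config}.
#' @export
paper_pattern_preset <- function(seed = 1L) {
  sim_config(
    cluster_size_mean = matrix(c(4.0, 5.5,    # 4%:  tail < tunnel
                                 7.0, 7.0),   # 16%: ceiling, no gap
                               2, 2, dimnames = list(c("tail", "tunnel"),
                                                     c("4", "16"))),
    drinking_fraction = matrix(c(0.325, 0.350,
                                 0.380, 0.450),
                               2, 2, dimnames = list(c("tail", "tunnel"),
                                                     c("4", "16"))),
    seed = seed)
}

#' Simulate one lick train
#'
#' Draws complete lick clusters from the alternating renewal process until
#' the session's drinking-time budget (\code{drinking_fraction *
#' session_duration}) is exhausted: cluster size \eqn{K} from a shifted
#' negative binomial (\eqn{1 + NB}, minimum one lick, matching the
#' long-tailed cluster-size distributions of rodent licking), \eqn{K - 1}
#' within-cluster intervals, then one pause. Intervals are quantized to
#' the 0.01 s device grid before accumulation, so timestamps sit on the
#' grid and the segmentation threshold is respected exactly. Only
#' complete clusters are emitted (the process stops before a cluster that
#' would overrun the budget), keeping the session mean cluster size an
#' unbiased estimate of the configured mean.
#'
#' @param config a \code{\link{sim_config}}.
#' @param handling \code{"tail"} or \code{"tunnel"}.
#' @param concentration 4 or 16.
#' @param seed optional integer; when given, seeds the RNG for a
#'   byte-identical train.
#' @param subject_id,session_day metadata stored on the train.
#' @param mu_multiplier,frac_multiplier subject-level multipliers on the
#'   condition's cluster-size mean and drinking fraction (default 1;
#'   \code{\link{simulate_experiment}} draws them once per animal).
#' @return a \code{\link{lick_train}} with attribute \code{n_true_clusters}.
#' @export
simulate_lick_train <- function(config, handling, concentration, seed = NULL,
                                subject_id = "sim", session_day = NA_integer_,
                                mu_multiplier = 1, frac_multiplier = 1) {
  stopifnot(inherits(config, "sim_config"),
            handling %in% c("tail", "tunnel"),
            as.character(concentration) %in% c("4", "16"))
  if (!is.null(seed)) set.seed(seed)
  mu_k <- max(1.05, config$cluster_size_mean[handling, as.character(concentration)] *
                mu_multiplier)
  frac <- min(1, config$drinking_fraction[handling, as.character(concentration)] *
                frac_multiplier)
  budget <- frac * config$session_duration

  exp_cycle <- (mu_k - 1) * config$ili_mean + config$pause_shift + config$pause_mean
  sizes <- integer(0); ilis_all <- numeric(0); pauses <- numeric(0)
  repeat {
    need <- max(16L, ceiling((budget / exp_cycle) * 1.5) - length(sizes))
    k_new <- if (config$cluster_size_dispersion <= 0) {
      rep(max(1L, as.integer(round(mu_k))), need)
    } else {
      1L + stats::rnbinom(need, size = config$cluster_size_dispersion,
                          mu = mu_k - 1)
    }
    ili_new <- stats::rnorm(sum(pmax(k_new - 1L, 0L)), config$ili_mean, config$ili_sd)
    ili_new <- round(pmin(pmax(ili_new, config$ili_min),
                          config$interbout_interval - 0.01), 2)
    p_new <- round(config$pause_shift + stats::rexp(need, 1 / config$pause_mean), 2)
    sizes <- c(sizes, k_new)
    ilis_all <- c(ilis_all, ili_new)
    pauses <- c(pauses, p_new)
    dur <- rep(0, length(sizes))
    has_ili <- sizes > 1L
    if (any(has_ili)) {
      sums <- rowsum(ilis_all, rep(seq_along(sizes), sizes - 1L))
      dur[as.integer(rownames(sums))] <- sums[, 1L]
    }
    starts <- cumsum(c(0, (dur + pauses)[-length(sizes)]))
    fits <- starts + dur <= budget
    if (!all(fits)) break
  }
  keep <- which(cumsum(!fits) == 0)          # complete clusters before the first overrun
  if (!length(keep)) {
    tr <- lick_train(subject_id, numeric(0), session_day = session_day,
                     concentration = as.numeric(concentration),
                     session_duration = config$session_duration)
    attr(tr, "n_true_clusters") <- 0L
    return(tr)
  }
  sizes <- sizes[keep]
  n_ili <- sum(sizes - 1L)
  ilis <- ilis_all[seq_len(n_ili)]
  p_used <- pauses[keep]

  L <- sum(sizes)
  gaps <- numeric(L)
  first <- cumsum(c(1L, sizes[-length(sizes)]))
  gaps[first] <- c(0, p_used[-length(p_used)])
  if (n_ili) gaps[-first] <- ilis
  ts <- round(cumsum(gaps), 2)
  tr <- lick_train(subject_id, ts, session_day = session_day,
                   concentration = as.numeric(concentration),
                   session_duration = config$session_duration)
  attr(tr, "n_true_clusters") <- length(sizes)
  tr
}

# Deterministic per-subject / per-session substream seeds (< 2^31).
.substream_seed <- function(master, subject_index, session_index = 0L) {
  ((as.numeric(master) %% 65521) * 32452843 +
     subject_index * 15485863 + session_index * 2038074743) %% 2147483647 + 1
}

#' Simulate a full counterbalanced crossover experiment
#'
#' Generates the complete synthetic study: two handling groups of
#' \code{n_per_group} mice (pair-housed, cage-level assignment), a
#' counterbalanced two-phase crossover in which half of each handling
#' group drinks 4 percent sucrose in phase 1 and 16 percent in phase 2
#' and half the reverse (phase 1 on study days 22-26, phase 2 on days
#' 29-33), \code{sessions_per_phase} lick trains per phase per mouse, and
#' per-session consumption masses proportional to lick count
#' (\code{total licks x volume_per_lick}) plus Gaussian measurement
#' noise truncated at zero.
#'
#' @param config a \code{\link{sim_config}} (\code{n_per_group} must be
#'   even for counterbalancing).
#' @return object of class \code{synthetic_experiment}: list with
#'   \code{subjects} (\code{\link{subject_records}}), \code{trains}
#'   (list of \code{\link{lick_train}}), \code{consumption}
#'   (\code{\link{consumption_records}}) and \code{ground_truth} (the
#'   configured condition means plus per-session true cluster counts).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_per_group %% 2L != 0L) {
    stop("n_per_group must be even so the concentration order can be counterbalanced")
  }
  n <- config$n_per_group
  handling <- rep(c("tail", "tunnel"), each = n)
  ids <- sprintf("m%02d", seq_len(2L * n))
  cage <- sprintf("c%02d", rep(seq_len(n), each = 2L))
  tgroup <- rep(rep(1:4, length.out = n), each = 2L)[seq_len(2L * n)]
  # counterbalancing: alternate concentration order within each handling group
  order_first4 <- rep(c(TRUE, FALSE), length.out = n)
  order_first4 <- c(order_first4, order_first4)

  # per-subject substream: weight + stable animal-level multipliers
  cv <- config$subject_cv
  sdlog <- sqrt(log(1 + cv^2))
  subj_draw <- t(vapply(seq_len(2L * n), function(i) {
    set.seed(.substream_seed(config$seed, i, 0L))
    c(w = stats::rnorm(1, config$body_weight_mean, config$body_weight_sd),
      mk = if (cv > 0) stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1,
      mf = if (cv > 0) stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1)
  }, numeric(3)))
  weights <- subj_draw[, "w"]

  subjects <- subject_records(data.frame(
    subject_id = ids, cage_id = cage, handling = handling,
    body_weight = round(weights, 1), testing_group = tgroup,
    stringsAsFactors = FALSE))

  days <- list(phase1 = 22:(21 + config$sessions_per_phase),
               phase2 = 29:(28 + config$sessions_per_phase))
  trains <- list()
  cons <- list()
  truth_rows <- list()
  for (i in seq_len(2L * n)) {
    concs <- if (order_first4[i]) c(4, 16) else c(16, 4)
    sess <- 0L
    for (ph in 1:2) {
      for (d in days[[ph]]) {
        sess <- sess + 1L
        sd_seed <- .substream_seed(config$seed, i, sess)
        tr <- simulate_lick_train(config, handling[i], concs[ph], seed = sd_seed,
                                  subject_id = ids[i], session_day = d,
                                  mu_multiplier = subj_draw[i, "mk"],
                                  frac_multiplier = subj_draw[i, "mf"])
        mass <- n_licks(tr) * config$volume_per_lick +
          stats::rnorm(1, 0, config$consumption_noise_sd)
        trains[[length(trains) + 1L]] <- tr
        cons[[length(cons) + 1L]] <- data.frame(
          subject_id = ids[i], session_day = d, concentration = concs[ph],
          mass_consumed = max(0, mass), stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          subject_id = ids[i], session_day = d, concentration = concs[ph],
          handling = handling[i],
          true_n_clusters = attr(tr, "n_true_clusters"),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(subjects = subjects,
         trains = trains,
         consumption = consumption_records(do.call(rbind, cons)),
         ground_truth = list(config = config,
                             cluster_size_mean = config$cluster_size_mean,
                             drinking_fraction = config$drinking_fraction,
                             subject_multipliers = data.frame(
                               subject_id = ids,
                               mu_multiplier = subj_draw[, "mk"],
                               frac_multiplier = subj_draw[, "mf"],
                               stringsAsFactors = FALSE),
                             sessions = do.call(rbind, truth_rows))),
    class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("synthetic_experiment:", nrow(x$subjects), "mice,",
      length(x$trains), "lick trains,", nrow(x$consumption),
      "consumption records\n")
  invisible(x)
}

#' Write a synthetic experiment to disk
#'
#' Writes the metadata CSV, lick CSV, consumption CSV and a ground-truth
#' JSON (plus, optionally, MED-PC style files for parser testing) so the
#' file-reading path can be exercised end to end.
#'
#' @param experiment a \code{synthetic_experiment}.
#' @param dir output directory (created if needed).
#' @param medpc also write one MED-PC style file per train (default
#'   \code{FALSE}).
#' @return named character vector of the files written, invisibly.
#' @export
write_experiment <- function(experiment, dir, medpc = FALSE) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(metadata = file.path(dir, "metadata.csv"),
             licks = file.path(dir, "licks.csv"),
             consumption = file.path(dir, "consumption.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(as.data.frame(experiment$subjects), paths["metadata"],
                   row.names = FALSE, quote = FALSE)
  write_lick_csv(experiment$trains, paths["licks"])
  utils::write.csv(as.data.frame(experiment$consumption), paths["consumption"],
                   row.names = FALSE, quote = FALSE)
  gt <- experiment$ground_truth
  jsonlite::write_json(
    list(cluster_size_mean = gt$cluster_size_mean,
         drinking_fraction = gt$drinking_fraction,
         seed = gt$config$seed),
    paths["ground_truth"], auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  if (medpc) {
    mp <- file.path(dir, "medpc")
    dir.create(mp, showWarnings = FALSE)
    for (tr in experiment$trains) {
      write_medpc_file(list(tr), file.path(mp, sprintf("%s_d%02d.txt",
                                                       tr$subject_id,
                                                       tr$session_day)))
    }
    paths <- c(paths, medpc_dir = mp)
  }
  invisible(paths)
}
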