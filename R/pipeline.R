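# 31-bit multiplicative hash of a deparsed R object; cheap provenance
# fingerprint for configs and input files (not cryptographic).
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}

.file_digest <- function(path) .fnv1a(readLines(path, warn = FALSE))

#' Run the end-to-end drinking analysis
#'
#' Orchestrates ingest, segmentation, summarization and the statistical
#' battery: the consumption ANOVA (handling between, concentration
#' within), its body-weight-adjusted rerun, the lick-cluster-size ANOVA on
#' log-transformed per-animal means with Bonferroni simple-effect
#' comparisons of handling at each concentration, and the
#' interbout-interval robustness sweep. Input data come either from CSV
#' files or from the synthetic generator.
#'
#' @param config a named list, a path to a YAML file with the same
#'   structure, or a \code{\link{sim_config}} (which is wrapped as a
#'   simulation run). Recognised entries: \code{simulate} (a
#'   \code{sim_config} or \code{list(preset = "paper_pattern", seed = )}),
#'   or \code{inputs} (paths \code{licks}, \code{metadata},
#'   \code{consumption}); \code{interbout_interval} (default 0.25);
#'   \code{sweep} (thresholds, default \code{c(0.25, 0.5, 1)});
#'   \code{analyses} (default all four);
#'   \code{engagement_min_licks} (default \code{NULL}: the >100-licks
#'   criterion applies to training-phase sessions, which test-phase
#'   pipelines do not include; set a value to apply it here).
#' @return object of class \code{analysis_report}: provenance
#'   (config hash, seed, input digests) plus one block per analysis.
#' @export
run_pipeline <- function(config) {
  if (inherits(config, "sim_config")) config <- list(simulate = config)
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  ici <- config$interbout_interval %||% 0.25
  sweep_grid <- config$sweep %||% c(0.25, 0.5, 1)
  analyses <- config$analyses %||% c("consumption", "consumption_weight_adjusted",
                                     "cluster_size", "sweep")

  digests <- character(0)
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (!inherits(sim, "sim_config")) {
      preset <- sim$preset %||% "neutral"
      seed <- sim$seed %||% 1L
      sim <- if (identical(preset, "paper_pattern")) paper_pattern_preset(seed = seed)
             else sim_config(seed = seed)
    }
    expt <- simulate_experiment(sim)
    subjects <- expt$subjects
    trains <- expt$trains
    consumption <- expt$consumption
    seed <- sim$seed
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (nm in c("licks", "metadata", "consumption")) {
      if (is.null(inp[[nm]])) stop("config$inputs missing path: ", nm)
    }
    subjects <- read_metadata_table(inp$metadata)
    trains <- read_lick_csv(inp$licks)
    consumption <- read_consumption_table(inp$consumption)
    digests <- vapply(unlist(inp[c("licks", "metadata", "consumption")]),
                      .file_digest, character(1))
    seed <- NA_integer_
  } else {
    stop("config must provide either 'simulate' or 'inputs'")
  }

  summaries <- lapply(trains, summarize_session, interbout_interval = ici)
  if (!is.null(config$engagement_min_licks)) {
    flt <- engagement_filter(summaries, config$engagement_min_licks)
    summaries <- flt$kept
    engagement_flagged <- flt$flagged
  } else {
    engagement_flagged <- NULL
  }
  sm <- subject_means(summaries)
  sm$handling <- subjects$handling[match(sm$subject_id, subjects$subject_id)]
  cons <- mean_consumption(consumption)
  cons$handling <- subjects$handling[match(cons$subject_id, subjects$subject_id)]

  blocks <- list()
  for (an in analyses) {
    blocks[[an]] <- switch(
      an,
      consumption = list(
        design = "handling (between, 2) x concentration (within, 2), unit = mouse",
        n_per_group = length(unique(cons$subject_id[cons$handling == "tail"])),
        transform = "none",
        anova = mixed_anova(cons, unit = "subject_id", between = "handling",
                            within = "concentration", response = "mean_mass")),
      consumption_weight_adjusted = {
        wa <- weight_adjusted(cons, subjects)
        list(design = "as consumption, response in g per g body weight",
             n_per_group = length(unique(wa$subject_id[wa$handling == "tail"])),
             transform = "none",
             anova = mixed_anova(wa, unit = "subject_id", between = "handling",
                                 within = "concentration",
                                 response = "mass_per_gram_bw"))
      },
      cluster_size = list(
        design = "handling (between, 2) x concentration (within, 2), unit = mouse",
        n_per_group = length(unique(sm$subject_id[sm$handling == "tail"])),
        transform = "log",
        anova = mixed_anova(sm, unit = "subject_id", between = "handling",
                            within = "concentration",
                            response = "mean_cluster_size", transform = "log"),
        pairwise = bonferroni_pairwise(
          sm, unit = "subject_id", response = "mean_cluster_size",
          transform = "log",
          comparisons = list(
            list(factor = "handling", levels = c("tunnel", "tail"),
                 at = list(concentration = 4)),
            list(factor = "handling", levels = c("tunnel", "tail"),
                 at = list(concentration = 16))))),
      sweep = {
        tab <- sweep_thresholds(trains, sweep_grid)
        per_thr <- lapply(split(tab, tab$threshold), function(sub) {
          mm <- subject_means(sub[, setdiff(names(sub), "threshold")])
          mm$handling <- subjects$handling[match(mm$subject_id, subjects$subject_id)]
          mixed_anova(mm, unit = "subject_id", between = "handling",
                      within = "concentration", response = "mean_cluster_size",
                      transform = "log")
        })
        list(design = "cluster-size ANOVA re-run per interbout interval",
             thresholds = sweep_grid, per_threshold = per_thr, table = tab)
      },
      stop("unknown analysis '", an, "'"))
  }

  structure(
    list(provenance = list(config_hash = .fnv1a(config), seed = seed,
                           input_digests = digests,
                           interbout_interval = ici),
         subject_means = sm, consumption_means = cons,
         engagement_flagged = engagement_flagged,
         blocks = blocks),
    class = "analysis_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (config ", x$provenance$config_hash,
      ", interbout interval ", x$provenance$interbout_interval, " s)\n\n", sep = "")
  for (nm in names(x$blocks)) {
    b <- x$blocks[[nm]]
    cat("== ", nm, " ==\n", sep = "")
    if (!is.null(b$design)) cat(b$design, "\n")
    if (!is.null(b$anova)) {
      tab <- b$anova[!is.na(b$anova$F), ]
      for (i in seq_len(nrow(tab))) {
        err_df <- b$anova$df[b$anova$effect == tab$error_term[i]]
        cat(sprintf("  %-28s F(%g,%g) = %.3f, p = %s\n", tab$effect[i],
                    tab$df[i], err_df, tab$F[i], .fmt_p(tab$p[i])))
      }
    }
    if (!is.null(b$pairwise)) {
      for (i in seq_len(nrow(b$pairwise))) {
        cat(sprintf("  %-40s t(%g) = %.3f, adj. p = %s\n",
                    b$pairwise$comparison[i], b$pairwise$df[i],
                    b$pairwise$t[i], .fmt_p(b$pairwise$adjusted_p[i])))
      }
    }
    if (!is.null(b$per_threshold)) {
      for (thr in names(b$per_threshold)) {
        a <- b$per_threshold[[thr]]
        ia <- a[grepl(":", a$effect) & !is.na(a$F), ]
        cat(sprintf("  threshold %s s: interaction F = %.3f, p = %s\n",
                    thr, ia$F[1], .fmt_p(ia$p[1])))
      }
    }
    cat("\n")
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' One CSV per ANOVA / pairwise table (full precision) plus a
#' human-readable \code{report.txt} in which p values are rendered to
#' three decimals with a "<0.001" floor. The text body is deterministic
#' for fixed config and inputs (no timestamps).
#'
#' @param report an \code{analysis_report}.
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(report$blocks)) {
    b <- report$blocks[[nm]]
    if (!is.null(b$anova)) {
      p <- file.path(dir, paste0(nm, "_anova.csv"))
      utils::write.csv(as.data.frame(b$anova), p, row.names = FALSE)
      written <- c(written, p)
    }
    if (!is.null(b$pairwise)) {
      p <- file.path(dir, paste0(nm, "_pairwise.csv"))
      utils::write.csv(as.data.frame(b$pairwise), p, row.names = FALSE)
      written <- c(written, p)
    }
    if (!is.null(b$table)) {
      p <- file.path(dir, paste0(nm, "_table.csv"))
      utils::write.csv(b$table, p, row.names = FALSE)
      written <- c(written, p)
    }
  }
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  sink(con)
  on.exit({ sink(); close(con) })
  print(report)
  written <- c(written, txt)
  invisible(written)
}

# Variable -> test mapping for the scored behaviour battery.
.behaviour_map <- list(
  open_arm_entries  = "mann_whitney",
  open_arm_duration = "mann_whitney",
  stretch_attend    = "unpaired_t",
  movement_duration = "unpaired_t",
  centre_duration   = "unpaired_t",
  centre_crosses    = "unpaired_t",
  distance          = "unpaired_t",
  velocity          = "unpaired_t",
  defecated         = "logistic",
  interaction_pct   = "rm_anova")

#' Run the scored-behaviour test battery
#'
#' Applies the conventional test to each pre-scored behavioural variable:
#' Mann-Whitney U for elevated-plus-maze open-arm entries and duration,
#' unpaired t for stretch-attend postures and the open-field metrics,
#' binary logistic regression for defecation, and the repeated-measures
#' ANOVA (handling between; day and pre/post-handling time within) on
#' cage-mean voluntary-interaction scores. Video scoring itself is out of
#' scope: the input is a long table of already-scored values.
#'
#' @param scored long data.frame with columns \code{unit}, \code{group}
#'   (tail/tunnel), \code{variable}, \code{value}, and \code{day} /
#'   \code{time} for the repeated-measures variables.
#' @param tests optional named character vector overriding the default
#'   variable-to-test mapping for the variables present.
#' @return named list of \code{test_result} / \code{anova_table} objects,
#'   one per variable.
#' @export
behavioural_tests <- function(scored, tests = NULL) {
  need <- c("unit", "group", "variable", "value")
  miss <- setdiff(need, names(scored))
  if (length(miss)) stop("scored table missing column(s): ", paste(miss, collapse = ", "))
  map <- .behaviour_map
  if (!is.null(tests)) map[names(tests)] <- as.list(tests)
  out <- list()
  for (v in unique(scored$variable)) {
    if (is.null(map[[v]])) {
      stop("unknown variable '", v, "'; supported: ",
           paste(names(map), collapse = ", "),
           " (or pass an explicit test via 'tests')")
    }
    sub <- scored[scored$variable == v, , drop = FALSE]
    g <- factor(sub$group, levels = c("tail", "tunnel"))
    out[[v]] <- switch(
      map[[v]],
      mann_whitney = mann_whitney_u(sub$value[g == "tail"],
                                    sub$value[g == "tunnel"]),
      unpaired_t = unpaired_t(sub$value[g == "tail"],
                              sub$value[g == "tunnel"]),
      logistic = binary_logistic(sub$value, g),
      rm_anova = {
        if (!all(c("day", "time") %in% names(sub))) {
          stop("variable '", v, "' needs 'day' and 'time' columns for the ",
               "repeated-measures ANOVA")
        }
        mixed_anova(sub, unit = "unit", between = "group",
                    within = c("day", "time"), response = "value")
      },
      stop("unknown test '", map[[v]], "' for variable '", v, "'"))
  }
  out
}
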