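# Shared fixtures and independent oracles, built in code at test time.

# Random lick train on the 0.01 s grid with a mix of short and long gaps.
random_train <- function(n, seed = NULL, duration = 900) {
  if (!is.null(seed)) set.seed(seed)
  gaps <- round(ifelse(runif(n - 1) < 0.7,
                       runif(n - 1, 0.05, 0.30),
                       runif(n - 1, 0.25, 5)), 2)
  ts <- cumsum(c(round(runif(1, 0, 5), 2), gaps))
  lick_train("rnd", ts, session_duration = max(duration, max(ts) + 1))
}

# Deliberately naive O(n^2) segmentation: each lick's cluster id is
# re-derived from scratch by scanning every preceding adjacent gap.
naive_cluster_ids <- function(ts, threshold, res = 0.01) {
  n <- length(ts)
  if (!n) return(integer(0))
  g <- round(diff(ts) / res) * res
  vapply(seq_len(n), function(i) {
    b <- 0L
    j <- 1L
    while (j < i) {
      if (g[j] >= threshold - res * 1e-6) b <- b + 1L
      j <- j + 1L
    }
    b + 1L
  }, integer(1))
}

naive_sizes <- function(ts, threshold) {
  ids <- naive_cluster_ids(ts, threshold)
  if (!length(ids)) return(integer(0))
  as.integer(table(ids))
}

# Independent mixed-ANOVA oracle: base R projection-based least squares
# via aov() with an Error() stratum specification.
oracle_mixed_anova <- function(data, unit, between, within, response) {
  d <- data
  d$.s <- factor(d[[unit]]); d$.b <- factor(d[[between]])
  for (i in seq_along(within)) d[[paste0(".w", i)]] <- factor(d[[within[i]]])
  d$.y <- d[[response]]
  form <- if (length(within) == 1) {
    .y ~ .b * .w1 + Error(.s / .w1)
  } else {
    .y ~ .b * .w1 * .w2 + Error(.s / (.w1 * .w2))
  }
  fit <- stats::aov(form, data = d)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    for (k in seq_along(eff)) {
      if (eff[k] == "Residuals") next
      out[[eff[k]]] <- c(SS = tab[k, "Sum Sq"], df = tab[k, "Df"],
                         F = tab[k, "F value"])
    }
  }
  out
}

# Random balanced mixed-design dataset.
random_mixed_data <- function(n_per_group, within_levels, seed) {
  set.seed(seed)
  units <- sprintf("u%02d", seq_len(2 * n_per_group))
  grp <- rep(c("tail", "tunnel"), each = n_per_group)
  cells <- do.call(expand.grid, c(list(unit = units),
                                  within_levels, stringsAsFactors = FALSE))
  cells$group <- grp[match(cells$unit, units)]
  subj_eff <- stats::rnorm(length(units), sd = 1)
  cells$y <- stats::rnorm(nrow(cells)) + subj_eff[match(cells$unit, units)] +
    2 * (cells$group == "tunnel")
  cells
}

# Map lickstruct effect labels onto the aov oracle's labels.
match_effect <- function(tab, effect) {
  row <- tab[tab$effect == effect, ]
  stopifnot(nrow(row) == 1)
  row
}
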