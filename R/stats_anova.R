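#' Balanced mixed-design (repeated measures) ANOVA
#'
#' Univariate decomposition for a design with one two-level between-subject
#' factor and zero, one or two fully crossed within-subject factors, one
#' observation per unit per within-cell. The between effect is tested
#' against subjects-within-groups; each within effect and its interaction
#' with the between factor are tested against the matching
#' effect-by-subjects-within-groups error stratum. This covers both the
#' 2 x (2) sucrose design (denominator df 30 with 16 mice per group) and
#' the 2 x (6 x 2) voluntary-interaction design on cage means (df 14 with
#' 8 cages per group).
#'
#' Sums of squares are computed by Moebius inversion of marginal cell
#' means, which is exact for balanced data (where Type I/II/III coincide);
#' unbalanced groups or missing within-cells are rejected, not
#' approximated. Sphericity correction is not applied by default so that
#' the uncorrected univariate df are reported; a Greenhouse-Geisser
#' epsilon is available via \code{gg_correction} for within factors with
#' more than two levels.
#'
#' @param data long-format data.frame, one row per unit per within-cell.
#' @param unit column name of the experimental unit (mouse or cage).
#' @param between column name of the between-subject factor (2 levels).
#' @param within character vector of 0-2 within-subject factor columns.
#' @param response column name of the response.
#' @param transform \code{"none"} or \code{"log"} (natural log, applied via
#'   \code{\link{log_transform}} before decomposition).
#' @param gg_correction also report Greenhouse-Geisser adjusted p values
#'   for within effects (default \code{FALSE}, matching uncorrected df).
#' @return object of class \code{anova_table}: a data.frame with one row
#'   per effect and error stratum (\code{effect}, \code{SS}, \code{df},
#'   \code{MS}, \code{F}, \code{p}, \code{error_term}).
#' @examples
#' d <- expand.grid(unit = paste0("m", 1:6), conc = c(4, 16))
#' d$grp <- ifelse(as.integer(sub("m", "", d$unit)) <= 3, "tail", "tunnel")
#' set.seed(1); d$y <- rnorm(nrow(d), 5)
#' mixed_anova(d, unit = "unit", between = "grp", within = "conc",
#'             response = "y")
#' @export
mixed_anova <- function(data, unit, between, within = character(0), response,
                        transform = c("none", "log"), gg_correction = FALSE) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(data), length(within) <= 2L)
  cols <- c(unit, between, within, response)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("data missing column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(.s = factor(data[[unit]]),
                   .b = factor(data[[between]]))
  for (i in seq_along(within)) df[[paste0(".w", i)]] <- factor(data[[within[i]]])
  y <- as.numeric(data[[response]])
  if (any(!is.finite(y))) stop("response contains non-finite values")
  if (transform == "log") y <- log_transform(y)

  wcols <- if (length(within)) paste0(".w", seq_along(within)) else character(0)
  .check_balance(df, wcols, unit, between, within)

  n_total <- length(y)
  a <- nlevels(df$.b)
  subj_per_group <- n_total / a / prod(vapply(wcols, function(w) nlevels(df[[w]]), 1L))

  # Between stratum
  ss_b <- .ss_effect(df, y, ".b")
  df_b <- a - 1L
  ss_s <- .ss_effect(df, y, ".s")       # subjects, crossed decomposition
  ss_sb <- ss_s - ss_b                   # subjects within groups
  df_sb <- a * (subj_per_group - 1)

  rows <- list(
    .anova_row(between, ss_b, df_b, ss_sb / df_sb, df_sb, "subjects-in-groups"),
    .anova_row("subjects-in-groups", ss_sb, df_sb, NA, NA, NA))

  # Within strata: each non-empty subset V of within factors
  subsets <- list()
  if (length(wcols) >= 1L) subsets <- c(subsets, as.list(wcols))
  if (length(wcols) == 2L) subsets <- c(subsets, list(wcols))
  for (V in subsets) {
    lab_v <- paste(within[match(V, wcols)], collapse = ":")
    ss_v <- .ss_effect(df, y, V)
    df_v <- prod(vapply(V, function(w) nlevels(df[[w]]) - 1L, 1L))
    ss_bv <- .ss_effect(df, y, c(".b", V))
    df_bv <- df_b * df_v
    ss_sv <- .ss_effect(df, y, c(".s", V)) - ss_bv   # V x subjects-in-groups
    df_sv <- df_sb * df_v
    ms_err <- ss_sv / df_sv
    err_lab <- paste0(lab_v, ":subjects-in-groups")
    rows <- c(rows, list(
      .anova_row(lab_v, ss_v, df_v, ms_err, df_sv, err_lab),
      .anova_row(paste(between, lab_v, sep = ":"), ss_bv, df_bv, ms_err, df_sv, err_lab),
      .anova_row(err_lab, ss_sv, df_sv, NA, NA, NA)))
  }

  out <- do.call(rbind, rows)
  attr(out, "total_SS") <- sum((y - mean(y))^2)
  attr(out, "n_obs") <- n_total
  attr(out, "transform") <- transform
  if (gg_correction && length(wcols)) {
    out <- .add_gg(out, df, y, wcols, within, between, df_sb)
  }
  class(out) <- c("anova_table", "data.frame")
  out
}

.anova_row <- function(effect, ss, dff, ms_err, df_err, err_lab) {
  ms <- ss / dff
  if (!is.na(err_lab)) {
    f <- if (ss <= .Machine$double.eps^0.75 * max(ss, 1)) 0 else ms / ms_err
    if (!is.finite(f) && ms == 0) f <- 0
    p <- if (f == 0) 1 else stats::pf(f, dff, df_err, lower.tail = FALSE)
  } else {
    f <- NA_real_
    p <- NA_real_
  }
  data.frame(effect = effect, SS = ss, df = dff, MS = ms, F = f, p = p,
             error_term = err_lab, stringsAsFactors = FALSE)
}

# Sum of squares of one effect by Moebius inversion over marginal means.
# For balanced data the per-row effect value is
#   sum over subsets T of facs of (-1)^{|facs|-|T|} * mean over T-margin,
# and the SS is the sum of its squares over rows (replication weights fall
# out because every cell is filled equally).
.ss_effect <- function(df, y, facs) {
  k <- length(facs)
  e <- numeric(length(y))
  for (m in 0:(2^k - 1L)) {
    Tset <- facs[bitwAnd(m, 2^(seq_len(k) - 1L)) > 0]
    mu <- if (!length(Tset)) rep(mean(y), length(y))
          else do.call(stats::ave, c(list(y), unname(df[Tset]), list(FUN = mean)))
    e <- e + (-1)^(k - length(Tset)) * mu
  }
  sum(e^2)
}

.check_balance <- function(df, wcols, unit, between, within) {
  # units nested in groups, equal n per group
  map <- unique(df[c(".s", ".b")])
  if (anyDuplicated(map$.s)) {
    s <- map$.s[duplicated(map$.s)][1]
    stop("unit '", s, "' appears in more than one ", between, " group")
  }
  cnt <- table(map$.b)
  if (length(unique(cnt)) > 1L) {
    stop("unbalanced design: group sizes ",
         paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "),
         "; offending group: ", names(cnt)[which.min(cnt)])
  }
  # every unit observed exactly once per within-cell
  if (length(wcols)) {
    cell <- interaction(df[wcols], drop = FALSE)
    tab <- table(df$.s, cell)
  } else {
    tab <- table(df$.s)
  }
  if (any(tab != 1L)) {
    idx <- which(tab != 1L, arr.ind = TRUE)[1, , drop = TRUE]
    stop("design not complete: unit '", rownames(tab)[idx[1]],
         "' has ", tab[idx[1], idx[2]], " observation(s) in within-cell '",
         colnames(tab)[idx[2]], "' (need exactly 1)")
  }
  invisible(TRUE)
}

# Greenhouse-Geisser epsilon from the covariance of within-cell scores.
.add_gg <- function(out, df, y, wcols, within, between, df_sb) {
  for (i in seq_along(wcols)) {
    w <- wcols[i]
    if (nlevels(df[[w]]) <= 2L) next
    mat <- tapply(y, list(df$.s, df[[w]]), mean)
    S <- stats::cov(mat)
    k <- ncol(S)
    dbar <- mean(diag(S)); mbar <- mean(S)
    eps <- (k^2 * (dbar - mbar)^2) /
      ((k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mbar^2))
    sel <- out$effect %in% c(within[i], paste(between, within[i], sep = ":"))
    err <- out$effect == paste0(within[i], ":subjects-in-groups")
    out$p_gg <- if (is.null(out$p_gg)) NA_real_ else out$p_gg
    out$p_gg[sel] <- stats::pf(out$F[sel], out$df[sel] * eps,
                               out$df[err] * eps, lower.tail = FALSE)
  }
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Mixed-design ANOVA (", attr(x, "n_obs"), " observations",
      if (identical(attr(x, "transform"), "log")) ", log-transformed response",
      ")\n", sep = "")
  tab <- as.data.frame(x)
  tab$SS <- signif(tab$SS, 6); tab$MS <- signif(tab$MS, 6)
  tab$F <- ifelse(is.na(tab$F), "", sprintf("%.3f", tab$F))
  tab$p <- ifelse(is.na(tab$p), "",
                  ifelse(tab$p < 0.001, "<0.001", sprintf("%.3f", tab$p)))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' Follow-up simple-effect comparisons after a mixed ANOVA. Each
#' comparison contrasts two levels of a factor, optionally restricted to
#' one level of another factor (\code{at}), using an unpaired pooled
#' t test when the contrasted factor is between-subject and a paired t
#' test (on within-unit differences) when it is within-subject. The family
#' is the set of comparisons requested here, and the adjusted p value is
#' \code{min(1, m * p)} with m the family size.
#'
#' @param data long-format data.frame as for \code{\link{mixed_anova}}.
#' @param unit experimental-unit column name.
#' @param response response column name.
#' @param comparisons list of comparisons; each a list with \code{factor},
#'   \code{levels} (length 2), optional \code{at} (named value restricting
#'   another factor), and \code{paired} (logical; default \code{FALSE}).
#' @param transform \code{"none"} or \code{"log"}.
#' @return data.frame of class \code{pairwise_table}: one row per
#'   comparison with t, df, p and Bonferroni-adjusted p.
#' @export
bonferroni_pairwise <- function(data, unit, response, comparisons,
                                transform = c("none", "log")) {
  transform <- match.arg(transform)
  if (!length(comparisons)) stop("comparison family is empty")
  m <- length(comparisons)
  y_all <- as.numeric(data[[response]])
  if (transform == "log") y_all <- log_transform(y_all)
  data$.y <- y_all
  rows <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp$levels) == 2L)
    sub <- data
    lab_at <- ""
    if (!is.null(cmp$at)) {
      for (nm in names(cmp$at)) {
        if (!nm %in% names(sub)) stop("unknown factor in 'at': ", nm)
        sub <- sub[sub[[nm]] == cmp$at[[nm]], , drop = FALSE]
      }
      lab_at <- paste0(" at ", paste(names(cmp$at), cmp$at, sep = "=",
                                     collapse = ","))
    }
    fac <- as.character(sub[[cmp$factor]])
    if (!all(cmp$levels %in% fac)) {
      stop("level(s) not present in '", cmp$factor, "': ",
           paste(setdiff(cmp$levels, fac), collapse = ", "))
    }
    x1 <- sub$.y[fac == cmp$levels[1]]
    x2 <- sub$.y[fac == cmp$levels[2]]
    if (isTRUE(cmp$paired)) {
      u1 <- sub[[unit]][fac == cmp$levels[1]]
      u2 <- sub[[unit]][fac == cmp$levels[2]]
      d <- x1[order(u1)] - x2[order(u2)]
      res <- .one_sample_t(d)
    } else {
      res <- unpaired_t(x1, x2)
    }
    data.frame(comparison = paste0(cmp$factor, ": ", cmp$levels[1], " vs ",
                                   cmp$levels[2], lab_at),
               t = res$value, df = res$df, p = res$p,
               adjusted_p = min(1, m * res$p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "family_size") <- m
  class(out) <- c("pairwise_table", "data.frame")
  out
}
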