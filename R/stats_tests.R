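#' Generic test result container
#'
#' @param statistic name of the statistic ("U", "t", "z", "beta").
#' @param value numeric value of the statistic.
#' @param p two-sided p value.
#' @param df degrees of freedom, if applicable.
#' @param n sample sizes (named vector), if applicable.
#' @param method human-readable method label.
#' @param extra named list of additional fields (e.g. coefficients).
#' @return object of class \code{test_result}.
#' @keywords internal
test_result <- function(statistic, value, p, df = NULL, n = NULL,
                        method = "", extra = list()) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  structure(c(list(statistic = statistic, value = value, p = p, df = df,
                   n = n, method = method), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dftxt <- if (!is.null(x$df)) paste0("(", paste(round(x$df, 2), collapse = ","), ")") else ""
  cat(sprintf("%s: %s%s = %.4g, p = %s\n", x$method, x$statistic, dftxt,
              x$value, format.pval(x$p, digits = 3)))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples, with midranks for ties. The
#' reported U is the statistic of the first sample
#' (\eqn{U_1 = R_1 - n_1(n_1+1)/2}); \eqn{U_1 + U_2 = n_1 n_2} always. The
#' exact two-sided p value is computed by enumerating all rank
#' configurations when \code{n1 + n2 <= 20} and there are no ties
#' (\code{mode = "auto"}); otherwise the normal approximation with tie
#' correction and continuity correction is used — the same switch
#' convention as standard statistics packages, so a comparison of 14 vs 15
#' animals uses the normal approximation.
#'
#' @param x,y numeric samples.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal_approx"}.
#' @return \code{test_result} with fields \code{U1}, \code{U2} and the
#'   mode actually used.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p   # exact: 0.3333
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  ties <- anyDuplicated(c(x, y)) > 0
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1

  use_exact <- switch(mode,
                      exact = TRUE,
                      normal_approx = FALSE,
                      auto = (n <= 20 && !ties))
  if (use_exact && ties) {
    warning("exact enumeration with ties treats midranks as fixed; ",
            "p value is conditional on the observed tie pattern")
  }
  if (use_exact) {
    # Distribution of U1 over all C(n, n1) assignments of the observed ranks
    combos <- utils::combn(n, n1)
    rs <- sort(r)
    u_all <- colSums(matrix(rs[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u1 + 1e-9), mean(u_all >= u1 - 1e-9)))
    method <- "Mann-Whitney U (exact)"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
      z <- 0
    } else {
      z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
      if (u1 == mu) z <- 0
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "Mann-Whitney U (normal approximation)"
  }
  test_result("U", u1, p, n = c(n1 = n1, n2 = n2), method = method,
              extra = list(U1 = u1, U2 = u2,
                           mode = if (use_exact) "exact" else "normal_approx"))
}

#' Unpaired (pooled-variance) t test
#'
#' Two-sample Student t with pooled variance and df = n1 + n2 - 2, the
#' form whose df match reported group sizes directly (14 + 16 gives
#' df 28).
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return \code{test_result} with statistic t.
#' @export
unpaired_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance: t statistic undefined")
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  test_result("t", t, 2 * stats::pt(-abs(t), df), df = df,
              n = c(n1 = n1, n2 = n2), method = "Unpaired t-test (pooled)")
}

# One-sample t on a vector (used for paired comparisons on differences).
.one_sample_t <- function(d) {
  n <- length(d)
  stopifnot(n >= 2)
  s <- stats::sd(d)
  if (s <= 0) stop("zero variance of differences: paired t undefined")
  t <- mean(d) / (s / sqrt(n))
  test_result("t", t, 2 * stats::pt(-abs(t), n - 1), df = n - 1,
              n = c(n = n), method = "Paired t-test")
}

#' Binary logistic regression with a two-level predictor
#'
#' Maximum-likelihood fit by iteratively reweighted least squares of
#' \eqn{logit P(y=1) = \beta_0 + \beta_1 [group = g_1]}, with the
#' indicator on the \emph{first} group level so that the slope is the log
#' odds ratio of the first group relative to the second, exactly the 2x2
#' table's \eqn{\log((a/b)/(c/d))}. Complete separation (a group with all
#' or no events) is flagged and no finite estimate is reported.
#'
#' @param outcome binary vector (0/1 or logical), one value per unit.
#' @param group two-level factor or character vector.
#' @return \code{test_result} with the slope as value, Wald z p value and
#'   fields \code{intercept}, \code{slope}, \code{se}, \code{separation}.
#' @examples
#' out <- binary_logistic(c(rep(1, 5), rep(0, 5), rep(1, 2), rep(0, 8)),
#'                        rep(c("A", "B"), each = 10))
#' out$slope   # log((5/5)/(2/8)) = log(4)
#' @export
binary_logistic <- function(outcome, group) {
  y <- as.numeric(outcome)
  stopifnot(all(y %in% c(0, 1)), length(y) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2L) stop("group must have exactly 2 levels")
  tab <- table(g, factor(y, levels = c(0, 1)))
  if (any(tab[, 1] == 0) || any(tab[, 2] == 0)) {
    return(test_result("beta", NA_real_, NA_real_,
                       n = c(n1 = sum(g == levels(g)[1]), n2 = sum(g == levels(g)[2])),
                       method = "Binary logistic regression",
                       extra = list(separation = TRUE,
                                    note = "complete separation: a group has all or no events")))
  }
  X <- cbind(1, as.numeric(g == levels(g)[1]))
  beta <- c(0, 0)
  for (it in 1:50) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    step <- solve(info, crossprod(X, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  se <- sqrt(diag(solve(crossprod(X, X * (stats::plogis(drop(X %*% beta)) *
                                            (1 - stats::plogis(drop(X %*% beta))))))))
  z <- beta[2] / se[2]
  test_result("beta", beta[2], 2 * stats::pnorm(-abs(z)),
              n = c(n1 = sum(g == levels(g)[1]), n2 = sum(g == levels(g)[2])),
              method = "Binary logistic regression",
              extra = list(intercept = beta[1], slope = beta[2],
                           se = se[2], z = z, separation = FALSE))
}

#' Natural log transform with strict positivity check
#'
#' @param values numeric vector, all strictly positive.
#' @param units optional labels used in the error message.
#' @return \code{log(values)}.
#' @export
log_transform <- function(values, units = NULL) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    lab <- if (is.null(units)) paste("index", paste(utils::head(bad, 5), collapse = ", "))
           else paste(utils::head(units[bad], 5), collapse = ", ")
    stop("log transform requires strictly positive values; offending: ", lab)
  }
  log(values)
}

#' Normality and homogeneity-of-variance reports
#'
#' Shapiro-Wilk per group and a Brown-Forsythe (median-centred Levene)
#' test across groups. These are advisory: low p values produce warnings
#' but never switch the analysis automatically — test choice stays
#' explicit in the analysis configuration.
#'
#' @param values numeric response.
#' @param groups grouping factor.
#' @param alpha warning threshold (default 0.05).
#' @return list with \code{shapiro} (per-group p values) and
#'   \code{levene_p}.
#' @export
check_assumptions <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  shp <- vapply(split(values, g), function(v) {
    if (length(unique(v)) < 3 || length(v) < 3 || length(v) > 5000) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  med <- stats::ave(values, g, FUN = stats::median)
  z <- abs(values - med)
  lev <- stats::anova(stats::lm(z ~ g))
  levene_p <- lev$`Pr(>F)`[1]
  if (any(shp < alpha, na.rm = TRUE)) {
    warning("Shapiro-Wilk p < ", alpha, " in group(s): ",
            paste(names(shp)[which(shp < alpha)], collapse = ", "),
            " — consider a transform or a non-parametric test")
  }
  if (isTRUE(levene_p < alpha)) {
    warning("Brown-Forsythe p = ", signif(levene_p, 3),
            ": variances may be heterogeneous")
  }
  list(shapiro = shp, levene_p = levene_p)
}
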