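# Normality-gated group comparisons, sarcomere-length regressions, and the
# pooled-interaction slope-equality test.

#' Compare groups with normality- and variance-gated test selection
#'
#' For two groups: if both pass the Shapiro-Wilk normality test at
#' \code{alpha}, a Student t test is used, switching to Welch's correction
#' when Levene's test indicates unequal variances; otherwise the
#' Mann-Whitney U test. For three or more groups: one-way ANOVA when all
#' groups are normal, otherwise Kruskal-Wallis.
#'
#' @param samples named list of numeric vectors (>= 2 groups, each n >= 3).
#' @param alpha gate significance level (default 0.05).
#' @return list of class \code{groupComparison}: \code{groups},
#'   \code{method} (one of \code{t}, \code{welch_t}, \code{mann_whitney},
#'   \code{anova}, \code{kruskal}), \code{statistic}, \code{p_value},
#'   \code{normality_p} per group, \code{variance_p} (two-group case).
#' @export
compareGroups <- function(samples, alpha = 0.05) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("samples must be a list of >= 2 groups")
  n <- vapply(samples, length, 0L)
  if (any(n < 3L))
    stop("insufficient data: every group needs n >= 3")
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  normP <- vapply(samples, function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate: not testably normal
    stats::shapiro.test(if (length(v) > 5000) sample(v, 5000) else v)$p.value
  }, 0)
  allNormal <- all(normP >= alpha)
  varianceP <- NA_real_
  if (length(samples) == 2L) {
    if (allNormal) {
      g <- factor(rep(names(samples), n))
      v <- unlist(samples, use.names = FALSE)
      varianceP <- car::leveneTest(v ~ g)[1L, "Pr(>F)"]
      welch <- varianceP < alpha
      tt <- stats::t.test(samples[[1L]], samples[[2L]], var.equal = !welch)
      method <- if (welch) "welch_t" else "t"
      statistic <- unname(tt$statistic); p <- tt$p.value
    } else {
      wt <- stats::wilcox.test(samples[[1L]], samples[[2L]], exact = FALSE)
      method <- "mann_whitney"
      statistic <- unname(wt$statistic); p <- wt$p.value
    }
  } else {
    g <- factor(rep(names(samples), n))
    v <- unlist(samples, use.names = FALSE)
    if (allNormal) {
      fit <- stats::aov(v ~ g)
      s <- summary(fit)[[1L]]
      method <- "anova"
      statistic <- s[["F value"]][1L]; p <- s[["Pr(>F)"]][1L]
    } else {
      kt <- stats::kruskal.test(v, g)
      method <- "kruskal"
      statistic <- unname(kt$statistic); p <- kt$p.value
    }
  }
  structure(list(groups = names(samples), method = method,
                 statistic = statistic, p_value = p,
                 normality_p = normP, variance_p = varianceP,
                 alpha = alpha, n = n),
            class = "groupComparison")
}

#' @export
print.groupComparison <- function(x, ...) {
  cat(sprintf("groupComparison [%s]: statistic %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  cat("  groups:", paste(sprintf("%s (n=%d)", x$groups, x$n),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Ordinary least-squares regression of a metric on sarcomere length
#'
#' Fits \code{metric ~ sl_um} over QC-passed measurements restricted to the
#' sarcomere-length window (default 1.8-2.6 um). Excluded measurements
#' (QC failures and out-of-window points) are counted in the result.
#'
#' @param measurements measurement data.frame (from [profileDataset()] or
#'   [profileSarcomeres()]); needs \code{sl_um}, \code{qc_pass} and the
#'   metric column.
#' @param metric metric column name (e.g. \code{"aband_titin_len_nm"},
#'   \code{"dtk_nm"}).
#' @param slRangeUm inclusive SL window in um (default c(1.8, 2.6)).
#' @param group optional group label stored in the result.
#' @param useQc apply the QC filter column (default TRUE).
#' @return list of class \code{lengthRegression}: \code{metric},
#'   \code{group}, \code{slope} (metric units per um), \code{intercept}
#'   (at SL 0), \code{intercept_at_slack} (at SL 1.8 um), \code{se_slope},
#'   \code{se_intercept}, \code{n}, \code{n_excluded_qc},
#'   \code{n_excluded_range}, \code{sl_range}, \code{data}, \code{fit}.
#' @export
fitLengthRegression <- function(measurements, metric,
                                slRangeUm = c(1.8, 2.6), group = NA_character_,
                                useQc = TRUE) {
  if (!metric %in% names(measurements))
    stop("unknown metric column '", metric, "'")
  m <- measurements
  nAll <- nrow(m)
  if (useQc && "qc_pass" %in% names(m)) m <- m[m$qc_pass, , drop = FALSE]
  nQc <- nrow(m)
  tol <- 1e-9
  m <- m[m$sl_um >= slRangeUm[1L] - tol & m$sl_um <= slRangeUm[2L] + tol, ,
         drop = FALSE]
  if (nrow(m) < 3L)
    stop("insufficient data: fewer than 3 QC-passed measurements in the SL window")
  d <- data.frame(sl_um = m$sl_um, y = m[[metric]])
  fit <- stats::lm(y ~ sl_um, data = d)
  co <- summary(fit)$coefficients
  structure(list(
    metric = metric, group = group,
    slope = co["sl_um", "Estimate"],
    intercept = co["(Intercept)", "Estimate"],
    intercept_at_slack = co["(Intercept)", "Estimate"] +
      1.8 * co["sl_um", "Estimate"],
    se_slope = co["sl_um", "Std. Error"],
    se_intercept = co["(Intercept)", "Std. Error"],
    n = nrow(d),
    n_excluded_qc = nAll - nQc,
    n_excluded_range = nQc - nrow(d),
    sl_range = slRangeUm,
    data = d, fit = fit),
    class = "lengthRegression")
}

#' @export
print.lengthRegression <- function(x, ...) {
  cat(sprintf(
    "lengthRegression of %s%s: slope %.3f +/- %.3f per um, intercept at 1.8 um %.2f (n=%d)\n",
    x$metric, if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
    x$slope, x$se_slope, x$intercept_at_slack, x$n))
  invisible(x)
}

#' Test the equality of two sarcomere-length regression slopes
#'
#' Pooled-model interaction test: the two groups' data are stacked and
#' \code{y ~ sl * group} is fitted; the p value of the dummy-coded
#' \code{sl:group} interaction term tests slope equality. The intercept
#' difference at SL 1.8 um is reported as well.
#'
#' @param a,b \code{lengthRegression} results on the same metric.
#' @return list: \code{delta_slope} (b minus a), \code{se_delta_slope},
#'   \code{p_value} (interaction), \code{delta_intercept_at_slack},
#'   \code{p_value_intercept} and the pooled \code{fit}.
#' @export
compareSlopes <- function(a, b) {
  stopifnot(inherits(a, "lengthRegression"), inherits(b, "lengthRegression"))
  if (!identical(a$metric, b$metric))
    stop("regressions compare different metrics: ", a$metric, " vs ", b$metric)
  d <- rbind(
    data.frame(sl = a$data$sl_um, y = a$data$y, grp = 0),
    data.frame(sl = b$data$sl_um, y = b$data$y, grp = 1))
  d$slc <- d$sl - 1.8  # centre at slack so the group term is the slack offset
  fit <- stats::lm(y ~ slc * grp, data = d)
  co <- summary(fit)$coefficients
  list(delta_slope = co["slc:grp", "Estimate"],
       se_delta_slope = co["slc:grp", "Std. Error"],
       p_value = co["slc:grp", "Pr(>|t|)"],
       delta_intercept_at_slack = co["grp", "Estimate"],
       p_value_intercept = co["grp", "Pr(>|t|)"],
       fit = fit)
}

#' Worked intensity-contrast summary of two group means
#'
#' For two group means of a normalised intensity (e.g. the A170/MIR ratio
#' in TTNtv+ and TTNtv- sarcomeres) returns the between-group ratio and
#' the percent reduction.
#'
#' @param meanA affected-group mean (e.g. 0.1765).
#' @param meanB reference-group mean (e.g. 0.2646).
#' @return list with \code{ratio} (meanA/meanB) and \code{pct_reduction}
#'   (100 x (1 - ratio)).
#' @examples
#' intensityRatioSummary(0.1765, 0.2646)  # ratio 0.667, reduction 33.3%
#' @export
intensityRatioSummary <- function(meanA, meanB) {
  if (meanB <= 0) stop("reference mean must be positive")
  r <- meanA / meanB
  list(ratio = r, pct_reduction = 100 * (1 - r))
}
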