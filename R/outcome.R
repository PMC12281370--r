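#' Kaplan-Meier estimate
#'
#' Product-limit estimator for one group. The median is the smallest
#' observed time at which the survival estimate drops to 0.5 or below
#' (undefined, \code{NA}, when the curve never reaches 0.5); the survival
#' rate at a fixed horizon (12 months by default) is reported with its
#' log-transformed 95% CI.
#'
#' @param time follow-up times in months, >= 0.
#' @param event logical/0-1 event indicator (TRUE = death, FALSE =
#'   censored at last follow-up).
#' @param horizon months at which to report the survival rate (default 12).
#' @param conf_level confidence level (default 0.95).
#' @return Object of class \code{"km_curve"}: \code{time}, \code{n_risk},
#'   \code{surv}, \code{lower}, \code{upper}, \code{median},
#'   \code{median_ci}, \code{horizon}, \code{rate_at_horizon}, \code{n},
#'   \code{events}, and the underlying \code{survival::survfit} in
#'   \code{fit}.
#' @examples
#' km_estimate(c(2, 4, 6, 8), c(1, 1, 1, 1))$median  # 4
#' @export
km_estimate <- function(time, event, horizon = 12, conf_level = 0.95) {
  if (any(time < 0, na.rm = TRUE)) stop("negative survival times")
  event <- as.integer(as.logical(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.int = conf_level)
  med <- km_median(fit$time, fit$surv)
  tab <- summary(fit)$table
  rate <- {
    s <- summary(fit, times = horizon, extend = TRUE)
    list(surv = s$surv, lower = s$lower, upper = s$upper)
  }
  structure(list(
    time = fit$time, n_risk = fit$n.risk, surv = fit$surv,
    lower = fit$lower, upper = fit$upper,
    median = med,
    median_ci = c(lower = unname(tab["0.95LCL"]),
                  upper = unname(tab["0.95UCL"])),
    horizon = horizon, rate_at_horizon = rate,
    n = length(time), events = sum(event), fit = fit
  ), class = "km_curve")
}

km_median <- function(time, surv) {
  hit <- surv <= 0.5 + 1e-12
  if (!any(hit)) NA_real_ else min(time[hit])
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d\n", x$n, x$events))
  cat(sprintf("  median %s months (95%% CI %s-%s)\n",
              fmt_num(x$median), fmt_num(x$median_ci[["lower"]]),
              fmt_num(x$median_ci[["upper"]])))
  cat(sprintf("  %g-month survival rate %s (95%% CI %s-%s)\n", x$horizon,
              fmt_num(x$rate_at_horizon$surv, 3),
              fmt_num(x$rate_at_horizon$lower, 3),
              fmt_num(x$rate_at_horizon$upper, 3)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ..., xlab = "Months", ylab = "Survival") {
  plot(x$fit, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

fmt_num <- function(x, digits = 2) {
  if (length(x) == 0 || is.na(x)) "NR" else format(round(x, digits))
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing two survival curves; the
#' p-value is the upper chi-square tail. Degenerate inputs with zero events
#' in both groups combined return statistic 0, p = 1.
#'
#' @param time,event as in \code{\link{km_estimate}}.
#' @param group two-level grouping vector.
#' @return List: \code{statistic} (chi-square), \code{df}, \code{p}.
#' @export
logrank <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("log-rank here compares exactly two groups")
  if (any(table(g) == 0L)) stop("both groups must be non-empty")
  event <- as.integer(as.logical(event))
  if (sum(event) == 0L) return(list(statistic = 0, df = 1L, p = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(statistic = unname(sd$chisq), df = 1L,
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Two-group comparison (exploratory)
#'
#' Continuous variables: Wilcoxon-Mann-Whitney. Categorical (binary)
#' variables: 2x2 test of proportions, Fisher's exact test when any
#' observed or expected cell count is below 5, chi-square otherwise.
#' p-values are exploratory (no multiplicity correction).
#'
#' @param a,b the two groups: numeric vectors (continuous) or
#'   logical/binary vectors (categorical).
#' @param kind \code{"continuous"} or \code{"categorical"}.
#' @return List: \code{method}, \code{statistic}, \code{p}, and for
#'   categorical comparisons \code{proportions}.
#' @export
group_compare <- function(a, b, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  if (kind == "continuous") {
    if (!is.numeric(a) || !is.numeric(b)) stop("continuous comparison needs numeric inputs")
    ht <- stats::wilcox.test(a, b)
    list(method = "Wilcoxon-Mann-Whitney", statistic = unname(ht$statistic),
         p = ht$p.value)
  } else {
    a <- as.logical(a); b <- as.logical(b)
    tab <- rbind(c(sum(a), sum(!a)), c(sum(b), sum(!b)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5) || any(tab < 5)) {
      ht <- stats::fisher.test(tab)
      list(method = "Fisher exact", statistic = unname(ht$estimate),
           p = ht$p.value, proportions = tab[, 1] / rowSums(tab))
    } else {
      ht <- stats::chisq.test(tab)
      list(method = "Chi-square", statistic = unname(ht$statistic),
           p = ht$p.value, proportions = tab[, 1] / rowSums(tab))
    }
  }
}

#' Immune-triad status
#'
#' The vaccine-induced immune triad is the conjunction of a polyfunctional
#' triple+ Th1 immunotype, a positive anti-peptide antibody response, and
#' epitope spreading. Records with any missing component are undetermined
#' (\code{NA}) and are excluded from triad-based grouping.
#'
#' @param immunotype character/factor, \code{"polyF_triple"} marks the
#'   triple+ immunotype.
#' @param ab_positive,spreading_positive logical flags.
#' @return Logical vector (NA where any component is missing).
#' @export
triad_status <- function(immunotype, ab_positive, spreading_positive) {
  triple <- as.character(immunotype) == "polyF_triple"
  out <- triple & as.logical(ab_positive) & as.logical(spreading_positive)
  out[is.na(triple) | is.na(ab_positive) | is.na(spreading_positive)] <- NA
  out
}

#' PCA + k-means immune grouping
#'
#' Z-scores the per-patient feature table, projects it by PCA and clusters
#' with k-means under a fixed seed; labels are deterministic given the
#' seed. Constant feature columns are dropped with a warning; rows with
#' missing values are excluded (complete-case).
#'
#' @param features numeric data.frame/matrix, one row per patient (row
#'   names = patient ids), columns e.g. specific spots, triple+ frequency,
#'   antibody titer, spreading breadth.
#' @param k number of clusters (default 4).
#' @param seed RNG seed for k-means initialization (default 1).
#' @param nstart k-means restarts (default 25).
#' @return List of class \code{"immune_grouping"}: \code{pca}
#'   (\code{prcomp}), \code{cluster} (named integer vector),
#'   \code{centers}, \code{dropped} (constant columns), \code{excluded}
#'   (incomplete rows).
#' @export
immune_group_clustering <- function(features, k = 4, seed = 1, nstart = 25) {
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("features must be numeric")
  cc <- stats::complete.cases(x)
  excluded <- rownames(x)[!cc]
  x <- x[cc, , drop = FALSE]
  if (nrow(x) < 2L) stop("need at least two complete-case patients")
  if (k > nrow(x)) stop("k exceeds the number of patients")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant feature column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("no non-constant features left")
  z <- scale(x)
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart)
  structure(list(pca = pca,
                 cluster = stats::setNames(km$cluster, rownames(x)),
                 centers = km$centers, dropped = dropped,
                 excluded = excluded),
            class = "immune_grouping")
}

#' @export
print.immune_grouping <- function(x, ...) {
  cat(sprintf("Immune grouping: k-means on %d PCA-projected patients, k = %d\n",
              length(x$cluster), nrow(x$centers)))
  print(table(cluster = x$cluster))
  ve <- x$pca$sdev^2 / sum(x$pca$sdev^2)
  cat(sprintf("  PC1/PC2 variance explained: %.1f%% / %.1f%%\n",
              100 * ve[1], 100 * ve[2]))
  invisible(x)
}
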