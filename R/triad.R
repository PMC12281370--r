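#' Join assay calls into a patient-level table
#'
#' Merges the per-module call outputs into one row per patient, the input
#' of the triad classifier and survival association. Patients missing an
#' assay keep \code{NA} there (complete-case handling happens downstream).
#'
#' @param elispot_calls output of \code{\link{call_elispot}}.
#' @param ics_calls output of \code{\link{call_ics}}.
#' @param ab_calls output of \code{\link{call_ab}}.
#' @param spreading_calls output of \code{\link{call_spreading}}.
#' @param survival_df data.frame \code{patient_id}, \code{os_months},
#'   \code{event}.
#' @param baseline baseline timepoint label of the ELISpot table.
#' @return data.frame, one row per patient, with per-peptide responder
#'   flags (\code{responder_<peptide>}), \code{vaccine_responder} (pooled),
#'   \code{peak_specific_spots}, immunotype and triple+ frequency, antibody
#'   and spreading calls, \code{triad}, and survival columns.
#' @export
join_cohort <- function(elispot_calls, ics_calls, ab_calls, spreading_calls,
                        survival_df = NULL, baseline = "baseline") {
  per <- elispot_responders(elispot_calls, baseline = baseline)
  pooled <- attr(per, "pooled")
  wide <- pooled
  names(wide)[2] <- "vaccine_responder"
  for (s in unique(per$stimulus)) {
    d <- per[per$stimulus == s, c("patient_id", "responder")]
    names(d)[2] <- paste0("responder_", s)
    wide <- merge(wide, d, by = "patient_id", all = TRUE)
  }
  peak <- tapply(per$peak_specific_spots, per$patient_id, max)
  wide$peak_specific_spots <- as.numeric(peak[wide$patient_id])

  joined <- merge(wide, ics_calls, by = "patient_id", all = TRUE)
  joined <- merge(joined,
                  ab_calls[, c("patient_id", "ab_positive", "ab_high_titer",
                               "titer_ng_ml")],
                  by = "patient_id", all = TRUE)
  joined <- merge(joined,
                  spreading_calls[, c("patient_id", "spreading_positive",
                                      "breadth")],
                  by = "patient_id", all = TRUE)
  if (!is.null(survival_df))
    joined <- merge(joined, survival_df, by = "patient_id", all.x = TRUE)
  joined$triad <- triad_status(joined$immunotype, joined$ab_positive,
                               joined$spreading_positive)
  joined
}

#' Immune-correlate analysis of a vaccine cohort
#'
#' The integrative fit: runs every assay caller on its table, joins the
#' calls per patient, classifies the vaccine-induced immune triad
#' (polyfunctional triple+ Th1 response AND anti-peptide IgG AND epitope
#' spreading), estimates Kaplan-Meier survival by triad group with a
#' log-rank comparison, and builds the PCA + k-means immune grouping.
#'
#' @param cohort either a \code{\link{generate_cohort}} result or a named
#'   list with elements \code{elispot}, \code{ics}, \code{elisa},
#'   \code{standards}, \code{spreading}, \code{survival} (tables in the
#'   schemas documented at each caller).
#' @param baseline baseline timepoint label.
#' @param k clusters for the immune grouping (capped at the number of
#'   complete-case patients).
#' @param seed seed for the k-means initialization.
#' @param horizon months for the reported survival rate.
#' @return Object of class \code{"triad_analysis"}; see
#'   \code{\link{summary.triad_analysis}}. Main elements: \code{patients}
#'   (joined per-patient table), \code{rates} (responder-rate objects),
#'   \code{km} (per-group \code{km_curve}s), \code{logrank},
#'   \code{grouping}, \code{concurrent_th1} (Fisher/chi-square comparison
#'   of Th1 response by antibody status).
#' @export
triad_analysis <- function(cohort, baseline = "baseline", k = 4, seed = 1,
                           horizon = 12) {
  need <- c("elispot", "ics", "elisa", "standards", "spreading", "survival")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing table(s): ", paste(miss, collapse = ", "))

  calls <- call_elispot(cohort$elispot)
  ics <- call_ics(cohort$ics, baseline = baseline)
  ab <- call_ab(cohort$elisa, cohort$standards, baseline = baseline)
  spr <- call_spreading(cohort$spreading)
  joined <- join_cohort(calls, ics, ab, spr, cohort$survival,
                        baseline = baseline)

  per <- elispot_responders(calls, baseline = baseline)
  rates <- lapply(split(per$responder, per$stimulus), responder_rate)
  rates$pooled <- responder_rate(joined$vaccine_responder)
  rates$antibody <- ab_response_rate(joined$ab_positive)
  rates$spreading <- responder_rate(joined$spreading_positive)

  km <- NULL; lr <- NULL
  cc <- !is.na(joined$triad) & !is.na(joined$os_months)
  if (any(cc)) {
    d <- joined[cc, ]
    km <- lapply(split(d, ifelse(d$triad, "triad", "no_triad")),
                 function(g) km_estimate(g$os_months, g$event,
                                         horizon = horizon))
    if (length(km) == 2L)
      lr <- logrank(d$os_months, d$event, d$triad)
  }

  feats <- data.frame(
    spots = joined$peak_specific_spots,
    triple_pct = joined$triple_post_pct,
    titer = ifelse(is.na(joined$titer_ng_ml) |
                     !joined$ab_positive, 0, joined$titer_ng_ml),
    breadth = joined$breadth,
    row.names = joined$patient_id)
  grouping <- tryCatch(
    immune_group_clustering(feats,
                            k = min(k, sum(stats::complete.cases(feats))),
                            seed = seed),
    error = function(e) NULL)

  conc <- NULL
  ok <- !is.na(joined$ab_positive) & !is.na(joined$vaccine_responder)
  if (any(ok & joined$ab_positive) && any(ok & !joined$ab_positive))
    conc <- group_compare(joined$vaccine_responder[ok & joined$ab_positive],
                          joined$vaccine_responder[ok & !joined$ab_positive],
                          kind = "categorical")

  structure(list(
    patients = joined, rates = rates,
    triad_count = sum(joined$triad, na.rm = TRUE),
    n_evaluable_triad = sum(!is.na(joined$triad)),
    km = km, logrank = lr, grouping = grouping, concurrent_th1 = conc,
    calls = list(elispot = calls, ics = ics, ab = ab, spreading = spr),
    horizon = horizon
  ), class = "triad_analysis")
}

#' @export
print.triad_analysis <- function(x, ...) {
  cat("Immune-correlate analysis\n")
  cat(sprintf("  %d patients; immune triad in %d/%d evaluable\n",
              nrow(x$patients), x$triad_count, x$n_evaluable_triad))
  for (nm in names(x$rates))
    cat(sprintf("  %-10s response rate: %d%% (%d/%d)\n", nm,
                x$rates[[nm]]$percent, x$rates[[nm]]$positives,
                x$rates[[nm]]$n))
  if (!is.null(x$logrank))
    cat(sprintf("  OS triad vs rest: log-rank chi-sq %.2f, p = %.3g (exploratory)\n",
                x$logrank$statistic, x$logrank$p))
  invisible(x)
}

#' Summary of a triad analysis
#'
#' @param object a \code{\link{triad_analysis}}.
#' @param ... unused.
#' @return The object, invisibly, after printing response rates, the
#'   immunotype distribution, triad count, per-group Kaplan-Meier medians
#'   with the log-rank comparison, and the antibody/Th1 concurrence test.
#' @export
summary.triad_analysis <- function(object, ...) {
  print(object)
  cat("  immunotypes:",
      paste(sprintf("%s=%d", levels(object$patients$immunotype),
                    table(object$patients$immunotype)), collapse = ", "),
      "\n")
  if (!is.null(object$km))
    for (g in names(object$km))
      cat(sprintf("  median OS (%s): %s months; %g-month rate %s\n", g,
                  fmt_num(object$km[[g]]$median), object$horizon,
                  fmt_num(object$km[[g]]$rate_at_horizon$surv, 3)))
  if (!is.null(object$concurrent_th1))
    cat(sprintf("  Th1 response by Ab status (%s): p = %.3g; proportions %.3f vs %.3f\n",
                object$concurrent_th1$method, object$concurrent_th1$p,
                object$concurrent_th1$proportions[1],
                object$concurrent_th1$proportions[2]))
  invisible(object)
}

#' Kaplan-Meier plot by triad group
#'
#' @param x a \code{\link{triad_analysis}}.
#' @param ... passed to \code{plot.survfit}.
#' @export
plot.triad_analysis <- function(x, ...) {
  if (is.null(x$km)) stop("no survival curves available")
  d <- x$patients[!is.na(x$patients$triad) & !is.na(x$patients$os_months), ]
  fit <- survival::survfit(
    survival::Surv(os_months, event) ~ triad, data = d)
  plot(fit, col = c(1, 2), lty = 1, xlab = "Months",
       ylab = "Overall survival", ...)
  graphics::legend("topright", legend = c("no triad", "triad"),
                   col = c(1, 2), lty = 1, bty = "n")
  invisible(x)
}
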