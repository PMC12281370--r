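#' Fit an ELISA standard curve
#'
#' Least-squares polynomial calibration mapping optical density to
#' concentration, fitted on an IgG standard dilution series (0.31--20 ng/mL
#' by convention). Degree 2 by default: the lowest degree that captures
#' ELISA curvature on a 7-point series.
#'
#' @param conc_ng_ml known standard concentrations, strictly increasing.
#' @param od measured optical densities, >= 0. A non-monotone OD series
#'   triggers a warning (the fit proceeds).
#' @param degree polynomial degree (default 2); needs at least
#'   \code{degree + 1} points.
#' @return Object of class \code{"standard_curve"}: the \code{lm} fit,
#'   calibration ranges, degree and residual standard error.
#' @export
fit_standard_curve <- function(conc_ng_ml, od, degree = 2) {
  stopifnot(length(conc_ng_ml) == length(od))
  if (length(conc_ng_ml) < degree + 1)
    stop("need at least ", degree + 1, " calibration points for degree ",
         degree)
  if (any(diff(conc_ng_ml) <= 0))
    stop("standard concentrations must be strictly increasing")
  if (any(od < 0)) stop("optical densities must be >= 0")
  if (any(diff(od) <= 0))
    warning("standard ODs are not strictly increasing; ",
            "calibration may be unreliable")
  fit <- stats::lm(conc_ng_ml ~ poly(od, degree, raw = TRUE))
  structure(list(
    fit = fit, degree = degree,
    od_range = range(od), conc_range = range(conc_ng_ml),
    residual_se = suppressWarnings(summary(fit)$sigma),
    points = data.frame(conc_ng_ml = conc_ng_ml, od = od)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "ELISA standard curve: degree-%d polynomial, %d points,\n  OD range [%.3f, %.3f] -> %.3g-%.3g ng/mL, residual SE %.3g\n",
    x$degree, nrow(x$points), x$od_range[1], x$od_range[2],
    x$conc_range[1], x$conc_range[2], x$residual_se))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) stats::coef(object$fit)

#' Predict concentration from OD
#'
#' Titer prediction is restricted to the calibration OD range; out-of-range
#' ODs are flagged and return \code{NA}, never a silent extrapolation.
#'
#' @param object a \code{\link{fit_standard_curve}} result.
#' @param od optical densities to convert.
#' @param ... unused.
#' @return data.frame with \code{od}, \code{conc_ng_ml} (NA out of range)
#'   and \code{flag} (\code{"ok"}, \code{"below_range"}, \code{"above_range"}).
#' @export
predict.standard_curve <- function(object, od, ...) {
  flag <- ifelse(od < object$od_range[1], "below_range",
                 ifelse(od > object$od_range[2], "above_range", "ok"))
  conc <- rep(NA_real_, length(od))
  ok <- flag == "ok"
  if (any(ok))
    conc[ok] <- stats::predict(object$fit, newdata = data.frame(od = od[ok]))
  data.frame(od = od, conc_ng_ml = conc, flag = flag,
             stringsAsFactors = FALSE)
}

#' Antibody response call
#'
#' Positivity: the UCP-coated well OD must be at least \code{fold} times the
#' ovalbumin (background) OD. If the patient was already positive at
#' baseline, the post-vaccination call additionally requires at least a
#' \code{fold}-fold increase of titer or specific OD over baseline. A high
#' titer is a positive call with titer strictly above
#' \code{high_titer_ng_ml} ng/mL.
#'
#' @param od_ucp,od_ova optical densities of the UCP- and ovalbumin-coated
#'   wells, >= 0. A zero ovalbumin OD satisfies the fold clause iff
#'   \code{od_ucp > 0}.
#' @param titer_ng_ml optional extrapolated IgG concentration (plasma scale).
#' @param baseline optional prior \code{ab_result} from the pre-vaccination
#'   sample; when it is positive the fold-over-baseline rule applies.
#' @param fold required ratio (default 2).
#' @param high_titer_ng_ml high-titer threshold, strict (default 1000).
#' @return List of class \code{"ab_result"}: \code{specific_od},
#'   \code{titer_ng_ml}, \code{positive}, \code{high_titer}.
#' @examples
#' ab_call(0.80, 0.30)$positive  # TRUE (fold 2.67)
#' ab_call(0.50, 0.30)$positive  # FALSE
#' @export
ab_call <- function(od_ucp, od_ova, titer_ng_ml = NA_real_, baseline = NULL,
                    fold = 2, high_titer_ng_ml = 1000) {
  if (od_ucp < 0 || od_ova < 0) stop("optical densities must be >= 0")
  specific <- max(0, od_ucp - od_ova)
  positive <- if (od_ova == 0) od_ucp > 0 else od_ucp >= fold * od_ova
  if (!is.null(baseline) && isTRUE(baseline$positive)) {
    od_up <- baseline$specific_od > 0 && specific >= fold * baseline$specific_od
    titer_up <- !is.na(titer_ng_ml) && !is.na(baseline$titer_ng_ml) &&
      baseline$titer_ng_ml > 0 && titer_ng_ml >= fold * baseline$titer_ng_ml
    positive <- positive && (od_up || titer_up)
  }
  structure(list(
    specific_od = specific,
    titer_ng_ml = titer_ng_ml,
    positive = positive,
    high_titer = positive && !is.na(titer_ng_ml) &&
      titer_ng_ml > high_titer_ng_ml
  ), class = "ab_result")
}

#' @export
print.ab_result <- function(x, ...) {
  cat(sprintf("Ab call: %s (specific OD %.3f, titer %s ng/mL%s)\n",
              if (x$positive) "POSITIVE" else "negative", x$specific_od,
              if (is.na(x$titer_ng_ml)) "NA" else sprintf("%.0f", x$titer_ng_ml),
              if (x$high_titer) ", high titer" else ""))
  invisible(x)
}

#' Antibody response rate
#'
#' @param calls logical vector of per-patient antibody calls.
#' @return A \code{\link{responder_rate}} object (exact percentage retained;
#'   integer percent for reporting).
#' @export
ab_response_rate <- function(calls) responder_rate(calls)

#' Call an ELISA table
#'
#' Computes per-patient antibody calls from a long-format OD table and a
#' standards series. Titers are extrapolated from the specific OD
#' (UCP minus ovalbumin at the same dilution) through the fitted standard
#' curve and multiplied back by the dilution factor; when several dilutions
#' are in calibration range the least-diluted one wins.
#'
#' @param elisa data.frame with columns \code{patient_id}, \code{timepoint},
#'   \code{coat} (\code{"UCP"}/\code{"OVA"}), \code{dilution} (e.g. 125,
#'   1000), \code{od}.
#' @param standards data.frame with columns \code{conc_ng_ml}, \code{od}.
#' @param baseline label of the pre-vaccination timepoint.
#' @param degree,fold,high_titer_ng_ml tuning forwarded to
#'   \code{\link{fit_standard_curve}} and \code{\link{ab_call}}.
#' @return data.frame, one row per patient: \code{ab_positive},
#'   \code{ab_high_titer}, \code{titer_ng_ml}, \code{specific_od} (peak post
#'   values).
#' @export
call_ab <- function(elisa, standards, baseline = "baseline", degree = 2,
                    fold = 2, high_titer_ng_ml = 1000) {
  need <- c("patient_id", "timepoint", "coat", "dilution", "od")
  miss <- setdiff(need, names(elisa))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  curve <- fit_standard_curve(standards$conc_ng_ml, standards$od,
                              degree = degree)

  # one ab_call per patient/timepoint, preferring the least-diluted in-range
  # well for the titer
  tp_call <- function(d, base = NULL) {
    dil <- sort(unique(d$dilution))
    per_dil <- lapply(dil, function(dl) {
      ucp <- d$od[d$coat == "UCP" & d$dilution == dl]
      ova <- d$od[d$coat == "OVA" & d$dilution == dl]
      if (!length(ucp) || !length(ova)) return(NULL)
      sp <- max(0, mean(ucp) - mean(ova))
      pr <- predict(curve, sp)
      list(od_ucp = mean(ucp), od_ova = mean(ova),
           titer = if (pr$flag == "ok") pr$conc_ng_ml * dl else NA_real_)
    })
    per_dil <- Filter(Negate(is.null), per_dil)
    if (!length(per_dil)) stop("no complete UCP/OVA well pair")
    titer <- NA_real_
    for (p in per_dil) if (!is.na(p$titer)) { titer <- p$titer; break }
    ab_call(per_dil[[1]]$od_ucp, per_dil[[1]]$od_ova, titer_ng_ml = titer,
            baseline = base, fold = fold,
            high_titer_ng_ml = high_titer_ng_ml)
  }

  out <- lapply(split(elisa, elisa$patient_id), function(d) {
    tps <- split(d, d$timepoint)
    base_call <- if (baseline %in% names(tps)) tp_call(tps[[baseline]])
                 else NULL
    post_names <- setdiff(names(tps), baseline)
    if (!length(post_names))
      stop("patient ", d$patient_id[1], ": no post-vaccination sample")
    posts <- lapply(tps[post_names], tp_call, base = base_call)
    pos <- vapply(posts, function(p) p$positive, logical(1))
    best <- posts[[which.max(vapply(posts, function(p)
      p$specific_od, numeric(1)))]]
    data.frame(patient_id = d$patient_id[1],
               ab_positive = any(pos),
               ab_high_titer = any(vapply(posts, function(p)
                 p$high_titer, logical(1))),
               titer_ng_ml = best$titer_ng_ml,
               specific_od = best$specific_od,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
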