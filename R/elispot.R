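#' Specific spot count for an ELISpot record
#'
#' Computes the antigen-specific spot count as the mean of the stimulated
#' replicate wells minus the mean of the background (irrelevant-peptide)
#' wells, floored at zero. Counts are reported on the per-well cell basis
#' they were acquired on (3e5 PBMC/well for the ex vivo assay, 1e5 for
#' post-IVS readouts); no rescaling is applied.
#'
#' @param stimulated numeric vector of spot counts in stimulated wells
#'   (>= 1 replicate).
#' @param background numeric vector of spot counts in background wells.
#' @return Non-negative scalar, specific spots per well.
#' @examples
#' elispot_specific_spots(c(30, 32, 28), c(10, 10))  # 20
#' @export
elispot_specific_spots <- function(stimulated, background) {
  check_wells(stimulated, "stimulated")
  check_wells(background, "background")
  max(0, mean(stimulated) - mean(background))
}

#' ELISpot positivity call
#'
#' A response is positive when the stimulated well mean is at least
#' \code{fold} times the background mean AND the specific spot count exceeds
#' \code{min_spots}. When the background mean is exactly zero the fold clause
#' is satisfied by any non-zero stimulated signal.
#'
#' @inheritParams elispot_specific_spots
#' @param min_spots specific spots must strictly exceed this (default 10).
#' @param fold required ratio of stimulated mean over background mean
#'   (default 2).
#' @return A list of class \code{"elispot_call"} with elements
#'   \code{specific_spots}, \code{positive}, and \code{fold_over_background}
#'   (\code{NA} when the background mean is zero).
#' @examples
#' elispot_call(c(30, 30), c(10, 10))$positive    # TRUE
#' elispot_call(c(100, 100), c(60, 60))$positive  # FALSE: fold 1.67 < 2
#' @export
elispot_call <- function(stimulated, background, min_spots = 10, fold = 2) {
  spec <- elispot_specific_spots(stimulated, background)
  sm <- mean(stimulated)
  bm <- mean(background)
  fold_ok <- if (bm == 0) sm > 0 else sm >= fold * bm
  structure(list(
    specific_spots       = spec,
    positive             = fold_ok && spec > min_spots,
    fold_over_background = if (bm > 0) sm / bm else NA_real_
  ), class = "elispot_call")
}

#' @export
print.elispot_call <- function(x, ...) {
  cat(sprintf("ELISpot call: %s (%.1f specific spots, fold %s)\n",
              if (x$positive) "POSITIVE" else "negative",
              x$specific_spots,
              if (is.na(x$fold_over_background)) "undefined (background 0)"
              else sprintf("%.2f", x$fold_over_background)))
  invisible(x)
}

#' Responder rate from per-patient calls
#'
#' @param calls logical vector, one entry per evaluable patient.
#' @return List of class \code{"responder_rate"}: \code{positives}, \code{n},
#'   \code{exact_pct} (exact percentage), \code{percent} (nearest integer,
#'   the reporting convention).
#' @examples
#' responder_rate(rep(c(TRUE, FALSE), c(41, 19)))  # 68% (41/60)
#' @export
responder_rate <- function(calls) {
  if (length(calls) == 0L) stop("no evaluable patients")
  if (anyNA(calls)) {
    calls <- calls[!is.na(calls)]
    if (length(calls) == 0L) stop("no evaluable patients after removing NA")
  }
  calls <- as.logical(calls)
  exact <- 100 * sum(calls) / length(calls)
  structure(list(positives = sum(calls), n = length(calls),
                 exact_pct = exact, percent = round(exact)),
            class = "responder_rate")
}

#' @export
print.responder_rate <- function(x, ...) {
  cat(sprintf("%d%% (%d/%d evaluable; exact %.2f%%)\n",
              x$percent, x$positives, x$n, x$exact_pct))
  invisible(x)
}

#' Low/high responder intensity class
#'
#' Positive responders are split at the cohort median of specific spots for
#' the peptide (UCP2 median 84, UCP4 median 63 in the reference cohort);
#' ties at the median are assigned to "high".
#'
#' @param specific_spots numeric vector of specific spot counts (responders
#'   only).
#' @param cohort_median the median specific spot count over responders to
#'   this peptide.
#' @return Character vector, \code{"high"} or \code{"low"}.
#' @export
intensity_class <- function(specific_spots, cohort_median) {
  stopifnot(is.numeric(specific_spots), length(cohort_median) == 1L,
            is.finite(cohort_median))
  ifelse(specific_spots >= cohort_median, "high", "low")
}

#' Durable response across booster timepoints
#'
#' A response is durable when it is positive at one or more boost-phase
#' timepoints.
#'
#' @param boost_calls logical vector of positivity calls at boost timepoints
#'   (in time order; order does not affect the result).
#' @return Logical scalar.
#' @export
durable_response <- function(boost_calls) {
  if (length(boost_calls) == 0L) stop("no boost-phase timepoints")
  any(as.logical(boost_calls), na.rm = TRUE)
}

#' Call an ELISpot table
#'
#' Applies \code{\link{elispot_call}} to every patient x timepoint x stimulus
#' cell of a long-format well table.
#'
#' @param wells data.frame with columns \code{patient_id}, \code{timepoint},
#'   \code{stimulus}, \code{arm} (\code{"stimulated"}, \code{"background"},
#'   optionally \code{"positive_control"}), \code{spots}, and optionally
#'   \code{cells_per_well}. Positive-control wells are carried through but do
#'   not enter the call.
#' @param min_spots,fold forwarded to \code{\link{elispot_call}}.
#' @return data.frame, one row per patient/timepoint/stimulus with
#'   \code{specific_spots}, \code{positive}, \code{fold_over_background}.
#' @export
call_elispot <- function(wells, min_spots = 10, fold = 2) {
  need <- c("patient_id", "timepoint", "stimulus", "arm", "spots")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  wells <- wells[wells$arm %in% c("stimulated", "background"), , drop = FALSE]
  key <- interaction(wells$patient_id, wells$timepoint, wells$stimulus,
                     drop = TRUE, lex.order = TRUE)
  out <- lapply(split(wells, key), function(d) {
    stim <- d$spots[d$arm == "stimulated"]
    bg   <- d$spots[d$arm == "background"]
    cl <- elispot_call(stim, bg, min_spots = min_spots, fold = fold)
    data.frame(patient_id = d$patient_id[1], timepoint = d$timepoint[1],
               stimulus = d$stimulus[1],
               specific_spots = cl$specific_spots, positive = cl$positive,
               fold_over_background = cl$fold_over_background,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-patient ELISpot responder summary
#'
#' A patient is a responder to a peptide when positive at any
#' post-vaccination timepoint; pooled immunogenicity is a response to at
#' least one peptide. Intensity (low/high at the per-peptide responder
#' median of the peak specific spots) and durability (any positive boost
#' timepoint) are derived alongside.
#'
#' @param calls output of \code{\link{call_elispot}}.
#' @param baseline label of the baseline timepoint (default
#'   \code{"baseline"}).
#' @param boost_prefix timepoints whose label starts with this prefix are
#'   boost-phase (default \code{"boost"}).
#' @return data.frame, one row per patient/stimulus with \code{responder},
#'   \code{peak_specific_spots}, \code{intensity}, \code{durable} (NA when
#'   no boost timepoints were assayed), plus an attribute
#'   \code{"pooled"}: per-patient data.frame with the pooled responder flag.
#' @export
elispot_responders <- function(calls, baseline = "baseline",
                               boost_prefix = "boost") {
  post <- calls[calls$timepoint != baseline, , drop = FALSE]
  key <- interaction(post$patient_id, post$stimulus, drop = TRUE,
                     lex.order = TRUE)
  per <- lapply(split(post, key), function(d) {
    is_boost <- startsWith(as.character(d$timepoint), boost_prefix)
    data.frame(
      patient_id = d$patient_id[1], stimulus = d$stimulus[1],
      responder = any(d$positive),
      peak_specific_spots = max(d$specific_spots),
      durable = if (any(is_boost)) durable_response(d$positive[is_boost])
                else NA,
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  per$intensity <- NA_character_
  for (s in unique(per$stimulus)) {
    idx <- per$stimulus == s & per$responder
    if (any(idx)) {
      med <- stats::median(per$peak_specific_spots[idx])
      per$intensity[idx] <- intensity_class(per$peak_specific_spots[idx], med)
    }
  }
  pooled <- tapply(per$responder, per$patient_id, any)
  attr(per, "pooled") <- data.frame(patient_id = names(pooled),
                                    responder = as.logical(pooled),
                                    stringsAsFactors = FALSE)
  per
}

check_wells <- function(x, what) {
  if (length(x) < 1L) stop("empty replicate list in ", what, " arm")
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x < 0))
    stop(what, " spot counts must be finite and >= 0")
  invisible(x)
}
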