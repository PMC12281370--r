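#' Background subtraction for ICS frequencies
#'
#' Subtracts the unstimulated-condition frequency from the stimulated one,
#' floored at zero.
#'
#' @param stim_pct,unstim_pct frequencies (percent of CD4+ T cells), >= 0.
#' @return Background-subtracted percentage(s).
#' @export
ics_subtract_background <- function(stim_pct, unstim_pct) {
  if (any(stim_pct < 0, na.rm = TRUE) || any(unstim_pct < 0, na.rm = TRUE))
    stop("ICS frequencies must be >= 0")
  pmax(0, stim_pct - unstim_pct)
}

#' ICS positivity rule
#'
#' A cytokine combination is positive when its background-subtracted
#' post-vaccination frequency shows at least a \code{fold}-fold increase over
#' baseline AND exceeds \code{min_pct} percent of CD4+ T cells. A baseline of
#' exactly zero satisfies the fold clause (the threshold clause still binds).
#'
#' @param post_pct,baseline_pct background-subtracted frequencies (percent).
#' @param fold required fold increase (default 2).
#' @param min_pct frequency that must be strictly exceeded (default 0.05).
#' @return Logical, vectorized over the inputs.
#' @examples
#' ics_positive(0.12, 0.05)  # TRUE
#' ics_positive(0.06, 0.04)  # FALSE: fold 1.5
#' ics_positive(0.05, 0.00)  # FALSE: not > 0.05
#' @export
ics_positive <- function(post_pct, baseline_pct, fold = 2, min_pct = 0.05) {
  if (any(post_pct < 0, na.rm = TRUE) || any(baseline_pct < 0, na.rm = TRUE))
    stop("ICS frequencies must be >= 0")
  (post_pct >= fold * baseline_pct) & (post_pct > min_pct)
}

#' The 7 Boolean cytokine combinations
#'
#' All non-null combinations of IFN-gamma, TNF-alpha and IL-2, in canonical
#' order (singles, doubles, triple). The \code{degree} column counts
#' co-expressed cytokines and drives the single/double/triple hierarchy.
#'
#' @return data.frame with columns \code{ifng}, \code{tnfa}, \code{il2}
#'   (0/1), \code{combo} (label) and \code{degree}.
#' @export
cytokine_combos <- function() {
  g <- expand.grid(il2 = 0:1, tnfa = 0:1, ifng = 0:1)[-1, c("ifng", "tnfa", "il2")]
  g <- g[order(g$ifng + g$tnfa + g$il2,
               -(4 * g$ifng + 2 * g$tnfa + g$il2)), ]
  lab <- apply(g, 1, function(r) {
    paste(c("IFNg", "TNFa", "IL2")[r == 1], collapse = "+")
  })
  out <- data.frame(g, combo = lab, degree = g$ifng + g$tnfa + g$il2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Polyfunctional Th1 immunotype
#'
#' Classifies a patient's Th1 response by the highest-order positive
#' cytokine combination across post-vaccination timepoints:
#' \code{polyF_triple} when the IFNg+TNFa+IL2 triple combination is positive,
#' else \code{polyF_double} when any two-cytokine combination is positive,
#' else \code{singleF} when any single-cytokine combination is positive,
#' else \code{none}.
#'
#' @param post_pct numeric vector (or matrix with one column per post
#'   timepoint) of background-subtracted post frequencies for the 7 combos,
#'   in the row order of \code{\link{cytokine_combos}}.
#' @param baseline_pct background-subtracted baseline frequencies, same
#'   order.
#' @param fold,min_pct forwarded to \code{\link{ics_positive}}.
#' @return One of \code{"none"}, \code{"singleF"}, \code{"polyF_double"},
#'   \code{"polyF_triple"}.
#' @export
ics_immunotype <- function(post_pct, baseline_pct, fold = 2, min_pct = 0.05) {
  post <- as.matrix(post_pct)
  if (nrow(post) != 7L || length(baseline_pct) != 7L)
    stop("expected frequencies for the 7 cytokine combinations")
  deg <- cytokine_combos()$degree
  pos <- apply(post, 2, ics_positive, baseline_pct = baseline_pct,
               fold = fold, min_pct = min_pct)
  pos <- matrix(pos, nrow = 7L)
  any_pos <- apply(pos, 1, any)
  if (any(any_pos & deg == 3L)) return("polyF_triple")
  if (any(any_pos & deg == 2L)) return("polyF_double")
  if (any(any_pos & deg == 1L)) return("singleF")
  "none"
}

#' Composition of the cytokine-positive compartment
#'
#' The 7 Boolean combinations partition the cytokine-positive cells, so
#' their frequencies sum to the total any-cytokine-positive frequency.
#'
#' @param combo_pct numeric vector of 7 combination frequencies (percent).
#' @return List with \code{per_combo} (named vector) and \code{total}.
#' @export
combo_composition <- function(combo_pct) {
  if (length(combo_pct) != 7L) stop("expected 7 combination frequencies")
  if (any(combo_pct < 0)) stop("frequencies must be >= 0")
  names(combo_pct) <- cytokine_combos()$combo
  list(per_combo = combo_pct, total = sum(combo_pct))
}

#' Absolute cell count from a frequency
#'
#' Converts a percent-of-CD4 frequency into cells per mm3 of blood.
#'
#' @param freq_pct percent of CD4+ T cells.
#' @param cd4_per_mm3 absolute CD4 count per mm3; \code{NA} propagates
#'   (missing counts give an undefined, not zero, result).
#' @return Cells per mm3.
#' @examples
#' ics_absolute_count(0.2, 719)  # 1.438
#' @export
ics_absolute_count <- function(freq_pct, cd4_per_mm3) {
  if (any(freq_pct < 0, na.rm = TRUE) || any(cd4_per_mm3 < 0, na.rm = TRUE))
    stop("inputs must be >= 0")
  freq_pct / 100 * cd4_per_mm3
}

#' Call an ICS table
#'
#' Background-subtracts (stimulated minus unstimulated) each of the 7
#' cytokine combinations per patient/timepoint, applies the positivity rule
#' between baseline and every post timepoint, and assigns the patient
#' immunotype.
#'
#' @param ics data.frame with columns \code{patient_id}, \code{timepoint},
#'   \code{condition} (\code{"stimulated"}/\code{"unstimulated"}),
#'   \code{ifng}, \code{tnfa}, \code{il2} (0/1 flags), \code{freq_pct}, and
#'   optionally \code{cd4_count_per_mm3}.
#' @param baseline label of the baseline timepoint.
#' @param fold,min_pct forwarded to \code{\link{ics_positive}}.
#' @return data.frame, one row per patient: \code{immunotype} (factor with
#'   levels none < singleF < polyF_double < polyF_triple),
#'   \code{triple_post_pct} (peak background-subtracted triple-combo post
#'   frequency), \code{triple_per_mm3} (absolute count at the peak, NA
#'   without a CD4 count), \code{total_post_pct} (peak total
#'   cytokine-positive frequency).
#' @export
call_ics <- function(ics, baseline = "baseline", fold = 2, min_pct = 0.05) {
  need <- c("patient_id", "timepoint", "condition", "ifng", "tnfa", "il2",
            "freq_pct")
  miss <- setdiff(need, names(ics))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  combos <- cytokine_combos()
  key_of <- function(d) paste(d$ifng, d$tnfa, d$il2)
  ckey <- paste(combos$ifng, combos$tnfa, combos$il2)

  # background-subtracted 7-vector for one patient/timepoint
  sub7 <- function(d) {
    stim <- d[d$condition == "stimulated", ]
    unst <- d[d$condition == "unstimulated", ]
    s <- stim$freq_pct[match(ckey, key_of(stim))]
    u <- unst$freq_pct[match(ckey, key_of(unst))]
    s[is.na(s)] <- 0; u[is.na(u)] <- 0
    ics_subtract_background(s, u)
  }

  out <- lapply(split(ics, ics$patient_id), function(d) {
    tps <- split(d, d$timepoint)
    if (!baseline %in% names(tps))
      stop("patient ", d$patient_id[1], ": missing baseline timepoint")
    base <- sub7(tps[[baseline]])
    post_names <- setdiff(names(tps), baseline)
    if (length(post_names) == 0L)
      stop("patient ", d$patient_id[1], ": no post-vaccination timepoint")
    post <- vapply(tps[post_names], sub7, numeric(7))
    itype <- ics_immunotype(post, base, fold = fold, min_pct = min_pct)
    triple <- max(post[combos$degree == 3L, ])
    cd4 <- if ("cd4_count_per_mm3" %in% names(d))
      d$cd4_count_per_mm3[1] else NA_real_
    data.frame(patient_id = d$patient_id[1], immunotype = itype,
               triple_post_pct = triple,
               triple_per_mm3 = ics_absolute_count(triple, cd4),
               total_post_pct = max(colSums(post)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$immunotype <- factor(out$immunotype,
                           levels = c("none", "singleF", "polyF_double",
                                      "polyF_triple"), ordered = TRUE)
  out
}
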