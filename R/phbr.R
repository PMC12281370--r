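#' Patient harmonic-mean best rank (PHBR)
#'
#' Harmonic mean of a peptide's per-allele best presentation ranks over a
#' patient's two HLA-DRB1 alleles:
#' \deqn{PHBR = 2 / (1/BR_1 + 1/BR_2).}
#' Lower scores mean better predicted presentation. Homozygous genotypes
#' use the same rank twice and return that rank. Any positive rank scale
#' where lower is better (e.g. a predictor's \%rank) is acceptable.
#'
#' @param br1,br2 per-allele best ranks, > 0. Vectorized.
#' @return PHBR score(s), bounded by
#'   \code{min(br1, br2) <= PHBR <= min(2 * min(br1, br2), max(br1, br2))}.
#' @examples
#' phbr(4, 4)    # 4
#' phbr(2, 6)    # 3
#' phbr(1, 1e6)  # ~2: dominated by the best-presenting allele
#' @export
phbr <- function(br1, br2) {
  if (any(br1 <= 0) || any(br2 <= 0) || anyNA(br1) || anyNA(br2))
    stop("best ranks must be positive")
  2 / (1 / br1 + 1 / br2)
}

#' Cohort PHBR scores and two-peptide comparison
#'
#' Per-patient PHBR for each peptide, with a Mann-Whitney comparison of the
#' two peptides' score distributions when exactly two peptides are present
#' (reported descriptively, no threshold enforced), and the Spearman
#' correlation of PHBR with response magnitude when one is supplied.
#'
#' @param br data.frame with columns \code{patient_id}, \code{peptide},
#'   \code{allele_1}, \code{allele_2}, \code{br_1}, \code{br_2}. Patients
#'   with missing ranks for a peptide are listed in the \code{missing}
#'   element, never imputed.
#' @param response optional data.frame \code{patient_id}, \code{peptide},
#'   \code{magnitude} (e.g. specific spots) for the correlation.
#' @return List of class \code{"cohort_phbr"}: \code{scores} (data.frame
#'   patient_id, peptide, phbr), \code{comparison} (wilcox.test result or
#'   NULL), \code{correlation} (per-peptide Spearman or NULL),
#'   \code{missing}.
#' @export
cohort_phbr <- function(br, response = NULL) {
  need <- c("patient_id", "peptide", "br_1", "br_2")
  miss <- setdiff(need, names(br))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- !is.finite(br$br_1) | !is.finite(br$br_2) | br$br_1 <= 0 |
    br$br_2 <= 0
  missing <- br[bad, c("patient_id", "peptide")]
  ok <- br[!bad, , drop = FALSE]
  scores <- data.frame(patient_id = ok$patient_id, peptide = ok$peptide,
                       phbr = phbr(ok$br_1, ok$br_2),
                       stringsAsFactors = FALSE)
  peps <- unique(scores$peptide)
  comparison <- NULL
  if (length(peps) == 2L) {
    comparison <- stats::wilcox.test(
      scores$phbr[scores$peptide == peps[1]],
      scores$phbr[scores$peptide == peps[2]], exact = FALSE)
    comparison$data.name <- paste(peps, collapse = " vs ")
  }
  correlation <- NULL
  if (!is.null(response)) {
    m <- merge(scores, response, by = c("patient_id", "peptide"))
    correlation <- lapply(split(m, m$peptide), function(d)
      stats::cor.test(d$phbr, d$magnitude, method = "spearman",
                      exact = FALSE))
  }
  structure(list(scores = scores, comparison = comparison,
                 correlation = correlation, missing = missing),
            class = "cohort_phbr")
}

#' @export
print.cohort_phbr <- function(x, ...) {
  med <- tapply(x$scores$phbr, x$scores$peptide, stats::median)
  cat("PHBR scores (HLA-DRB1 harmonic-mean best rank; lower = better presentation)\n")
  for (p in names(med))
    cat(sprintf("  %s: median %.3f (n = %d)\n", p, med[[p]],
                sum(x$scores$peptide == p)))
  if (!is.null(x$comparison))
    cat(sprintf("  Mann-Whitney %s: W = %.1f, p = %.3g\n",
                x$comparison$data.name, x$comparison$statistic,
                x$comparison$p.value))
  if (nrow(x$missing))
    cat("  missing ranks for", nrow(x$missing), "patient-peptide pair(s)\n")
  invisible(x)
}
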