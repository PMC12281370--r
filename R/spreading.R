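#' Epitope-spreading status of one antigen
#'
#' De novo: negative before vaccination, positive after. A response already
#' present at baseline is pre-existing regardless of its post-vaccination
#' evolution (maintained or expanded) and is not epitope spreading.
#'
#' @param pre_positive,post_positive logical ELISpot positivity calls for
#'   the antigen before/after vaccination. Vectorized. A missing baseline
#'   call (\code{NA}) means the antigen cannot be called de novo
#'   (conservative) and yields \code{"none"}.
#' @return Character vector: \code{"de_novo"}, \code{"preexisting"} or
#'   \code{"none"}.
#' @export
antigen_spread <- function(pre_positive, post_positive) {
  if (anyNA(post_positive)) stop("missing post-vaccination call")
  out <- ifelse(is.na(pre_positive), "none",
         ifelse(pre_positive, "preexisting",
         ifelse(post_positive, "de_novo", "none")))
  as.character(out)
}

#' Patient-level epitope-spreading call
#'
#' A patient has epitope spreading when at least one panel antigen is de
#' novo positive after vaccination; breadth counts the de novo antigens.
#' De novo reactivity against non-vaccine class II tumor antigens is
#' intermolecular spreading; against class I epitopes of the vaccinated
#' antigen (hTERT) it is intramolecular.
#'
#' @param spread character vector of per-antigen
#'   \code{\link{antigen_spread}} states.
#' @param antigen_class per-antigen class, \code{"classII_TAA"} or
#'   \code{"classI_hTERT"}.
#' @return List: \code{positive}, \code{breadth}, \code{intermolecular},
#'   \code{intramolecular}, \code{n_preexisting}.
#' @export
patient_spreading <- function(spread, antigen_class) {
  if (length(spread) == 0L) stop("empty antigen panel")
  stopifnot(length(spread) == length(antigen_class))
  de_novo <- spread == "de_novo"
  list(positive = any(de_novo),
       breadth = sum(de_novo),
       intermolecular = any(de_novo & antigen_class == "classII_TAA"),
       intramolecular = any(de_novo & antigen_class == "classI_hTERT"),
       n_preexisting = sum(spread == "preexisting"))
}

#' Call an IVS-ELISpot spreading table
#'
#' Reuses the ELISpot positivity rule on post-IVS well counts (per 1e5 cells
#' by that protocol's convention) for every antigen at the pre and post
#' phase, then classifies each antigen and each patient. Antigens are
#' treated independently: a pre-existing response against one antigen does
#' not block a de novo call on another.
#'
#' @param ivs data.frame in the ELISpot well schema (\code{patient_id},
#'   \code{stimulus} = antigen label, \code{arm}, \code{spots}) plus a
#'   \code{phase} column (\code{"pre"}/\code{"post"}). Antigen class is
#'   taken from an optional \code{antigen_class} column, else inferred:
#'   stimuli whose label contains \code{"hTERT"} are class I hTERT
#'   (intramolecular), all others class II TAA.
#' @param min_spots,fold forwarded to \code{\link{elispot_call}}.
#' @return data.frame, one row per patient: \code{spreading_positive},
#'   \code{breadth}, \code{intermolecular}, \code{intramolecular}; attribute
#'   \code{"antigens"} holds the per-antigen calls.
#' @export
call_spreading <- function(ivs, min_spots = 10, fold = 2) {
  need <- c("patient_id", "stimulus", "arm", "spots", "phase")
  miss <- setdiff(need, names(ivs))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  per_ag <- lapply(split(ivs, list(ivs$patient_id, ivs$stimulus),
                         drop = TRUE, sep = "\r"), function(d) {
    call_phase <- function(ph) {
      dd <- d[d$phase == ph, ]
      if (!nrow(dd)) return(NA)
      elispot_call(dd$spots[dd$arm == "stimulated"],
                   dd$spots[dd$arm == "background"],
                   min_spots = min_spots, fold = fold)$positive
    }
    cls <- if ("antigen_class" %in% names(d)) d$antigen_class[1]
           else if (grepl("hTERT", d$stimulus[1])) "classI_hTERT"
           else "classII_TAA"
    data.frame(patient_id = d$patient_id[1], stimulus = d$stimulus[1],
               antigen_class = cls,
               spread = antigen_spread(call_phase("pre"), call_phase("post")),
               stringsAsFactors = FALSE)
  })
  per_ag <- do.call(rbind, per_ag)
  rownames(per_ag) <- NULL
  out <- lapply(split(per_ag, per_ag$patient_id), function(d) {
    s <- patient_spreading(d$spread, d$antigen_class)
    data.frame(patient_id = d$patient_id[1],
               spreading_positive = s$positive, breadth = s$breadth,
               intermolecular = s$intermolecular,
               intramolecular = s$intramolecular,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "antigens") <- per_ag
  out
}
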