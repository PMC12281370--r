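#' Synthetic-cohort configuration
#'
#' Parameters of the seeded cohort generator. Defaults mirror the reference
#' study conditions: 60 patients, two telomerase-derived helper peptides
#' (UCP2/UCP4) given as priming then repeated boosts, per-peptide responder
#' rates 68%/57%, specific-spot effects matching the printed responder
#' medians (84 and 63 spots per 3e5 cells), a 62% antibody-response rate
#' with a log-normal titer distribution putting ~60% of positives above
#' 1000 ng/mL, spreading conditional on vaccine response, power-law
#' clone-size repertoires, and exponential survival with hazards
#' log(2)/15 (immune-triad group) and log(2)/8.3 per month.
#'
#' @param n_patients number of patients.
#' @param peptides vaccine stimulus labels.
#' @param timepoints ordered labels; the first is baseline, labels starting
#'   with \code{"boost"} are boost-phase.
#' @param responder_rate_per_peptide named probabilities in [0,1], one per
#'   peptide.
#' @param bg_spot_rate Poisson mean of background wells (spots/well).
#' @param effect_spots named per-peptide mean added spots in responders.
#' @param ics_combo_concentration positive Dirichlet concentration for the
#'   7 cytokine combinations (order of \code{\link{cytokine_combos}}).
#' @param ics_total_lognormal (meanlog, sdlog) of the total
#'   cytokine-positive post frequency (percent) in responders.
#' @param ab_rate probability of an antibody response.
#' @param titer_lognormal_params (meanlog, sdlog) of positive titers
#'   (ng/mL).
#' @param spreading_rate_given_response probability of epitope spreading
#'   among vaccine responders (non-responders never spread).
#' @param repertoire_zipf_exponent positive Zipf exponent of the ranked
#'   clone-frequency distribution.
#' @param n_clonotypes clonotypes per repertoire.
#' @param repertoire_reads sequencing reads per repertoire.
#' @param survival_hazard_by_group named monthly hazards
#'   (\code{triad}, \code{no_triad}), > 0.
#' @param censor_rate probability of independent early censoring.
#' @param follow_up_months administrative follow-up horizon (may be
#'   \code{Inf}).
#' @param replicates wells per arm.
#' @param cells_per_well PBMC per ex vivo ELISpot well.
#' @param seed integer master seed; identical configurations with identical
#'   seeds generate byte-identical tables.
#' @return Validated list of class \code{"synth_config"}.
#' @export
synth_config <- function(n_patients = 60,
                         peptides = c("UCP2", "UCP4"),
                         timepoints = c("baseline", "priming", "boost_1",
                                        "boost_2", "boost_3"),
                         responder_rate_per_peptide = c(UCP2 = 0.68,
                                                        UCP4 = 0.57),
                         bg_spot_rate = 5,
                         effect_spots = c(UCP2 = 84, UCP4 = 63),
                         ics_combo_concentration = c(1, 1, 1, 1, 1, 2, 2),
                         ics_total_lognormal = c(meanlog = log(0.35),
                                                 sdlog = 0.35),
                         ab_rate = 0.62,
                         titer_lognormal_params = c(meanlog = 7.3,
                                                    sdlog = 1.5),
                         spreading_rate_given_response = 0.45,
                         repertoire_zipf_exponent = 1.0,
                         n_clonotypes = 300,
                         repertoire_reads = 20000,
                         survival_hazard_by_group = c(triad = log(2) / 15,
                                                      no_triad = log(2) / 8.3),
                         censor_rate = 0.15,
                         follow_up_months = 36,
                         replicates = 3,
                         cells_per_well = 3e5,
                         seed = 1) {
  cfg <- list(n_patients = n_patients, peptides = peptides,
              timepoints = timepoints,
              responder_rate_per_peptide = responder_rate_per_peptide,
              bg_spot_rate = bg_spot_rate, effect_spots = effect_spots,
              ics_combo_concentration = ics_combo_concentration,
              ics_total_lognormal = ics_total_lognormal,
              ab_rate = ab_rate,
              titer_lognormal_params = titer_lognormal_params,
              spreading_rate_given_response = spreading_rate_given_response,
              repertoire_zipf_exponent = repertoire_zipf_exponent,
              n_clonotypes = n_clonotypes,
              repertoire_reads = repertoire_reads,
              survival_hazard_by_group = survival_hazard_by_group,
              censor_rate = censor_rate,
              follow_up_months = follow_up_months,
              replicates = replicates, cells_per_well = cells_per_well,
              seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  chk <- function(cond, field, msg) {
    if (!cond) stop("invalid synth_config field '", field, "': ", msg,
                    call. = FALSE)
  }
  fin <- function(x) is.numeric(x) && all(is.finite(x))
  chk(fin(cfg$n_patients) && cfg$n_patients >= 1, "n_patients",
      "must be a positive count")
  chk(length(cfg$peptides) >= 1, "peptides", "at least one peptide")
  chk(length(cfg$timepoints) >= 2, "timepoints",
      "need baseline plus at least one post timepoint")
  prob_fields <- c("responder_rate_per_peptide", "ab_rate",
                   "spreading_rate_given_response", "censor_rate")
  for (f in prob_fields)
    chk(fin(cfg[[f]]) && all(cfg[[f]] >= 0 & cfg[[f]] <= 1), f,
        "probabilities must lie in [0, 1]")
  chk(all(cfg$peptides %in% names(cfg$responder_rate_per_peptide)),
      "responder_rate_per_peptide", "needs one rate per peptide")
  chk(all(cfg$peptides %in% names(cfg$effect_spots)), "effect_spots",
      "needs one effect per peptide")
  chk(fin(cfg$bg_spot_rate) && cfg$bg_spot_rate >= 0, "bg_spot_rate",
      "must be a non-negative Poisson mean")
  chk(fin(cfg$effect_spots) && all(cfg$effect_spots >= 0), "effect_spots",
      "must be non-negative")
  chk(fin(cfg$ics_combo_concentration) &&
        length(cfg$ics_combo_concentration) == 7 &&
        all(cfg$ics_combo_concentration > 0), "ics_combo_concentration",
      "must be 7 positive Dirichlet concentrations")
  chk(fin(cfg$titer_lognormal_params) &&
        length(cfg$titer_lognormal_params) == 2 &&
        cfg$titer_lognormal_params[2] > 0, "titer_lognormal_params",
      "must be (meanlog, sdlog > 0)")
  chk(fin(cfg$repertoire_zipf_exponent) && cfg$repertoire_zipf_exponent > 0,
      "repertoire_zipf_exponent", "must be > 0")
  chk(fin(cfg$n_clonotypes) && cfg$n_clonotypes >= 1, "n_clonotypes",
      "must be a positive count")
  chk(fin(cfg$survival_hazard_by_group) &&
        all(cfg$survival_hazard_by_group > 0) &&
        all(c("triad", "no_triad") %in%
              names(cfg$survival_hazard_by_group)),
      "survival_hazard_by_group", "needs positive 'triad'/'no_triad' hazards")
  chk(is.numeric(cfg$follow_up_months) && !is.na(cfg$follow_up_months) &&
        cfg$follow_up_months > 0, "follow_up_months", "must be > 0 (Inf allowed)")
  chk(fin(cfg$replicates) && cfg$replicates >= 1, "replicates",
      "need at least one well per arm")
  chk(fin(cfg$seed) && abs(cfg$seed) < 2^31, "seed",
      "must be a finite 32-bit integer")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort config: %d patients, peptides %s, %d timepoints, seed %d\n",
    x$n_patients, paste(x$peptides, collapse = "/"), length(x$timepoints),
    as.integer(x$seed)))
  invisible(x)
}

#' Read a generator configuration from JSON
#'
#' JSON keys mirror the \code{\link{synth_config}} arguments field for
#' field; absent keys keep their defaults. Requires the jsonlite package.
#'
#' @param path JSON file.
#' @return A \code{\link{synth_config}}.
#' @export
synth_config_from_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to read JSON configurations")
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synth_config, js)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# generator-side ELISA standard curve: mildly saturating, monotone on
# [0, 25] ng/mL in-well
std_curve_od <- function(conc) 0.08 * conc - 0.0012 * conc^2

#' Generate a synthetic cohort
#'
#' Draws a full assay bundle with the statistical structure the analysis
#' modules assume. One master seed fans out into independent per-table
#' substreams, so the same (config, seed) pair is byte-identical and
#' generating a subset of tables does not perturb the others.
#'
#' Latent patient truth (responder flags, immunotype realized through a
#' Dirichlet split of the cytokine-positive compartment, antibody titer,
#' spreading, the resulting triad flag and its survival hazard) is stored
#' in the \code{patients} table with \code{true_}-prefixed columns.
#'
#' @param config a \code{\link{synth_config}}.
#' @param tables which tables to build (subset of \code{"elispot"},
#'   \code{"ics"}, \code{"elisa"}, \code{"hla"}, \code{"repertoire"},
#'   \code{"spreading"}, \code{"survival"}); default all. The
#'   \code{patients} index (latent truth) is always produced.
#' @return List of class \code{"synthetic_cohort"} with the requested
#'   data.frames plus \code{standards} (ELISA calibration series) and the
#'   config.
#' @export
generate_cohort <- function(config = synth_config(),
                            tables = c("elispot", "ics", "elisa", "hla",
                                       "repertoire", "spreading",
                                       "survival")) {
  validate_synth_config(config)
  tables <- match.arg(tables, several.ok = TRUE)
  cfg <- config
  set.seed(cfg$seed)
  ss <- sample.int(2^31 - 2, 9)  # per-table substream seeds

  ids <- sprintf("P%03d", seq_len(cfg$n_patients))
  combos <- cytokine_combos()
  baseline_tp <- cfg$timepoints[1]
  post_tps <- cfg$timepoints[-1]

  ## latent truth ------------------------------------------------------
  set.seed(ss[1])
  resp <- sapply(cfg$peptides, function(p)
    stats::runif(cfg$n_patients) < cfg$responder_rate_per_peptide[[p]])
  resp <- matrix(resp, nrow = cfg$n_patients,
                 dimnames = list(ids, cfg$peptides))
  vaccine_responder <- apply(resp, 1, any)

  ics_total <- stats::rlnorm(cfg$n_patients,
                             cfg$ics_total_lognormal[[1]],
                             cfg$ics_total_lognormal[[2]])
  combo_freq <- t(vapply(seq_len(cfg$n_patients), function(i) {
    if (!vaccine_responder[i]) return(rep(0, 7))
    ics_total[i] * rdirichlet1(cfg$ics_combo_concentration)
  }, numeric(7)))
  # immunotype realized by the generated frequencies themselves
  # (baseline-subtracted baseline ~ 0, so positivity reduces to > 0.05%)
  immunotype_true <- apply(combo_freq, 1, function(f) {
    pos <- f > 0.05
    if (any(pos & combos$degree == 3)) "polyF_triple"
    else if (any(pos & combos$degree == 2)) "polyF_double"
    else if (any(pos & combos$degree == 1)) "singleF"
    else "none"
  })

  ab_true <- stats::runif(cfg$n_patients) < cfg$ab_rate
  titer_true <- ifelse(ab_true,
                       pmin(pmax(stats::rlnorm(
                         cfg$n_patients,
                         cfg$titer_lognormal_params[[1]],
                         cfg$titer_lognormal_params[[2]]), 50), 20000),
                       NA_real_)
  spreading_true <- vaccine_responder &
    stats::runif(cfg$n_patients) < cfg$spreading_rate_given_response
  triad_true <- immunotype_true == "polyF_triple" & ab_true & spreading_true
  cd4 <- pmax(150, stats::rnorm(cfg$n_patients, 719, 200))

  patients <- data.frame(
    patient_id = ids,
    true_vaccine_responder = vaccine_responder,
    true_immunotype = immunotype_true,
    true_ab = ab_true, true_titer_ng_ml = titer_true,
    true_spreading = spreading_true, true_triad = triad_true,
    cd4_count_per_mm3 = round(cd4),
    stringsAsFactors = FALSE)
  for (p in cfg$peptides)
    patients[[paste0("true_responder_", p)]] <- resp[, p]

  out <- list(patients = patients, config = cfg)

  ## ELISpot ------------------------------------------------------------
  if ("elispot" %in% tables) {
    set.seed(ss[2])
    grid <- expand.grid(patient_id = ids, timepoint = cfg$timepoints,
                        stimulus = cfg$peptides,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(r) {
      g <- grid[r, ]
      responding <- resp[g$patient_id, g$stimulus] &&
        g$timepoint != baseline_tp
      lam_stim <- cfg$bg_spot_rate +
        if (responding) cfg$effect_spots[[g$stimulus]] else 0
      data.frame(
        patient_id = g$patient_id, timepoint = g$timepoint,
        stimulus = g$stimulus,
        well_index = seq_len(2 * cfg$replicates),
        arm = rep(c("stimulated", "background"), each = cfg$replicates),
        spots = c(stats::rpois(cfg$replicates, lam_stim),
                  stats::rpois(cfg$replicates, cfg$bg_spot_rate)),
        cells_per_well = cfg$cells_per_well, stringsAsFactors = FALSE)
    })
    out$elispot <- do.call(rbind, rows)
  }

  ## ICS ---------------------------------------------------------------
  if ("ics" %in% tables) {
    set.seed(ss[3])
    ics_tps <- c(baseline_tp, post_tps[1])
    rows <- lapply(seq_len(cfg$n_patients), function(i) {
      do.call(rbind, lapply(ics_tps, function(tp) {
        unstim <- stats::runif(7, 0.002, 0.02)
        spec <- if (tp == baseline_tp) stats::runif(7, 0, 0.01)
                else combo_freq[i, ]
        data.frame(
          patient_id = rep(ids[i], 14), timepoint = rep(tp, 14),
          condition = rep(c("stimulated", "unstimulated"), each = 7),
          ifng = rep(combos$ifng, 2), tnfa = rep(combos$tnfa, 2),
          il2 = rep(combos$il2, 2),
          freq_pct = round(c(unstim + spec, unstim), 5),
          cd4_count_per_mm3 = patients$cd4_count_per_mm3[i],
          stringsAsFactors = FALSE)
      }))
    })
    out$ics <- do.call(rbind, rows)
  }

  ## ELISA --------------------------------------------------------------
  if ("elisa" %in% tables) {
    set.seed(ss[4])
    std_conc <- c(0.31, 0.625, 1.25, 2.5, 5, 10, 20)
    out$standards <- data.frame(conc_ng_ml = std_conc,
                                od = round(std_curve_od(std_conc), 4))
    dils <- c(125, 1000)
    rows <- lapply(seq_len(cfg$n_patients), function(i) {
      do.call(rbind, lapply(c(baseline_tp, post_tps[1]), function(tp) {
        do.call(rbind, lapply(dils, function(dl) {
          ova <- stats::runif(1, 0.05, 0.15)
          spec <- if (tp != baseline_tp && ab_true[i]) {
            std_curve_od(min(titer_true[i] / dl, 25))
          } else {
            ova * stats::runif(1, -0.1, 0.3)  # negative: < 2-fold over OVA
          }
          data.frame(patient_id = ids[i], timepoint = tp,
                     coat = c("UCP", "OVA"), dilution = dl,
                     od = round(c(max(0, ova + spec), ova), 4),
                     stringsAsFactors = FALSE)
        }))
      }))
    })
    out$elisa <- do.call(rbind, rows)
  }

  ## HLA best ranks -----------------------------------------------------
  if ("hla" %in% tables) {
    set.seed(ss[5])
    pool <- c("DRB1*01:01", "DRB1*03:01", "DRB1*04:01", "DRB1*07:01",
              "DRB1*11:01", "DRB1*13:01", "DRB1*15:01")
    # per-allele best ranks are a property of the allele, shared by carriers
    br_base <- stats::rlnorm(length(pool), log(4), 0.6)
    br_map <- list()
    for (p in cfg$peptides) br_map[[p]] <-
      stats::setNames(br_base * stats::rlnorm(length(pool),
                                              log(0.5) * (p == cfg$peptides[1]),
                                              0.25), pool)
    a1 <- sample(pool, cfg$n_patients, replace = TRUE)
    a2 <- sample(pool, cfg$n_patients, replace = TRUE)
    rows <- lapply(cfg$peptides, function(p)
      data.frame(patient_id = ids, peptide = p, allele_1 = a1, allele_2 = a2,
                 br_1 = round(br_map[[p]][a1], 4),
                 br_2 = round(br_map[[p]][a2], 4),
                 stringsAsFactors = FALSE))
    out$hla <- do.call(rbind, rows)
    rownames(out$hla) <- NULL
  }

  ## TCR-beta repertoires ----------------------------------------------
  if ("repertoire" %in% tables) {
    set.seed(ss[6])
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    vs <- paste0("TRBV", c(2, 5, 6, 7, 9, 11, 12, 19, 20, 28))
    p_rank <- seq_len(cfg$n_clonotypes)^(-cfg$repertoire_zipf_exponent)
    p_rank <- p_rank / sum(p_rank)
    rows <- lapply(ids, function(id) {
      cnt <- as.vector(stats::rmultinom(1, cfg$repertoire_reads, p_rank))
      keep <- cnt > 0
      cdr3 <- paste0("CASS",
                     vapply(seq_len(sum(keep)), function(j)
                       paste(sample(aa, 7, replace = TRUE), collapse = ""),
                       character(1)),
                     "EQFF")
      data.frame(patient_id = id, cdr3_aa = cdr3,
                 v_gene = sample(vs, sum(keep), replace = TRUE),
                 count = cnt[keep], stringsAsFactors = FALSE)
    })
    out$repertoire <- do.call(rbind, rows)
  }

  ## epitope-spreading IVS panel ---------------------------------------
  if ("spreading" %in% tables) {
    set.seed(ss[7])
    antigens <- c("NY-ESO-1", "KK-LC-1", "Mesothelin_366-380",
                  "Mesothelin_523-537", "KRAS_G12V", "hTERT_classI")
    ivs_bg <- 3
    ivs_effect <- 40
    rows <- lapply(seq_len(cfg$n_patients), function(i) {
      preex <- stats::runif(length(antigens)) < 0.05
      de_novo <- rep(FALSE, length(antigens))
      if (spreading_true[i]) {
        breadth <- 1 + stats::rbinom(1, 2, 0.4)
        cand <- which(!preex)
        if (length(cand))
          de_novo[sample(cand, min(breadth, length(cand)))] <- TRUE
      }
      do.call(rbind, lapply(seq_along(antigens), function(j) {
        do.call(rbind, lapply(c("pre", "post"), function(ph) {
          hot <- preex[j] || (de_novo[j] && ph == "post")
          lam <- ivs_bg + if (hot) ivs_effect else 0
          data.frame(patient_id = ids[i], phase = ph,
                     stimulus = antigens[j],
                     antigen_class = if (antigens[j] == "hTERT_classI")
                       "classI_hTERT" else "classII_TAA",
                     well_index = seq_len(2 * cfg$replicates),
                     arm = rep(c("stimulated", "background"),
                               each = cfg$replicates),
                     spots = c(stats::rpois(cfg$replicates, lam),
                               stats::rpois(cfg$replicates, ivs_bg)),
                     cells_per_well = 1e5, stringsAsFactors = FALSE)
        }))
      }))
    })
    out$spreading <- do.call(rbind, rows)
  }

  ## survival -----------------------------------------------------------
  if ("survival" %in% tables) {
    set.seed(ss[8])
    haz <- ifelse(triad_true, cfg$survival_hazard_by_group[["triad"]],
                  cfg$survival_hazard_by_group[["no_triad"]])
    t_event <- stats::rexp(cfg$n_patients, haz)
    cens <- stats::runif(cfg$n_patients) < cfg$censor_rate
    t_cens <- ifelse(cens,
                     stats::runif(cfg$n_patients) * pmin(t_event,
                                                         cfg$follow_up_months),
                     Inf)
    obs <- pmin(t_event, t_cens, cfg$follow_up_months)
    out$survival <- data.frame(
      patient_id = ids, os_months = round(obs, 3),
      event = as.integer(obs == t_event & obs < cfg$follow_up_months),
      stringsAsFactors = FALSE)
  }

  structure(out, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic vaccine-trial cohort: %d patients (seed %d)\n",
              nrow(x$patients), as.integer(x$config$seed)))
  tabs <- setdiff(names(x), c("patients", "config"))
  for (t in tabs)
    cat(sprintf("  %-10s %6d rows\n", t, nrow(x[[t]])))
  cat(sprintf("  latent: %d vaccine responders, %d triple+, %d Ab+, %d spreading, %d triad\n",
              sum(x$patients$true_vaccine_responder),
              sum(x$patients$true_immunotype == "polyF_triple"),
              sum(x$patients$true_ab), sum(x$patients$true_spreading),
              sum(x$patients$true_triad)))
  invisible(x)
}

#' Write a synthetic cohort as delimited text
#'
#' One CSV per table, in the schemas the calling functions consume.
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in setdiff(names(cohort), "config"))
    utils::write.csv(cohort[[t]], file.path(dir, paste0(t, ".csv")),
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
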