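test_that("invalid configurations are rejected with the field named", {
  expect_error(synth_config(ab_rate = 1.5), "ab_rate")
  expect_error(synth_config(bg_spot_rate = -1), "bg_spot_rate")
  expect_error(synth_config(ics_combo_concentration = rep(0, 7)),
               "ics_combo_concentration")
  expect_error(synth_config(survival_hazard_by_group = c(triad = -0.1,
                                                         no_triad = 0.1)),
               "survival_hazard_by_group")
  expect_error(synth_config(responder_rate_per_peptide = c(UCP2 = 0.5)),
               "responder_rate_per_peptide")
  expect_error(synth_config(n_clonotypes = NaN), "n_clonotypes")
})

test_that("the same config and seed give identical tables", {
  cfg <- synth_config(n_patients = 12, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (t in setdiff(names(a), "config")) expect_identical(a[[t]], b[[t]])
  c2 <- generate_cohort(synth_config(n_patients = 12, seed = 100))
  expect_false(identical(a$elispot$spots, c2$elispot$spots))
})

test_that("generating a subset of tables does not perturb the others", {
  cfg <- synth_config(n_patients = 10, seed = 5)
  full <- generate_cohort(cfg)
  only_surv <- generate_cohort(cfg, tables = "survival")
  expect_identical(full$survival, only_surv$survival)
  expect_identical(full$patients, only_surv$patients)
  expect_null(only_surv$elispot)
})

test_that("with no signal the caller finds zero responders", {
  cfg <- synth_config(n_patients = 20,
                      responder_rate_per_peptide = c(UCP2 = 0, UCP4 = 0),
                      effect_spots = c(UCP2 = 0, UCP4 = 0),
                      ab_rate = 0, spreading_rate_given_response = 0,
                      seed = 3)
  co <- generate_cohort(cfg, tables = c("elispot", "spreading"))
  per <- elispot_responders(call_elispot(co$elispot))
  expect_equal(sum(per$responder), 0)
  expect_equal(sum(call_spreading(co$spreading)$spreading_positive), 0)
})

test_that("called responder fraction is calibrated to the configured rate", {
  cfg <- synth_config(n_patients = 250, seed = 7)
  co <- generate_cohort(cfg, tables = "elispot")
  per <- elispot_responders(call_elispot(co$elispot))
  for (p in cfg$peptides) {
    rate <- cfg$responder_rate_per_peptide[[p]]
    frac <- mean(per$responder[per$stimulus == p])
    se <- sqrt(rate * (1 - rate) / cfg$n_patients)
    expect_lt(abs(frac - rate), 3 * se)
  }
})

test_that("responder fraction at n=60 sits in the exact binomial interval of 0.68", {
  co <- generate_cohort(synth_config(n_patients = 60, seed = 7),
                        tables = "elispot")
  per <- elispot_responders(call_elispot(co$elispot))
  k <- sum(per$responder[per$stimulus == "UCP2"])
  ci <- qbinom(c(0.025, 0.975), 60, 0.68)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("generated repertoire frequencies sum to one per sample", {
  co <- generate_cohort(synth_config(n_patients = 5, seed = 13),
                        tables = "repertoire")
  for (d in split(co$repertoire, co$repertoire$patient_id)) {
    r <- repertoire(d$cdr3_aa, d$v_gene, d$count)
    expect_equal(sum(r$frequency), 1, tolerance = 1e-9)
  }
})

test_that("KM median recovers the configured hazard without censoring", {
  lam <- log(2) / 10
  cfg <- synth_config(n_patients = 500,
                      survival_hazard_by_group = c(triad = lam,
                                                   no_triad = lam),
                      censor_rate = 0, follow_up_months = Inf, seed = 17)
  co <- generate_cohort(cfg, tables = "survival")
  expect_equal(sum(co$survival$event), 500)
  km <- km_estimate(co$survival$os_months, co$survival$event)
  expect_lt(abs(km$median - 10), 0.15 * 10)
})

test_that("latent spreading occurs only among vaccine responders", {
  co <- generate_cohort(synth_config(n_patients = 200, seed = 23),
                        tables = "spreading")
  p <- co$patients
  expect_true(all(!p$true_spreading[!p$true_vaccine_responder]))
  spr <- call_spreading(co$spreading)
  m <- merge(spr, p, by = "patient_id")
  expect_true(all(m$true_vaccine_responder[m$spreading_positive]))
})
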