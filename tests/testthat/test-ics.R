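test_that("background subtraction floors at zero", {
  expect_equal(ics_subtract_background(0.30, 0.05), 0.25)
  expect_equal(ics_subtract_background(0.05, 0.05), 0)
  expect_equal(ics_subtract_background(0.03, 0.08), 0)
  expect_error(ics_subtract_background(-0.1, 0), ">= 0")
})

test_that("ICS positivity needs a 2-fold increase above 0.05%", {
  expect_true(ics_positive(0.12, 0.05))
  expect_false(ics_positive(0.06, 0.04))   # fold 1.5
  expect_false(ics_positive(0.05, 0.00))   # boundary: not > 0.05
  expect_true(ics_positive(0.051, 0.00))   # zero baseline passes the fold
})

test_that("ics_positive matches a brute-force restatement on a fine grid", {
  post <- seq(0, 0.3, by = 0.003)
  base <- seq(0, 0.15, by = 0.003)
  g <- expand.grid(post = post, base = base)
  oracle <- mapply(function(p, b) (p >= 2 * b) && (p > 0.05),
                   g$post, g$base)
  expect_identical(ics_positive(g$post, g$base), oracle)
})

test_that("ics_positive is monotone in the post frequency", {
  set.seed(5)
  for (i in 1:200) {
    b <- runif(1, 0, 0.2)
    p <- sort(runif(2, 0, 0.5))
    expect_false(ics_positive(p[1], b) && !ics_positive(p[2], b))
  }
})

test_that("the immunotype hierarchy is triple > double > single > none", {
  combos <- cytokine_combos()
  base <- rep(0.02, 7)
  post <- rep(0.02, 7)
  expect_equal(ics_immunotype(post, base), "none")
  post[combos$degree == 1][1] <- 0.2
  expect_equal(ics_immunotype(post, base), "singleF")
  post[combos$combo == "TNFa+IL2"] <- 0.2
  expect_equal(ics_immunotype(post, base), "polyF_double")
  post[combos$degree == 3] <- 0.2
  expect_equal(ics_immunotype(post, base), "polyF_triple")
  # triple remains triple under any increase of the triple combo
  post[combos$degree == 3] <- 5
  expect_equal(ics_immunotype(post, base), "polyF_triple")
})

test_that("combo composition is additive", {
  cc <- combo_composition(c(0.1, 0.05, 0.05, 0.02, 0.02, 0.02, 0.01))
  expect_equal(cc$total, 0.27)
  expect_equal(combo_composition(rep(0, 7))$total, 0)
  set.seed(9)
  for (i in 1:50) {
    f <- runif(7, 0, 0.3)
    expect_equal(combo_composition(f)$total, sum(f), tolerance = 1e-12)
  }
})

test_that("absolute counts scale frequency by the CD4 count", {
  expect_equal(ics_absolute_count(0.2, 719), 1.438)
  expect_equal(ics_absolute_count(0, 719), 0)
  expect_equal(ics_absolute_count(100, 500), 500)
  expect_true(is.na(ics_absolute_count(0.2, NA)))  # undefined, not zero
})

test_that("call_ics classifies a hand-built panel", {
  combos <- cytokine_combos()
  mk <- function(pid, tp, stim, unstim) {
    data.frame(patient_id = pid, timepoint = tp,
               condition = rep(c("stimulated", "unstimulated"), each = 7),
               ifng = rep(combos$ifng, 2), tnfa = rep(combos$tnfa, 2),
               il2 = rep(combos$il2, 2), freq_pct = c(stim, unstim),
               cd4_count_per_mm3 = 700)
  }
  u <- rep(0.01, 7)
  stim_post <- u; stim_post[combos$degree == 3] <- 0.21  # triple 0.20 net
  tab <- rbind(mk("P1", "baseline", u + 0.002, u),
               mk("P1", "priming", stim_post, u))
  res <- call_ics(tab)
  expect_equal(as.character(res$immunotype), "polyF_triple")
  expect_equal(res$triple_post_pct, 0.2, tolerance = 1e-9)
  expect_equal(res$triple_per_mm3, 0.2 / 100 * 700, tolerance = 1e-9)
  expect_error(call_ics(tab[tab$timepoint != "baseline", ]), "baseline")
})
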