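# shared fixtures: tiny repertoires and well tables built in code

make_rep <- function(counts, prefix = "CASS", v = "TRBV9") {
  repertoire(cdr3_aa = paste0(prefix, seq_along(counts), "F"),
             v_gene = rep(v, length(counts)), count = counts)
}

# random frequency vector summing to 1
rand_freq <- function(n) {
  x <- rexp(n)
  x / sum(x)
}

# minimal ELISpot well table for one patient/timepoint/stimulus
well_rows <- function(patient, tp, stim, stim_spots, bg_spots) {
  data.frame(patient_id = patient, timepoint = tp, stimulus = stim,
             well_index = seq_len(length(stim_spots) + length(bg_spots)),
             arm = rep(c("stimulated", "background"),
                       c(length(stim_spots), length(bg_spots))),
             spots = c(stim_spots, bg_spots),
             cells_per_well = 3e5, stringsAsFactors = FALSE)
}
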