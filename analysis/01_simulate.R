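#!/usr/bin/env Rscript
# Generate one synthetic study's worth of raw data with known ground truth:
# OCT volumes, confocal stacks, a calibration series, ratiometric image
# pairs, and a clustered trial table. Everything downstream (02-05) reads
# from data/synthetic/ and never sees the truth except through the saved
# truth tables.

suppressPackageStartupMessages(library(biofilmq))

seed <- 20260924L
out <- "data/synthetic"
dir.create(file.path(out, "oct"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "clsm"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "ph"), recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

## OCT volumes: 12 carriers with planted mean thicknesses 5-50 um ----------
oct_truth <- data.frame(carrier = sprintf("C%02d", 1:12),
                        planted_um = seq(5, 50, length.out = 12),
                        truth_um = NA_real_)
for (i in 1:12) {
  sim <- gen_oct_volume(c(64, 64, 128), mean_thickness = oct_truth$planted_um[i],
                        seed = seed + i)
  write_oct_tiff(sim$volume, file.path(out, "oct",
                                       paste0(oct_truth$carrier[i], ".tif")))
  oct_truth$truth_um[i] <- sim$truth$mean_thickness
}
write.csv(oct_truth, file.path(out, "oct_truth.csv"), row.names = FALSE)
cat("wrote", nrow(oct_truth), "OCT volumes; planted means",
    paste(range(oct_truth$planted_um), collapse = "-"), "um\n")

## Confocal stacks: 12 three-slice stacks --------------------------------
clsm_truth <- data.frame(stack = sprintf("Z%02d", 1:12), truth_um3 = NA_real_)
for (i in 1:12) {
  sim <- gen_clsm_stack(c(256, 256), n_slices = 3,
                        object_density = 0.01 + 0.01 * i,
                        slice_spacing = 2, seed = seed + 100 + i)
  write_clsm_tiff(sim$stack, file.path(out, "clsm",
                                       paste0(clsm_truth$stack[i], ".tif")))
  clsm_truth$truth_um3[i] <- sim$truth$true_biovolume
}
write.csv(clsm_truth, file.path(out, "clsm_truth.csv"), row.names = FALSE)
cat("wrote", nrow(clsm_truth), "confocal stacks\n")

## Calibration series and ratiometric pairs ------------------------------
write_calibration_csv(gen_calibration_table(noise_sd = 0.01, seed = seed),
                      file.path(out, "calibration.csv"))
ph_truth <- data.frame(field = sprintf("F%02d", 1:8),
                       true_ph = rep(c(5.0, 5.5, 6.0, 6.5), 2))
for (i in 1:8) {
  sim <- gen_ratiometric_pair(c(128, 128), true_ph = ph_truth$true_ph[i],
                              cell_density = 10, noise_sd = 0.05,
                              seed = seed + 200 + i)
  write_ratio_pair_tiff(sim$pair, file.path(out, "ph", ph_truth$field[i]))
}
write.csv(ph_truth, file.path(out, "ph_truth.csv"), row.names = FALSE)
cat("wrote calibration series (20 buffers) and", nrow(ph_truth),
    "ratiometric image pairs\n")

## Trial table: 11 participants, 6 biofilms per arm, 3 planted outliers ---
trial <- gen_trial_dataset(n_participants = 11, n_per_arm = 6,
                           effect_ratio = 1.05, participant_cv = 0.3,
                           shape = 8, n_outliers = 3, seed = seed + 300)
write_trial_csv(trial$table, file.path(out, "trial.csv"))
write.csv(data.frame(outlier_index = trial$truth$outlier_indices),
          file.path(out, "trial_outlier_truth.csv"), row.names = FALSE)
cat("wrote trial table:", nrow(trial$table), "records, planted effect ratio",
    trial$truth$effect_ratio, "with", length(trial$truth$outlier_indices),
    "planted outliers\n")
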