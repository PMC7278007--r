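#!/usr/bin/env Rscript
# Convert each case's MR to a synthetic CT: EM tissue segmentation into
# six classes, hard masks, HU lookup. Reads the cohort written by
# 01_simulate_cohort.R and writes sct.nii.gz next to each case.

library(sctdose)

out_dir <- "results/cohort"
manifest <- read.csv(file.path(out_dir, "manifest.csv"))

for (i in seq_len(nrow(manifest))) {
  dir <- file.path(out_dir, manifest$case_id[i])
  mr <- read_volume(file.path(dir, "mr.nii.gz"))
  sct <- run_sct_pipeline(mr, seed = manifest$seed[i] + 1)
  write_volume(sct, file.path(dir, "sct.nii.gz"))
  message(manifest$case_id[i], ": sCT written (",
          sum(sct$values == 942), " bone voxels)")
}
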