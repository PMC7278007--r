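#!/usr/bin/env Rscript
# Bone segmentation accuracy of the sCT against the CT: 300 HU bone
# masks, volumes and relative difference, whole-skull Dice coefficient,
# and MAE over the crown-to-cranial-base body region.

library(sctdose)

out_dir <- "results/cohort"
manifest <- read.csv(file.path(out_dir, "manifest.csv"))

rows <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
  dir <- file.path(out_dir, manifest$case_id[i])
  ct <- read_volume(file.path(dir, "ct.nii.gz"))
  sct <- read_volume(file.path(dir, "sct.nii.gz"))
  body <- read_mask(file.path(dir, "body.nii.gz"))
  cbind(case_id = manifest$case_id[i], group = manifest$group[i],
        bone_report(ct, sct, body))
}))

write.csv(rows, "results/bone_metrics.csv", row.names = FALSE)
message("per-group bone metrics:")
print(aggregate(cbind(dsc, mae_hu, dv_pct) ~ group, rows, function(x)
  sprintf("%.3f (%.3f)", mean(x), sd(x))))
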