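#!/usr/bin/env Rscript
# Generate the synthetic head-phantom cohort (10 glioma + 10 metastasis)
# at desk scale and write the per-case volumes and structures to disk.
#
# The cohort emulates the clinical study conditions: GTV volumes drawn
# uniformly from the group's clinical range, 2 mm slices for glioma and
# 1 mm for metastasis cases (coarsened by spacing_scale = 3 here), a
# contrast-enhanced lesion, CT noise, a continuous skull HU gradient and
# partial-volume blur.

library(sctdose)

seed <- 1
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- generate_cohort(10, 10, seed = seed, spacing_scale = 3)

manifest <- do.call(rbind, lapply(seq_along(cohort), function(i) {
  case <- cohort[[i]]
  id <- sprintf("%s_%02d", case$config$group, i)
  dir <- file.path(out_dir, id)
  dir.create(dir, showWarnings = FALSE)
  write_volume(case$ct, file.path(dir, "ct.nii.gz"))
  write_volume(case$mr, file.path(dir, "mr.nii.gz"))
  write_mask(case$structures$body, file.path(dir, "body.nii.gz"))
  write_mask(case$structures$gtv, file.path(dir, "gtv.nii.gz"))
  write_mask(case$structures$ptv, file.path(dir, "ptv.nii.gz"))
  jsonlite::write_json(
    list(prescription_gy = case$plan$prescription_gy,
         beams = case$plan$beams),
    file.path(dir, "plan.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  data.frame(case_id = id, group = case$config$group, seed = case$config$seed,
             gtv_cm3 = mask_volume_cm3(case$structures$gtv),
             ptv_cm3 = mask_volume_cm3(case$structures$ptv))
}))

write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
message("wrote ", nrow(manifest), " cases to ", out_dir)
print(aggregate(cbind(gtv_cm3, ptv_cm3) ~ group, manifest, function(x)
  sprintf("%.1f [%.1f-%.1f]", mean(x), min(x), max(x))))
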