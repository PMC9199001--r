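#!/usr/bin/env Rscript
# Generate the synthetic study dataset: 20 participants, 16 non-overlapping
# 0.16 mm^2 images per corneal region, participant densities gamma-matched to
# the published summaries (central 21.7 +/- 17.7, peripheral 62.0 +/- 26.1
# cells/mm^2), Poisson counting noise. Writes counts.csv + provenance.json.

library(icdensity)

out_dir <- "results/simulation"
cfg <- generator_config(seed = 20260925)
counts <- run_simulation(cfg, out_dir)

report <- validate_image_set(counts)
stopifnot(nrow(report) == 0)

tm <- true_mean_table(counts)
summ <- dplyr::summarise(dplyr::group_by(tm, region),
                         mean = mean(true_mean), sd = sd(true_mean))
cat(sprintf("records: %d (expected 640)\n", nrow(counts)))
cat(sprintf("quantified area per participant-region: %.2f mm^2\n",
            tm$total_area_mm2[1]))
print(as.data.frame(summ), row.names = FALSE)
cat(sprintf("outputs in %s\n", out_dir))
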