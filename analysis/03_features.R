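#!/usr/bin/env Rscript
# Stage 3: extract the rhythm features driving the AF decision.
#
# R peaks (Pan-Tompkins style energy detector), RR irregularity statistics
# (CV, normalized RMSSD, pNN50), the P-wave presence score, and the QRS
# amplitude.

suppressPackageStartupMessages(library(afscreen))
filtered <- readRDS("scratch/02_filtered.rds")
manifest <- read.csv("results/cohort_manifest.csv")

features <- lapply(filtered, extract_features)
saveRDS(features, "scratch/03_features.rds")
df <- features_to_df(features, manifest$record_id)
write.csv(df, "results/features.csv", row.names = FALSE)

df$true_rhythm <- manifest$true_rhythm
agg <- aggregate(cbind(rr_cv, p_score) ~ true_rhythm, df, median)
cat("median RR coefficient of variation and P score by true rhythm:\n")
print(agg, digits = 2)
cat(sprintf("records with fewer than 4 detectable beats: %d\n",
            sum(df$n_beats < 4)))
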