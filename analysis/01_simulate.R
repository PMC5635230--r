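#!/usr/bin/env Rscript
# Stage 1: simulate the screening cohort.
#
# 500 residents at community screening conditions: age 58.1 (SD 15.0),
# AF prevalence 4.1% above 65 / 0.8% at or below, the observed non-AF
# rhythm mix (sinus with and without ectopy, junctional, paced), and the
# observed artifact grade mix 83.5/12.8/2.7/0.8/0.2%. Waveforms go to
# scratch/ (they are bulky); the manifest is the deliverable table.

suppressPackageStartupMessages(library(afscreen))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

spec <- cohort_spec(n_subjects = 500, seed = 20160311)
coh <- generate_cohort(spec)

write_manifest(coh$manifest, "results/cohort_manifest.csv")
saveRDS(coh$records, "scratch/01_records.rds")

m <- coh$manifest
cat(sprintf("simulated %d ECGs from %d subjects (%.1f%% female, %d aged >65)\n",
            nrow(m), spec$n_subjects, 100 * mean(m$sex == "F"),
            sum(m$age[!duplicated(m$subject_id)] > 65)))
cat("rhythm mix:\n"); print(table(m$true_rhythm))
cat("injected grade mix:\n"); print(table(m$grade_class))
first <- m[!duplicated(m$subject_id), ]
cat(sprintf("subject-level AF prevalence: %.1f%% (>65: %.1f%%, <=65: %.1f%%)\n",
            100 * mean(first$is_af),
            100 * mean(first$is_af[first$age > 65]),
            100 * mean(first$is_af[first$age <= 65])))
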