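#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates 51 synthetic seated-child sessions (20 hyperactivity-risk,
# 31 control; 180 s at 30 fps) with the generator defaults: distal limb
# amplitudes doubled in the risk arm, confidence dropouts in bursts, and
# teacher ratings coupled to latent activity. Sessions go to
# scratch/sessions/ (large, regenerable); metadata to results/.

suppressPackageStartupMessages(library(povmotion))

seed <- 1L
dir.create("results", showWarnings = FALSE)
dir.create("scratch/sessions", recursive = TRUE, showWarnings = FALSE)

spec <- cohort_spec(seed = seed)
cat(sprintf("simulating %d risk + %d control sessions (%g s at %g fps)\n",
            spec$n_risk, spec$n_control, spec$duration_s, spec$fps))
cohort <- generate_cohort(spec)

for (s in cohort$sessions)
  write_session(s, file.path("scratch/sessions",
                             paste0(s$participant_id, ".csv")))
write_metadata(cohort$metadata, "results/metadata.csv")

md <- cohort$metadata
cat(sprintf("teacher hyperactivity scores: risk mean %.2f (sd %.2f), control mean %.2f (sd %.2f)\n",
            mean(md$conners_score[md$group == "risk"]),
            sd(md$conners_score[md$group == "risk"]),
            mean(md$conners_score[md$group == "control"]),
            sd(md$conners_score[md$group == "control"])))
cat(sprintf("ages %d-%d months; %d boys / %d girls\n",
            min(md$age_months), max(md$age_months),
            sum(md$sex == "boy"), sum(md$sex == "girl")))
cat("wrote scratch/sessions/*.csv and results/metadata.csv\n")
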