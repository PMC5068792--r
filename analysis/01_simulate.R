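#!/usr/bin/env Rscript
# Generate the two synthetic datasets the downstream analyses consume:
# a six-site field survey along a pH gradient (nested incidence with
# dominance turnover) and a two-inoculum x three-pH glasshouse experiment.
suppressMessages(library(nestgrad))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(regime = "nested", dominance_shift = TRUE, seed = 1)
survey <- simulate_communities(cfg)
write_sample_table(survey$samples, "results/data/survey_samples.tsv")
write.table(survey$truth$phylotypes, "results/data/survey_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_group_metadata(attr(survey$samples, "groups"),
                     "results/data/survey_groups.json")

ex <- simulate_ph_experiment(seed = 2)
write_sample_table(ex$samples, "results/data/experiment_samples.tsv")
write.table(data.frame(sample_id = unique(ex$samples$sample_id),
                       inoculum = ex$inoculum, ph_level = ex$ph_level),
            "results/data/experiment_factors.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "survey: %d occurrence records, %d samples, %d phylotypes across %d sites\n",
  nrow(survey$samples), length(unique(survey$samples$sample_id)),
  length(unique(survey$samples$phylotype)),
  nrow(attr(survey$samples, "groups"))))
cat(sprintf("experiment: %d pots in %d treatment cells\n",
            length(unique(ex$samples$sample_id)),
            length(unique(ex$samples$group))))
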