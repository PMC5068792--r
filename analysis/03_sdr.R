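#!/usr/bin/env Rscript
# Similarity-difference-replacement decomposition of all site pairs, in
# presence/absence and abundance modes, to ask how much of the pattern is
# nestedness versus phylotype (dominance) turnover.
suppressMessages(library(nestgrad))

rel <- read_community_matrix("results/survey_matrix_relabund.tsv",
                             cell_kind = "relative_abundance_percent")
pres <- to_presence_absence(rel)
bin <- sdr_simplex(pres, mode = "binary")
abn <- sdr_simplex(rel, mode = "abundance")
print(bin)
print(abn)

write.table(rbind(cbind(mode = "binary", bin$pairs),
                  cbind(mode = "abundance", abn$pairs)),
            "results/survey_sdr_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
summary <- data.frame(
  mode = c("binary", "abundance"),
  pct_turnover = c(bin$pct_turnover, abn$pct_turnover),
  pct_agreement = c(bin$pct_agreement, abn$pct_agreement),
  pct_nestedness = c(bin$pct_nestedness, abn$pct_nestedness))
write.table(summary, "results/survey_sdr_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nA drop in the nestedness contribution (and rise in turnover) from",
    "the\nbinary to the abundance mode indicates dominance turnover over a",
    "nested\nincidence skeleton.\n")
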