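#!/usr/bin/env Rscript
# Is pH the driver? Sample-level PERMANOVA (Jaccard distances) for the
# survey sites and the crossed glasshouse design, and a site-level Mantel
# test of community dissimilarity (Morisita-Horn) against pH difference.
suppressMessages(library(nestgrad))

st <- read_sample_table("results/data/survey_samples.tsv")
sm <- sample_matrix(st, presence = TRUE)
d <- community_distance(sm, "jaccard", along = "rows")
perm <- permanova_oneway(d, attr(sm, "group"), n_perm = 9999, seed = 41)
cat("Survey, one-way PERMANOVA (site):\n")
print(perm)

pooled <- pool_to_matrix(st)
pooled <- sort_columns_by_gradient(pooled)
rel <- normalize_relative_abundance(pooled, attr(st, "groups"))
site_ph <- attr(rel, "col_gradient")
man <- mantel_test(community_distance(rel, "morisita_horn"),
                   env_distance(site_ph), n_perm = 9999, seed = 42)
cat("\nSurvey, Mantel (community dissimilarity vs pH difference):\n")
print(man)

ex_st <- read_sample_table("results/data/experiment_samples.tsv")
fac <- read.table("results/data/experiment_factors.tsv", header = TRUE,
                  sep = "\t")
ex_sm <- sample_matrix(ex_st, presence = TRUE)
fac <- fac[match(rownames(ex_sm), fac$sample_id), ]
tw <- permanova_twoway(community_distance(ex_sm, "jaccard", along = "rows"),
                       fac$ph_level, fac$inoculum, n_perm = 9999, seed = 43)
cat("\nGlasshouse, two-way PERMANOVA (pH x inoculum):\n")
print(tw)

write.table(rbind(
  data.frame(analysis = "survey_oneway", term = perm$terms$term,
             df = perm$terms$df, pseudo_f = perm$terms$pseudo_f,
             p = perm$terms$p),
  data.frame(analysis = "experiment_twoway", term = tw$terms$term,
             df = tw$terms$df, pseudo_f = tw$terms$pseudo_f, p = tw$terms$p),
  data.frame(analysis = "survey_mantel", term = "ph_distance", df = NA,
             pseudo_f = NA, p = man$p)),
  "results/multivariate_tests.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
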