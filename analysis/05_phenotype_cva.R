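#!/usr/bin/env Rscript
# Stage 5: computational phenotyping by canonical correlation analysis.
#
# The per-subject model-averaged parameters (four constants plus the two
# surviving preference decay terms) are correlated with the behavioural
# measures (mean score per trial, percentage correct, mean saccades per
# trial, mean time between saccades). Dimensionality is assessed with
# Bartlett chi-squared tests. The qualitative phenotype of interest:
# heuristic bias loads against percentage correct.

suppressPackageStartupMessages(library(epiforage))

bma_df <- read.csv("results/bma.csv", check.names = FALSE,
                   stringsAsFactors = FALSE)
summaries <- read.csv("results/cohort/summaries.csv",
                      stringsAsFactors = FALSE)
beh <- behavioural_measures(summaries)
stopifnot(identical(bma_df$subject_id, beh$subject_id))

X <- as.matrix(bma_df[, c("ln_beta_const", "E_h_const", "ln_C_cor_const",
                          "ln_C_q_const", "ln_C_cor_decay", "ln_C_q_decay")])
cv <- phenotype_cva(X, beh)
print(cv)
jsonlite::write_json(
  list(correlations = cv$correlations, chi2 = cv$chi2, df = cv$df,
       log_p = cv$log_p,
       x_vectors = as.data.frame(cv$x_vectors),
       y_vectors = as.data.frame(cv$y_vectors),
       x_loadings = as.data.frame(cv$x_loadings),
       y_loadings = as.data.frame(cv$y_loadings),
       x_variates = as.data.frame(cv$x_variates),
       y_variates = as.data.frame(cv$y_variates)),
  "results/cva.json", auto_unbox = TRUE, digits = NA)

s_eh <- sign(cv$x_loadings["E_h_const", 1])
s_pct <- sign(cv$y_loadings["pct_correct", 1])
message("leading pair: heuristic bias loading ", round(s_eh, 2),
        ", percentage-correct loading ", round(s_pct, 2),
        if (s_eh != s_pct) " -- opposite signs (phenotype present)" else "")
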