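#!/usr/bin/env Rscript
# Stage 4: between-block effects by PEB, BMR and model averaging.
#
# A per-subject general linear model (constant + one-block exponential
# decay) is placed over the block posteriors; all 256 on/off combinations
# of the 8 second-level effects are scored analytically by Bayesian model
# reduction, evidence is pooled over subjects, and model-averaged effects
# are written per subject. The expected winner excludes the decay of the
# policy precision and of the heuristic bias (drift is planted on the
# preference scales only).

suppressPackageStartupMessages(library(epiforage))

files <- list.files("results/posteriors", full.names = TRUE)
sids <- unique(sub("_block.*", "", basename(files)))
pebs <- lapply(sids, function(sid) {
  bfiles <- sort(files[startsWith(basename(files), paste0(sid, "_"))])
  peb_fit(lapply(bfiles, read_posterior_json))
})
ms <- search_model_space(pebs)
win <- ms$winning$pattern
message("winning pattern: ", paste(names(win)[win], collapse = ", "))
message("posterior probability of winner: ",
        signif(max(ms$posterior_prob), 3))

avg <- bma(ms)
bma_df <- data.frame(subject_id = sids, avg$mean, check.names = FALSE)
write.csv(bma_df, "results/bma.csv", row.names = FALSE)
jsonlite::write_json(
  list(pooled_logev = ms$pooled_logev,
       posterior_prob = ms$posterior_prob,
       winning_index = ms$winning$index,
       winning_pattern = as.list(win)),
  "results/model_space.json", auto_unbox = TRUE, digits = NA)
message("wrote results/bma.csv and results/model_space.json")
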