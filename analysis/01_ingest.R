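#!/usr/bin/env Rscript
# Stage 1 — ingest: load the 61-hazard codebook and the 327 coded accident
# chains, apply the length->=2 validity filter, and summarize the corpus.

suppressPackageStartupMessages(library(cehn))
dir.create("results", showWarnings = FALSE)

codebook <- beijing_codebook()
corpus <- beijing_chains(codebook)
lens <- vapply(corpus$chains, length, integer(1))

message(sprintf("codebook: %d hazards in %d categories",
                nrow(codebook), length(unique(codebook$category))))
message(sprintf("corpus: %d chains retained, %d excluded; lengths %d-%d (mean %.2f)",
                length(corpus$chains), corpus$excluded_count,
                min(lens), max(lens), mean(lens)))

prevalence <- vapply(codebook$code, function(code) {
  sum(vapply(corpus$chains, function(ch) code %in% as.integer(ch), logical(1)))
}, integer(1))
tab <- data.frame(code = codebook$code, label = codebook$label,
                  category = codebook$category,
                  n_chains = prevalence,
                  pct_chains = round(100 * prevalence / length(corpus$chains), 2))
tab <- tab[order(-tab$n_chains, tab$code), ]
write.csv(tab, "results/01_hazard_prevalence.csv", row.names = FALSE)
message(sprintf("most prevalent hazard: %s (code %d), in %.2f%% of chains",
                tab$label[1], tab$code[1], tab$pct_chains[1]))
message("wrote results/01_hazard_prevalence.csv")
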