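#!/usr/bin/env Rscript
# Stage 4 — critical-hazard identification: classify each hazard as
# trigger / transitional / consequence from its strength asymmetry and
# emit the top-10 ranked tables.

suppressPackageStartupMessages(library(cehn))
dir.create("results", showWarnings = FALSE)

res <- run_pipeline(pipeline_config(tau = 0.2, k = 10,
                                    out_dir = "results/04_report"),
                    quiet = FALSE)

roles <- res$report$roles
message("role counts: ",
        paste(sprintf("%s=%d", names(table(roles$role)), table(roles$role)),
              collapse = ", "))
trig <- roles[roles$role == "trigger", ]
trig <- trig[order(-abs(trig$asymmetry)), ]
message("strongest triggers: ",
        paste(head(trig$label, 3), collapse = "; "))
message("see results/04_report/ for ranked tables and run summary")
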