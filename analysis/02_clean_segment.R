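#!/usr/bin/env Rscript

## Stage 2 — clean the raw fixes (satellite/HDOP filter) and segment them
## into individual-nights with weather attached; write the cleaned fixes,
## the removal report and the night exclusion report.

suppressPackageStartupMessages(library(owltrack))

sim <- "results/simulated"
out <- "results/clean"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- read.csv(file.path(sim, "individuals.csv"))
weather <- read_weather(file.path(sim, "weather.csv"))

reports <- list(); exclusions <- list(); all_clean <- list()
for (i in seq_len(nrow(meta))) {
  id <- meta$id[i]
  raw <- read_fixes(file.path(sim, paste0(id, "_fixes.csv")))
  fl <- filter_fixes(raw)
  reports[[i]] <- cbind(id = id, fl$report)
  seg <- attach_weather(segment_nights(fl$fixes), weather)
  exclusions[[i]] <- seg$exclusions
  clean <- do.call(rbind, lapply(seg$segments, function(s) s$fixes))
  all_clean[[i]] <- clean
  message(sprintf("%s: %d -> %d fixes (%.1f%% removed), %d night segments",
                  id, fl$report$n_in, nrow(clean), fl$report$pct_removed,
                  length(seg$segments)))
}
rep_tab <- do.call(rbind, reports)
write.csv(rep_tab, file.path(out, "removal_report.csv"), row.names = FALSE)
write.csv(do.call(rbind, exclusions), file.path(out, "night_exclusions.csv"),
          row.names = FALSE)
write_fixes(do.call(rbind, all_clean), file.path(out, "clean_fixes.csv"))
message(sprintf("overall removal: %.1f%% of %d fixes",
                100 * sum(rep_tab$n_removed) / sum(rep_tab$n_in),
                sum(rep_tab$n_in)))
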