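#!/usr/bin/env Rscript
# Discrete typing: tempo modes from a KDE over coda durations (with a
# bandwidth-robustness sweep) and rhythm centroids by per-click-count
# k-means. Writes the fitted models and the per-coda type table.

library(codacomb)

codas <- filter_clicks(read_codas("results/sim/contextual/codas.csv"), 10)
durations <- coda_duration(codas)

sweep <- tempo_bandwidth_sweep(durations)
print(sweep)
message("mode count as a function of bandwidth above; the analysis uses")
message("a 0.05 s bandwidth, the within-mode duration sd scale")

tempo <- fit_tempo_model(durations, bandwidth = 0.05)
print(tempo)

rhythm <- fit_rhythm_model(codas, c("4" = 1, "5" = 2, "6" = 1, "8" = 1,
                                    "9" = 1))
print(rhythm)

types <- assign_types(codas, tempo, rhythm)
message(sprintf("%d/%d codas typed (%d unassignable click counts)",
                sum(!is.na(types$discrete_type)), nrow(types),
                sum(is.na(types$discrete_type))))

dir.create("results/models", showWarnings = FALSE, recursive = TRUE)
write_rhythm_model(rhythm, "results/models/rhythm_centroids.csv")
utils::write.csv(
  data.frame(mode = tempo$mode_locations,
             lower = c(0, tempo$boundaries),
             upper = c(tempo$boundaries, Inf)),
  "results/models/tempo_modes.csv", row.names = FALSE)
utils::write.csv(types, "results/types.csv", row.names = FALSE)
message("written to results/models/ and results/types.csv")
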