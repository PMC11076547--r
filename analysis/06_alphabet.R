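#!/usr/bin/env Rscript
# The phonetic alphabet: rhythm x tempo co-occurrence annotated with
# rubato and ornamentation, the realised-combination threshold sweep,
# information-capacity summaries, and an exchange-plot figure.

library(codacomb)

codas <- filter_clicks(read_codas("results/sim/contextual/codas.csv"), 10)
types <- utils::read.csv("results/types.csv")
orn <- utils::read.csv("results/ornaments.csv")
rub <- rubato_classes(codas)

ann <- feature_annotations(types, orn, rub)
alpha <- build_alphabet(ann)
print(alpha, n = Inf)

sweep <- realized_sweep(ann, 1:20)
print(sweep, n = 20)
message(sprintf("%d rhythm x tempo cells realised; %d feature 4-tuples at",
                nrow(alpha), count_realized(ann, 5)))
message("threshold 5 (sweep above; the synthetic repertoire is small by design)")

cap <- capacity_bits(nrow(alpha))
message(sprintf("cell repertoire capacity: %.2f bits/coda (ceiling %d)",
                cap$bits, cap$bits_ceiling))
message(sprintf("full feature system (18 rhythms x 5 tempos x ornament x rubato): %.2f bits",
                feature_capacity(18, 5, 2, 3)))

utils::write.csv(alpha, "results/alphabet.csv", row.names = FALSE)
utils::write.csv(sweep, "results/alphabet_sweep.csv", row.names = FALSE)

render_exchange(codas, "results/exchange_plot.png",
                from = 0, to = 120, link = TRUE,
                ornaments = detect_ornaments(codas))
message("written to results/alphabet.csv, results/alphabet_sweep.csv, ",
        "results/exchange_plot.png")
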