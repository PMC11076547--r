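#!/usr/bin/env Rscript
# Conversational structure of the simulated exchange: call sequences
# (8 s gap rule), turn-taking/overlap links, choruses and roles. Emits
# one row per coda with its sequence, chorus and role annotations.

library(codacomb)

codas <- read_codas("results/sim/contextual/codas.csv")

seqs <- call_sequences(codas)
links <- coda_links(codas)
ch <- choruses(codas)
roles <- leader_follower(codas, ch)

message(sprintf("%d call sequences (median length %d codas)",
                length(unique(seqs$sequence_id)),
                as.integer(stats::median(seqs$seq_len))))
message(sprintf("%d links: %s", nrow(links),
                paste(names(table(links$relation)), table(links$relation),
                      collapse = ", ", sep = "=")))
message(sprintf("%d choruses covering %.0f%% of codas",
                nrow(ch$summary),
                100 * mean(!is.na(ch$membership$chorus_id))))

role_of <- function(cid, wid) {
  if (is.na(cid)) return(NA_character_)
  r <- roles$role[roles$chorus_id == cid & roles$whale_id == wid]
  if (length(r) == 1) r else NA_character_
}
out <- data.frame(
  coda_id = codas$coda_id, whale_id = codas$whale_id,
  sequence_id = seqs$sequence_id, seq_index = seqs$seq_index,
  chorus_id = ch$membership$chorus_id)
out$role <- mapply(role_of, out$chorus_id, out$whale_id)

dir.create("results", showWarnings = FALSE)
utils::write.csv(out, "results/segments.csv", row.names = FALSE)
message("written to results/segments.csv")
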