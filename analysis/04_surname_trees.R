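#!/usr/bin/env Rscript
# Robustness of the surname classification: 100 surname-type bootstrap
# replicates, one neighbor-joining tree per replicate, majority-rule
# consensus with percent supports; branches below 50 are collapsed.
# Run for both the Nei and the Hedrick distance, then scored against the
# planted kingdoms.

library(isonymia)
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

tt <- read_token_table("results/token_table.tsv")
truth <- read.delim("results/truth_kingdoms.tsv")
clades <- split(truth$region, truth$kingdom)

for (kind in c("nei", "hedrick")) {
  cons <- bootstrap_consensus_pipeline(tt, kind, replicates = 100,
                                       collapse_cutoff = 50, seed = seed + 10L)
  write_newick(cons, sprintf("results/consensus_%s.nwk", kind))
  sup <- vapply(clades, clade_support, integer(1), consensus = cons)
  cat(sprintf("%s consensus: %d retained splits (%d replicates rejected)\n",
              kind, length(cons$splits), cons$rejected))
  cat(sprintf("  planted kingdom supports: %s\n",
              paste(sprintf("K%s=%d", names(sup), sup), collapse = ", ")))
}
cat("wrote results/consensus_{nei,hedrick}.nwk\n")
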