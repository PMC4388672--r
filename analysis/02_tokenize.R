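#!/usr/bin/env Rscript
# Tokenize the roster (two tokens per double surname, one per single),
# apply the municipal (>= 5 bearers per municipality) and global (>= 20
# occurrences) cutoffs, aggregate to regions, and summarise diversity:
# token counts, surname types, random isonymy and entropy per region.

library(isonymia)

roster <- read_roster("results/roster.tsv")
tt_muni <- tokenize(roster)
tt_filt <- filter_municipal(tt_muni, 5)
tt <- filter_global(aggregate_regions(tt_filt), 20)

write_token_table(tt, "results/token_table.tsv",
                  cutoffs = list(municipal = 5, global = 20))
summ <- merge(corpus_summary(tt), region_diversity(tt), by = "region")
write.table(summ, "results/region_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("tokens: %d raw -> %d after municipal cutoff -> %d after global cutoff\n",
            sum(tt_muni$counts), sum(tt_filt$counts), sum(tt$counts)))
cat(sprintf("%d regions x %d surnames; isonymy %.4f-%.4f, entropy %.2f-%.2f\n",
            nrow(tt$counts), ncol(tt$counts),
            min(summ$isonymy), max(summ$isonymy),
            min(summ$entropy), max(summ$entropy)))
cat("wrote results/token_table.tsv, region_summary.tsv\n")
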