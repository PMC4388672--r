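#!/usr/bin/env Rscript
# Pairwise Nei and Hedrick surname distances between regions (negative
# log of the similarity coefficients), written as PHYLIP square matrices,
# plus the great-circle geographic distance matrix.

library(isonymia)

tt <- read_token_table("results/token_table.tsv")
geo <- read.delim("results/geography.tsv")

for (kind in c("nei", "hedrick")) {
  D <- distance_matrix(tt, kind)
  write_phylip_matrix(D, sprintf("results/distance_%s.phy", kind))
  cat(sprintf("%s distance: %d x %d, off-diagonal range %.4f-%.4f\n",
              kind, nrow(D), ncol(D), min(D[upper.tri(D)]), max(D[upper.tri(D)])))
}
G <- geographic_distance_matrix(geo[match(rownames(tt$counts), geo$region), ])
write_phylip_matrix(G, "results/distance_geographic.phy")
cat(sprintf("geographic distance: %.0f-%.0f km\n",
            min(G[upper.tri(G)]), max(G[upper.tri(G)])))
cat("wrote results/distance_{nei,hedrick,geographic}.phy\n")
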