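#!/usr/bin/env Rscript
# Cycle 2: call DEGs in the tumor and PBMC compartments (Welch t, BH,
# |logFC| > 0.5 and adjusted P < 0.05), intersect them with direction
# agreement, then intersect the shared set with the central genes from
# cycle 1 to obtain the consensus biomarker.

library(netmark)

tumor <- call_degs(read_expression("results/demo/tumor_expr.tsv",
                                   "results/demo/tumor_groups.tsv"))
pbmc <- call_degs(read_expression("results/demo/pbmc_expr.tsv",
                                  "results/demo/pbmc_groups.tsv"))
write_table(tumor, "results/degs_tumor.tsv")
write_table(pbmc, "results/degs_pbmc.tsv")

central_tab <- utils::read.delim("results/topology_central.tsv")
net <- read_edgelist("results/demo/network.tsv")
central <- select_central(net, 0.20, list(type = "top_k", k = 6))

shared <- shared_degs(tumor, pbmc)
res <- consensus_with_central(shared, central)
write_table(res$provenance, "results/consensus.tsv")

cat("tumor DEGs:", sum(tumor$significant),
    "| PBMC DEGs:", sum(pbmc$significant), "\n")
cat("shared same-direction DEGs:", paste(res$shared_degs, collapse = ", "), "\n")
cat("consensus biomarker(s):",
    if (length(res$consensus)) paste(res$consensus, collapse = ", ") else "(none)",
    "-> results/consensus.tsv\n")
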