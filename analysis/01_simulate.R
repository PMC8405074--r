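#!/usr/bin/env Rscript
# Generate the synthetic two-compartment breast-cancer study that the rest
# of the analysis consumes: a scale-free cancer-signature network, tumor
# and PBMC case/control expression, a co-expression matrix with a planted
# module, a gene-set library, a survival table and a 3-group qPCR table.
# One gene (aliased CCNB2) is planted as the top network hub AND an
# up-regulated DEG in both compartments; a peripheral gene (aliased PGK1)
# is planted as a shared DEG only.

library(netmark)

seed <- 7
config <- make_demo(seed = seed, out_dir = "results/demo",
                    n_genes = 100, n_coexpr_genes = 30)
truth <- config$truth

cat("synthetic study written to results/demo (seed", seed, ")\n")
cat("planted consensus gene:", truth$consensus_gene, "\n")
cat("planted shared DEGs:   ", paste(truth$shared_genes, collapse = ", "), "\n")
cat("planted network hubs:  ", paste(truth$hub_genes, collapse = ", "), "\n")
cat("planted module size:   ", length(truth$module_genes), "genes\n")
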