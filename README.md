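# netmark

Consensus network biomarker discovery from paired tumor / peripheral-blood
expression data.

## The problem

Solid tumors leave a molecular fingerprint in circulating immune cells:
peripheral blood mononuclear cells (PBMCs) shift their transcriptome in
cancer patients, which makes them attractive for non-invasive diagnosis.
The catch is that genes differentially expressed in any one comparison are
often transient or dataset-specific. netmark implements a two-cycle
strategy that requires a candidate biomarker to survive **three**
independent filters before it is reported:

1. **Topological centrality** (cycle 1). A pan-cancer signature gene set
   is consumed as a protein-protein interaction network; each gene is
   scored by degree and betweenness centrality, and the *central* set is

   *central* = *hubs* (top-k degree) ∪ *high-betweenness* (inclusive top
   20% among mediating nodes),

   with the fat-tailedness of the degree distribution summarized by the
   R² of a least-squares fit of log *f*(*d*) on log *d*.

2. **Cross-compartment differential expression** (cycle 2). Per gene and
   compartment (tumor, PBMC), logFC = mean(case) − mean(control) on log2
   data with a two-sided Welch t-test; Benjamini–Hochberg across genes; a
   gene is a DEG when |logFC| > 0.5 and adjusted P < 0.05 jointly. Shared
   DEGs must be significant in both compartments with the same direction.

3. **Consensus**: shared DEGs ∩ central genes, with a per-gene provenance
   table recording which criteria each gene met.

The consensus gene is then characterized downstream: an ARACNE-style
co-expression module (plug-in mutual information on equal-frequency bins,
permutation significance threshold, data-processing-inequality pruning
MI(i,j) < min(MI(i,k), MI(j,k))·(1−ε), first-neighborhood extraction);
Fisher-exact (hypergeometric upper tail) gene-set enrichment against a GMT
library; Kaplan–Meier survival of median-expression strata with a log-rank
test and an O/E hazard ratio (O₁/E₁)/(O₂/E₂); and comparative ΔΔCt qPCR
quantification, fold = 2^(−ΔΔCt), with a Kruskal–Wallis group test.

A seeded synthetic-data generator with planted ground truth (planted fold
changes, scale-free networks with known hubs, latent-factor co-expression
modules, expression-linked hazards, planted Ct shifts) drives the whole
pipeline end to end, so every stage is testable without downloads. See
`vignettes/consensus-biomarker-discovery.Rmd` for the models, parameter
defaults and design decisions.

## Worked example

The numbered drivers under `analysis/` run the complete study on a bundled
synthetic dataset in which one gene (aliased *CCNB2*) is planted as the
network's top hub **and** an up-regulated DEG in both compartments, while
a second gene (aliased *PGK1*) is a shared DEG but topologically
peripheral:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_topology.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_coexpression_enrichment.R
Rscript analysis/05_survival_qpcr.R
```

which prints (seed 7):

```
network: 100 nodes, 197 edges
log-log degree-distribution R^2 = 0.924 (fat tail => hubs)
hub genes (top 6 by degree): CCNB2, G0001, G0002, G0004, G0011, G0040
...
tumor DEGs: 5 | PBMC DEGs: 5
shared same-direction DEGs: CCNB2, PGK1
consensus biomarker(s): CCNB2 -> results/consensus.tsv
...
MI threshold: 0.5620 nats; surviving edges: 90
CCNB2 module: 12 genes -> results/module.tsv
top term: PLANTED_MODULE (overlap 12/12, adj P = 1.27e-07)
...
survival (5-year horizon): HR = 2.18, log-rank chi2 = 22.52, p = 0.0000
qPCR fold changes vs primary-stage reference:
  healthy    mean fold =   2.62 (n = 8)
  primary    mean fold =   1.00 (n = 8)
  metastatic mean fold =  23.79 (n = 8)
Kruskal-Wallis: H = 20.48, p = 3.57e-05
```

Reading the output: the degree distribution's high R² flags a hub
structure; of the two shared DEGs only *CCNB2* is also central, so it is
the sole consensus biomarker. Its co-expression module recovers the
planted 12-gene latent-factor module exactly (the enrichment stage finds
the planted term with full overlap), high *CCNB2* expression roughly
doubles the event hazard (true simulated HR is 2), and the qPCR folds
recover the planted contrasts (≈2.6× healthy and ≈24.8× metastatic versus
primary-stage, up to Ct noise). The same pipeline runs from a single
config via `run_pipeline()`; `make_demo()` regenerates all inputs for any
seed.

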