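# cnvClonality

Intra-tumor clonality trees from single-cell copy-number calls.

Single-cell RNA-seq CNV inference (inferCNV-style) emits, per subcluster
of cells, genomic regions with a six-state copy-number code (1–2 loss,
3 neutral, 4–6 gain). For tumors whose biology is written in arm-level
events — uveal melanoma being the motivating case, with monosomy 3,
8q gain and 6p gain as canonical lesions — the interesting object is not
the region list but the clonal architecture behind it. `cnvClonality`
post-processes those calls into that architecture, for researchers
studying intra-tumor heterogeneity who already run CNV inference and want
reproducible clonality trees out of it.

## What it computes

1. **Arm-level events.** Each region is converted to a p/q arm-level gain
   or loss using cytoband arm boundaries (the start of the first q band);
   centromere-spanning regions hit both arms, neutral states and
   mitochondrial regions are dropped.
2. **Clone tree.** Subclones with identical event sets are collapsed,
   then attached greedily by set containment: each subclone joins the
   deepest node whose cumulative event set is a strict subset of its own.
   Every node carries an *inclusive percentage*,

   `100 × (cells at the node and its descendants) / (all tumor cells)`,

   so the root is 100% and percentages never increase down a branch.
3. **Driver mutations.** Bulk VAFs are corrected for normal contamination
   by anchoring the truncal Gα mutation (GNAQ/GNA11) to 50%
   (`v_corrected = 0.5 · v / v_anchor`), converted to expected clone
   percentages (`min(100, 200·v)`, heterozygous diploid), and attributed
   to the branch of nearest percentage within a tolerance; unresolvable
   mutations are starred at the root.
4. **SVG tree.** Deterministic rendering in which every branch length is
   `scale × percentage + circle diameter + 5` pixels.

A seeded synthetic-data generator (`simulate*` functions) produces
region/grouping files, bulk VAFs and QC-grade expression matrices with
known ground truth, and the upstream cell filters are included
(UMI > 400, 100–8000 genes, mito < 10%; CD3E > mean + 2 SD with zero
PRAME/HTR2B for normal reference cells; UMI > 3000 for tumor cells
entering CNV inference).

## Worked example

The packaged demo is a synthetic version of a sequential-LOH3 tumor:
100 cells, of which 17 carry 3q loss and 6 carry both 3q and 3p loss,
with bulk GNAQ (VAF 0.465) and SF3B1 (VAF 0.107).

```r
library(cnvClonality)
demo <- function(f) system.file("extdata", f, package = "cnvClonality")
res <- runFullPipeline(
    demo("loh3_synthetic_regions.dat"),
    demo("loh3_synthetic_groupings.tsv"),
    demo("cytoBand_synthetic.txt"),
    outDir = "demo_out",
    mutationsPath = demo("loh3_synthetic_mutations.tsv"))
res$tree
```

```
CloneTree: 3 node(s), 100 tumor cells
  root (100.0%, 77 cells)
    3q_loss (23.0%, 17 cells)
      3p_loss (6.0%, 6 cells)
  mutations: GNAQ->3q_loss, SF3B1->3q_loss
```

Loss of 3q defines a 23% subclone within which a 6% subclone has
additionally lost 3p (completing loss of heterozygosity of chromosome 3);
the truncal GNAQ anchor sits on the trunk, and SF3B1 — corrected VAF
0.115, expected clone percentage 23.0 — is attributed to the 3q-loss
clone. `demo_out/` then contains the arm-events TSV, the tree as JSON and
Newick (`((3p_loss:6)3q_loss+GNAQ+SF3B1:23)root:100;`), the SVG, a
mutation report and a run log. The same chain is produced from raw
per-cell calls by the simulator:

```r
spec <- SimulationSpec(
    tree = data.frame(node = c("c1", "c2"), parent = c(NA, "c1"),
                      events = I(list("3q_loss", "3p_loss")),
                      fraction = c(0.17, 0.06)),
    nCells = 1000)
sim <- simulateCellCNVCalls(spec, simulateCytoband(), tempdir())
```

A command-line front end with subcommands (`run`, `arms`, `tree`,
`plot`, `simulate`, `qc`, `refcells`) is installed at
`system.file("scripts", "cnv-clonality.R", package = "cnvClonality")`.

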