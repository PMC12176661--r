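# crisprSelect

Selective-essentiality analysis of two-arm pooled CRISPR knockout
screens, built for the question: *which gene knockouts kill cells only
in the presence of a drug?* The motivating setting is screens for
synthetic-lethal partners of PIKfyve kinase inhibition in pancreatic
cancer cells, but the statistics apply to any vehicle-vs-drug pooled
screen counted into an sgRNA × sample table.

## The method

From read counts $c_{is}$ the pipeline computes, per arm:

- filters: sgRNAs with < 100 reads in the initial sample are removed,
  then genes with < 6 surviving guides;
- abundances $a_{is} = (c_{is}+1) / \sum_j (c_{js}+1)$ (pseudocount of
  one, normalized to sample total);
- guide scores $\mathrm{lfc}_i = \log_2(a_{i,\text{final}} /
  a_{i,\text{initial}})$ and gene scores as the mean lfc of a gene's
  guides;
- reference scaling anchored on the guide-level medians of
  non-targeting controls and of core-essential genes, mapped to 0 and
  −1: $\tilde x = (x - m_0)/(m_0 - m_{-1})$;
- the selective-essentiality z-score, the z-scored difference of
  scaled gene scores $z_g = (d_g - \bar d)/\mathrm{sd}(d)$ with
  $d_g = \tilde x_{g,\text{drug}} - \tilde x_{g,\text{vehicle}}$.

Strongly negative $z$ nominates synthetic-lethal candidates; strongly
positive $z$ genes whose loss confers resistance. Genes essential in
both arms are categorized separately (`essential_both`) so constitutive
dependencies are not mistaken for drug-selective ones.

The package also ships a generative screen simulator with planted
per-gene, per-arm fitness effects (for validation by parameter
recovery) and four companion assay statistics: composite RNA-ISH
expression scores (0–400), autophagic-flux reporter indices (RFP/GFP
normalized to the DMSO mean), Bliss-independence synergy excess, and
phosphoinositide HPLC peak percentages.

## Worked example

```r
library(crisprSelect)

sim <- simulateScreen(simPreset("small", seed = 7))   # 24 genes x 6 guides + 30 non-targeting
gs  <- scoreScreen(screen(sim))
gs
#> GeneScores: 21 genes, 156 sgRNAs
#>   categories: essential_both=4, neutral=14, selectively_lethal=2, sensitizing_enriched=1
#>   anchors[control]: non-targeting 0.2178, core-essential -6.2274
#>   anchors[treated]: non-targeting -0.1374, core-essential -6.5229

tab <- as.data.frame(scoreTable(gs))
head(tab[order(tab$selectiveZ),
         c("gene", "nSgRNAs", "scaledControl", "scaledTreated",
           "selectiveZ", "category")], 3)
#>        gene nSgRNAs scaledControl scaledTreated selectiveZ           category
#> 13 GENE0015       6      -0.00758        -0.462  -2.127009 selectively_lethal
#> 20 GENE0023       6      -0.00443        -0.446  -2.061211 selectively_lethal
#> 3  GENE0003       6       0.00553        -0.420  -1.977498            neutral

recoveryMetrics(gs, sim)[c("auroc", "recall")]
#> $auroc
#> [1] 1
#> $recall
#> [1] 1
```

Reading the output: 21 of 24 genes survived the filters (the tallies
are in `filterTallies(gs)`). The anchors line reports, per arm, the
median guide-level log2 fold-change of the two reference classes —
here core-essential guides fell ~6.2–6.5 log2 units below neutral, a
healthy screen. The three genes with the most negative selective z are
exactly planted drug-arm-only depletions (`geneTruth(sim)` shows
GENE0003, GENE0015 and GENE0023 with fitness −0.4 under drug, 0 under
vehicle), and the planted selective/neutral separation is perfect
(AUROC 1, full recall among the top ranks).

File-based runs are driven by a YAML config
(counts + annotation + sample-role design) through `runPipeline()`,
which writes `scores.tsv`, `rank_plot.tsv`, `scatter.tsv` and
`summary.json`; `inst/scripts/crisprscreen.R` exposes
`simulate` / `score` / `benchmark` / `pheno` / `fixture` subcommands
over the same functions. See the vignette
(`vignettes/selective-essentiality.Rmd`) for the model, parameter and
simulator details.

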