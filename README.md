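# cistrodyn

Temporal cistrome dynamics and regulatory integration for nuclear-receptor
ChIP-seq.

`cistrodyn` is for genomics analysts comparing two transcription-factor
signaling programs over a drug-treatment time course — the motivating case
is a pair of nuclear receptors (an LXR-class and a PPARG-class receptor)
profiled by replicate ChIP-seq at an early (2 h) and late (48 h) timepoint
alongside RNA-seq at 24/48 h. It turns peak calls, coverage, genome
sequence, gene models and differential-expression tables into the
statistics that characterize such programs:

* **Occupancy quantification** — reads tabulated over 100-bp windows
  centered on peak summits, normalized to reads per million (RPM);
  replicate agreement as Spearman ρ; condition contrasts as
  `log2((a + c) / (b + c))` read-depth ratios with pseudocount `c = 1`.
* **Temporal binding dynamics** — per site, ordinary least squares of RPM
  on time across replicate observations; the two-sided *t* test on the
  slope (df = n − 2) classifies sites as *gained* (β > 0, p < α), *lost*
  (β < 0, p < α) or *stable*; the top 50 % of p-ranked dynamic sites feed
  cofactor motif analysis.
* **Motif fold enrichment** — PWM log-odds scanning of both strands
  (`Σ log2 p_i(b)/q(b)` ≥ 60 % of the maximum score by default); the null
  is the mean hit count over composition-preserving scrambles of every
  site sequence, and `fold = observed / max(null, 0.5)`.
* **Responsive-gene concordance** — gene sets at adjusted p < 0.01 and
  signed linear fold change ±2 (and ±1.5); high-confidence intersections
  across two agonists; overlap/concordant/discordant tallies with
  upper-tail hypergeometric overlap tests.
* **Distance-CDF enrichment** — cumulative fraction of a gene set's
  promoters within increasing distances of the nearest binding site,
  against an all-genes background; co-occupancy stratification of sites
  by a second mark.
* **RNAP2 pausing signature** — for repressed genes, promoter RNAP2 ratio
  up with gene-body H3K36me3 ratio down ⇒ *pausing-consistent*; both
  down ⇒ *reduced initiation*; near/far (<10 kb / >100 kb) binding strata
  compared by exact or tie-corrected Wilcoxon rank-sum tests.

A seeded synthetic-data module generates every input the pipeline consumes
(genome FASTA, gene models, peak sets, negative-binomial count matrices,
DE tables, pausing tables) with planted ground truth, so the whole
analysis is testable end to end with no external data.

## Worked example

```r
library(cistrodyn)

scfg <- sim_config(seed = 11, n_genes = 200, n_sites = 600, chrom_length = 2e6)
res  <- run_pipeline(scfg, analysis_config(seed = 11), "example_out")

print(res$motif)
table(res$trends$class)
res$concordance[res$concordance$fc_cut == 2, ]
```

```
motif 'NR_DR4': observed 115 hits, null mean 0.20, fold 230.00 (10 scrambles, seed 11)

gained   lost stable
    84     84    432

  fc_cut overlap overlap_percent concordant discordant percent_concordant      p_hyper universe
1      2      30              75         29          1               96.7 1.106173e-17      200
```

The motif stage finds the planted nuclear-receptor direct-repeat motif 230×
enriched over its scrambled-sequence null. The trend stage calls 84 + 84
dynamic sites (the generator planted 120 + 120 with 4-fold shifts; the
remainder fall below the α = 0.05 slope test — see the vignette on the
power of a df = 2 per-site test). The concordance row says: 30 genes
responded to both simulated agonists at p < 0.01, |fc| ≥ 2 (75 % of the
first agonist's responsive set); 29 moved in the same direction (96.7 %
concordant), and an overlap that large has hypergeometric
p ≈ 1.1 × 10⁻¹⁷ in a 200-gene universe. The run directory also receives
distance-CDF tables (here the repressed-gene curve sits up to 0.145 above
background), per-gene pausing calls (100 % of planted mechanisms
recovered at noise sd 0.2) and a manifest with seed and config hashes;
rerunning with the same seed reproduces every file byte for byte.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/cistrodyn.R simulate --seed 1 --outdir sim_out
Rscript inst/cli/cistrodyn.R run      --seed 1 --outdir run_out
Rscript inst/cli/cistrodyn.R report   --outdir run_out
```

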