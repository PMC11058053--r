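# hubnet

Functional-connectivity analysis of islet Ca²⁺ imaging — identification of
highly connected **hub** beta cells and paired comparison of hub/follower
composition between labelled beta-cell subpopulations — plus clone-level
bisulphite **CpG methylation** quantification for sorted populations.

## Who this is for

Islet biologists and analysts with per-cell fluorescence time series from
glucose-stimulation experiments (cells × frames, with per-cell subpopulation
labels such as NNAT⁺/NNAT⁻) who want a tested, reproducible version of the
standard hub-cell workflow; and anyone quantifying amplicon bisulphite
clone data (per-clone methylated/unmethylated CpG calls) across sorted
populations. Because raw imaging data for this kind of study are rarely
deposited, the package also ships a synthetic-islet generator with exported
ground truth, so every stage of the pipeline is verifiable end to end.

## The method

For each islet: traces are normalised to *F*/*F*<sub>min</sub>, smoothed
(3 s moving average), and binarised per cell at
`median(baseline) + 3 × MAD(baseline)`. Pairwise coactivity is the Pearson
correlation *r* of binary activity vectors over the post-stimulus window.
Each pair's significance is assessed against a **circular-shift permutation
null** (burst structure preserved, alignment destroyed): a connection exists
iff observed *r* exceeds the (1 − α) null quantile, α = 0.01. Per-cell
connectivity is `100 × degree / (n − 1)`; a cell is a **hub** iff it is
significantly coactive with **≥ 30%** of the remaining cells. Per islet and
label, the hub:follower ratio is formed and compared across islets with an
**exact Wilcoxon matched-pairs signed-rank test** (full 2ⁿ enumeration up to
25 effective pairs, tie-corrected normal approximation beyond). Log–log
connectivity distributions are fitted by least squares on width-normalised
logarithmic bins. Methylation: per-CpG percent = methylated/informative
calls; region percent pools calls across sites; populations are compared by
a paired *t* test over CpG sites.

See `vignettes/hubnet-methods.Rmd` for the model, parameter defaults and
design rationale.

## Worked example

```r
library(hubnet)

# a synthetic islet: 50 cells, 50 min at 1 Hz, planted hubs (10%),
# label-positive cells de-enriched for hubs (odds multiplier 0.2)
cfg <- simulation_config(label_hub_odds = 0.2, seed = 11)
sim <- simulate_islet(cfg)

res <- analyse_islet(sim$recording)   # normalise, smooth, binarise,
print(res)                            # Pearson + permutation null, hubs
#> <connectivity_result 'islet_seed11'> 50 cells; mean r 0.050; 7 hubs (>=30%)

str(summarise_islet(res))
#> List of 4
#>  $ mean_r                      : num 0.0496
#>  $ hub_fraction                : num 0.14
#>  $ mean_hub_coactivity_pct     : num 36.7
#>  $ mean_follower_coactivity_pct: num 15.9

hub_follower_by_label(res, sim$truth$labels)
#> <islet_hub_comparison 'islet_seed11'>
#>  label n_cells n_hubs n_followers hub_follower_ratio hub_pct
#>    pos      10      1           9          0.1111111      10
#>    neg      40      6          34          0.1764706      15

sim$truth$hub_ids                     # planted ground truth
#> [1] 12 16 25 34 37
```

Called hubs are significantly coactive with ~37% of the islet on average
versus ~16% for followers; 5 of the 7 calls are the planted hubs. Across a
45-islet cohort, `cohort_hub_comparison()` turns the per-islet ratios into
the paired Wilcoxon endpoint (with `label_hub_odds = 0.2` the positive
label shows the lower ratio at p ≪ 0.01). `export_graphml()` writes the
network with node categories (≥80/≥60/≥40/<40% coactivity) and coordinates
for Cartesian-map rendering.

Methylation side:

```r
pos <- simulate_clone_matrix(13, c(1010L, 1042L, 1077L, 1130L),
                             c(.05, .1, .08, .05), seed = 2,
                             sample_id = "pos")
percent_methylation(pos)
#> <methylation_summary 'region'/'pos'> 13 clones, 4 CpGs; region 7.7% methylated
```

`read_traces()`/`write_traces()` and `read_clone_calls()`/
`write_clone_calls()` define the delimited-text formats (CSV with
`cell_id,label,x,y,f0...` plus a JSON sidecar; TSV with `clone_id` and one
column per CpG position).

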