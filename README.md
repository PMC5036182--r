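# addigest

Activity-based analysis of anaerobic digester (AD) microbiomes fed by
waste activated sludge (AS).

Digesters receive a massive, continuous influx of feed microorganisms, so
16S rDNA surveys conflate two populations that could not be more
different: organisms growing in the digester and doing the degradation,
and feed organisms that are merely being washed through and digested.
Occupancy-based core-microbiome analysis cannot tell them apart, and the
rRNA/rDNA activity ratio — computed from relative abundances — actively
misleads. `addigest` is for engineers and microbial ecologists who want
an activity-aware reading of digester amplicon data: per-population
specific growth rates from a steady-state mass balance, and a digestion
efficiency that accounts for growth inside the reactor.

## The model

Treating the digester as a completely mixed chemostat and approximating
cell mass by volatile solids (share of a stream's `Q·TS·VS` flux given by
relative abundance `p`), the steady-state balance for population *x*
gives

```
mu_x = D * (1 - (Q_in · TS_AS · VS_AS · p_x,AS) /
                (Q_out · TS_AD · VS_AD · p_x,AD)),     D = 1/SRT
```

`mu < 0` means the population is being digested; a population absent from
the feed must grow at exactly the washout rate `D` to persist, which caps
`mu`. Digestion efficiency is then decomposed as: (1) the feed abundance
of populations never detected in the digester, plus (2) the digested
biomass flux of detectable negative-`mu` populations — alongside the
conventional Van Kleeck and approximate mass-balance volatile-solids
reduction for comparison. A synthetic community generator inverts the
same model with known growth rates and rRNA activity factors, so every
stage of the pipeline is testable against ground truth.

## Worked example

Simulate three mesophilic digesters at steady state (study-design
defaults: 600 OTUs, 6 feed + 12 digester samples, depths 30,000/10,000),
fit the growth model, and score digestion efficiency:

```r
library(addigest)

sim <- simulate_community(sim_config(seed = 42))
fit <- fit_growth(sim$rdna, sim$meta, sim$reactors)
summary(fit)
#> Steady-state growth model fit (600 OTUs, mode 'srt')
#>   dilution rates: 0.0413, 0.0413, 0.0397 1/day (mean 0.0408)
#>   status: ad_only 102, estimated 464, feed_only 34
#>   mu in [-1.023, 0.041] 1/day (washout bound 0.0408)
#>   positive mu: 423 OTUs, 98.3% of AD sequences
#>   negative mu: 143 OTUs, 1.7% of AD sequences
```

The maximum `mu` equals the washout bound: populations native to the
digester (absent from the feed) grow at `1/SRT`, here 0.041/day on
average. The efficiency report:

```r
suppressWarnings(efficiency_report(fit))
#> <efficiency_report>
#>   part 1 (feed OTUs undetected in AD, 34 OTUs): 0.22%
#>   part 2 (digested negative-mu biomass, 143 OTUs): 22.66%
#>   total activity-based efficiency: 22.88%
#>   Van Kleeck VSR: 62.92%
#>   approximate mass-balance VSR: -438.55%
#>   new-growth fraction of digested sludge (423 OTUs): 98.31%
#>   (10 OTUs with inconsistent flux terms excluded)

truth_digested_fraction(sim$truth)
#> [1] 0.2265244
```

The activity-based total (22.88%) recovers the generator's true digested
fraction (22.65%) to within a quarter of a percentage point. The
mass-balance VSR is negative on this simulation because the generator
models microbial biomass only — growth adds effluent volatile solids — a
warning, not an error. Core populations come from occupancy plus
per-sample abundance:

```r
ad <- subset_table(sim$rdna, samples = samples_where(sim$meta, "AD", "rDNA"))
select_core(ad)
#> <core_set> 33 core OTUs (occupancy 12/12, top-80% rule 'every_sample')
#>   summed mean relative abundance: 72.4%
```

`run_pipeline()` chains the whole analysis (simulate/ingest → rarefy →
core → activity ratios → growth → efficiency) from one configuration list
or YAML file, writing TSV tables and a JSON manifest. Real data enter as
classic QIIME-style TSV (or BIOM) count tables, a sample metadata TSV and
a reactor-specification TSV; `stickney_digesters()` ships the packaged
three-digester parameter set.

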