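# medipchip

Differential DNA-methylation analysis for two-channel MeDIP tiling arrays
(CpG-island + promoter designs), with expression integration and qPCR
validation arithmetic — the full chain from probe intensities to
methylation–expression quadrant tables, plus a deterministic synthetic-data
generator so every stage can be tested against planted ground truth.

**Who it is for.** Analysts working with MeDIP-chip–style promoter tiling
data (or evaluating threshold-based DMR-calling rules on simulated data)
who need a transparent, scriptable re-implementation of the classic
NimbleGen-era analysis: per-channel background correction and quantile
normalization, Tukey-biweight-centred log2 IP/input ratios, sliding-window
Kolmogorov–Smirnov probe scores, and consecutive-probe DMR calling.

## The method in brief

For probe *i* in sample *s* the methylation signal is the centred
log-enrichment `r_is = log2(IP_is / Input_is)` (channels
background-corrected at the per-sample 5th percentile and
quantile-normalized; per-sample one-step Tukey biweight location removed).
Each probe also gets a signed local significance score from a 750 bp
sliding window *w* against the whole-sample background *b*:

```
KS_i = sign(median(w) - median(b)) * -log10( p_KS( sup_t |F_w(t) - F_b(t)| ) )
```

A **DMR** between samples A and B is a maximal run of ≥ 3 consecutive
probes (gaps ≤ 500 bp) with per-probe `Δlog2 = r_B - r_A ≥ 1` (two-fold)
and `ΔKS = KS_B - KS_A ≥ 1.0` for gains, both thresholds negated for
losses. DMRs are classified against TSSs (proximal `-100 ≤ d ≤ +500`,
distal `+500 < d ≤ +5000`, intragenic / intergenic via CpG islands),
paired with transcripts changing expression ≥ 1.5-fold (RMA-style median
polish summaries), and sorted into the four methylation × expression
quadrants. McrBC qPCR methylation is `1 - E^-(Cq_McrBC - Cq_Input)`,
relative expression `E^-(Cq_target - Cq_ref)`, compared across individuals
with Welch's t-test.

## Worked example

```r
library(medipchip)

cfg <- pipeline_config(n_genes = 60L, n_dmrs = 10L, seed = 42L)  # desk-scale
rep <- run_pipeline(cfg)                      # simulate -> ... -> integrate

r <- rep$contrasts[["d1:d7"]]
r$n_dmrs; r$gains; r$losses
#> [1] 9
#> [1] 4
#> [1] 5
unlist(r$location_distribution)
#>   proximal     distal intragenic intergenic
#>          1          8          0          0
r$quadrants
#>              quadrant distal proximal intragenic total
#> 1     meth_up_expr_up      1        1          0     2
#> 2   meth_up_expr_down      2        0          0     2
#> 3   meth_down_expr_up      3        0          0     3
#> 4 meth_down_expr_down      2        0          0     2
r$recovery$sensitivity; r$recovery$precision
#> [1] 0.9
#> [1] 1
rep$retained$n        # d1:d7 DMRs persisting (same direction) in w2 and w8
#> [1] 7

head(rep$details[["d1:d7"]]$dmrs[, c("dmr_id", "chrom", "start", "end",
                                     "n_probes", "direction")], 3)
#>    dmr_id chrom  start    end n_probes direction
#> 1 DMR0001  chr1 224012 224361        4      loss
#> 2 DMR0002  chr2  56408  56757        4      gain
#> 3 DMR0003  chr2 790496 790845        4      gain
```

Reading the output: 9 of the 10 planted DMRs were recovered (the tenth
lost a probe to noise — see the vignette for why sensitivity is bounded
well below 1 at these settings), every call overlaps a planted region
(precision 1), most DMRs sit distal to their TSS because the tiling is
promoter-upstream-heavy, and each recovered DMR pairs with its gene's
planted ±2-fold expression change to populate the four quadrants.

A command-line entry point wraps the same stages
(`system.file("cli", "medipchip", package = "medipchip")`):

```sh
medipchip simulate  --config run.cfg --outdir out/
medipchip normalize --in out/probes.tsv --out out/norm.tsv
medipchip call-dmrs --in out/norm.tsv --contrast d1:d7 --out out/dmrs.bed
medipchip pipeline run --config run.cfg --outdir out/
```

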