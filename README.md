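# cshpet

Mid-treatment FDG-PET response analysis for head-and-neck radiotherapy
cohorts, built around intra-tumoural metabolic heterogeneity scored as the
**area under the cumulative SUV-volume histogram (AUC-CSH)**.

## The problem

A subset of oropharyngeal squamous cell carcinoma (OPSCC) patients treated
with definitive (chemo)radiotherapy recur locoregionally, while others are
over-treated. Clinical markers (p16/HPV status, TNM stage, smoking) have
not proven *predictive* enough to drive risk-adapted therapy. A repeat
FDG-PET acquired early during radiotherapy (week 3) offers a window on the
individual tumour's response; this package quantifies that response and
turns it into pre-specified risk groups with a survival read-out.

For each scan, with a binary primary-tumour ROI, the package extracts:

- **SUVmax**, **SUVmean** — maximum / mean standardized uptake value over
  the ROI (raw voxel values);
- **MTV** — metabolic tumour volume (mL);
- **TLG** = SUVmean × MTV — total lesion glycolysis;
- **AUC-CSH** — SUVs are discretised with a fixed bin width of SUV 0.3
  (no other normalisation), and the cumulative SUV-volume histogram
  y(x) = fraction of tumour volume with uptake ≥ x · SUVmax is integrated
  over x ∈ [0, 1]. AUC-CSH = 1 means perfectly homogeneous uptake; lower
  values mean greater intra-tumoural heterogeneity.

Longitudinal change is the percentage delta ∆ = (week3 − week0)/week0 ×
100%. Two pre-specified binary rules — favourable volume response
∆MTV ≤ −50% and favourable heterogeneity response ∆AUC-CSH > 0% — feed two
three-group stratification schemes (p16 × ∆AUC-CSH, and ∆MTV × ∆AUC-CSH),
compared by Kaplan-Meier estimation, the Mantel-Cox log-rank test, 2-year
locoregional recurrence-free survival (LRRFS), and Cox regression adjusted
for the a-priori trio (p16, TNM stage, chemotherapy).

Patient imaging is never distributed with packages like this one, so
`cshpet` ships first-class synthetic generators: tumour phantoms with hot
"radioresistant subclone" subregions, a mid-treatment response simulator,
and a cohort simulator that ties imaging response groups to time-to-event
outcomes. Every published property of the method is validated against
brute-force oracles on these phantoms.

## Worked example

```r
library(cshpet)

# a heterogeneous baseline phantom: 11 mm lesion at SUV 5 with a hot
# 4.5 mm subclone at SUV 13, plus acquisition noise
ph <- make_phantom(phantom_spec(
  lesion_radius_mm = 11, base_suv = 5,
  subclones = list(list(offset_mm = c(3, -2, 1), radius_mm = 4.5, suv = 13)),
  noise_sd = 0.25, seed = 2024))
extract_features(ph$volume, ph$mask)
#> <feature_set> phantom-2024 [week0]
#>   SUVmax 13.528  SUVmean 5.523  MTV 5.376 mL  TLG 29.693  AUC-CSH 0.4044

# a partial responder: volume down 30%, uptake down 35%, and the hot
# subclone largely resolving (persistence 0.3)
wk3 <- apply_response(ph, response_spec(volume_shrink_frac = 0.3,
  suv_decline_frac = 0.35, subclone_persistence = 0.3))
f3 <- extract_features(wk3$volume, wk3$mask)
d  <- delta_features(extract_features(ph$volume, ph$mask), f3, "P001")
d
#> <delta_feature_set> P001
#>   d_suv_max  -54.33%
#>   d_suv_mean -37.22%
#>   d_mtv      -30.06%
#>   d_tlg      -56.09%
#>   d_auc_csh  +39.36%

stratify_mtv_csh(d$d_mtv, d$d_auc_csh)
#> group 2: the volume reduction misses the 50% cut-off (unfavourable
#> dMTV) but heterogeneity fell (dAUC-CSH +39% > 0, favourable)
```

The AUC-CSH rose from 0.40 to 0.56 because the hot subclone homogenised —
exactly the signal the ∆AUC-CSH > 0% rule rewards.

A full simulated cohort, end to end:

```r
res <- run_pipeline(run_config(cohort_spec(seed = 5)))
res
#> <pipeline_result> 114 patient(s), schemes: mtv_csh, p16_csh
#>   mtv_csh: 2-yr LRRFS 97.6% / 85.4% / 0.0%, log-rank p = 1.55e-19
#>   p16_csh: 2-yr LRRFS 98.0% / 93.8% / 0.0%, log-rank p = 1.01e-24
```

The three groups separate steeply: group 1 (favourable volume response)
has near-complete 2-year control, group 3 (persistent heterogeneity and
poor volume response) recurs early — the structure the stratification is
designed to surface. With `out_dir` set, every stage writes a CSV plus a
`manifest.json` recording bin width, anchor, cut-offs, time origin and
seed, and a rerun reproduces the outputs bit-identically.

A thin command-line wrapper over the same functions is included at
`inst/cli/cshpet.R` (subcommands `segment`, `features`, `deltas`,
`stratify`, `simulate`, `run`).

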