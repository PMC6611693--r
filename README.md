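# patentscape

Disease-landscape analysis of biomedical patent corpora: corpus filtering,
disease concept normalization to root PheCodes, per-year disease coverage,
research-resource misalignment indices (ROI/PHI), and dynamic topic
modeling of disease-specific subcorpora.

## What problem this addresses

Granted patents are a readable trace of where biomedical research and
development actually invests. For portfolio questions - *which diseases do
patented inventions reach? is that attention proportionate to the burden
each disease imposes? what technologies cluster inside a disease's
patents, and how do they evolve?* - one needs a pipeline that turns raw
patent documents plus disease-level statistics into comparable,
disease-indexed quantities. patentscape provides that pipeline for
analysts of research policy and biomedical innovation, built so that every
stage is testable against synthetic data with planted ground truth.

## The quantities at its core

With $Y_{nd}(t)$ the raw yearly measure $n$ for disease $d$ (burden $b$ as
treatment cost per million people; publications $r$, clinical trials $c$,
patent documents $p$ as resources), each measure-year is normalized to
shares $X_{nd}(t) = Y_{nd}(t) / \sum_{d'} Y_{nd'}(t)$, and the resource
shares combine into $R_d(t) = \sum_{n\in\{r,c,p\}} w_n X_{nd}(t)$
(default equal weights). Then, with $\rho_d(t) = X_{bd}(t)/R_d(t)$:

- **ROI** (Research Opportunity Index), per disease-year: $\rho$ if
  $\rho \ge 1$ (understudied, positive), $-1/\rho$ otherwise (overstudied,
  negative). $+1$ is exact alignment; magnitudes read as folds.
- **PHI** (Public Health Index), per year:
  $\tfrac12\sum_d |X_{bd}(t) - R_d(t)|$, the total-variation misalignment
  across the whole disease landscape; smaller is better aligned.
- **Coverage**, per disease-year: documents mentioning the disease over
  documents mentioning any disease.
- **VIF** audit: $1/(1-R^2)$ from regressing each measure's cross-disease
  share vector on the other three.

Disease mentions are recognized by a deterministic longest-match lexicon
recognizer and rolled up CUI → ICD-9-CM → PheCode → root PheCode, with an
audit of how many mappings are definitive. Topic structure is fitted with
a dynamic topic model: per-year topic-word distributions whose natural
parameters follow a Gaussian random walk (drift variance σ, default
0.005; document-topic concentration α, default 0.01), with UMass-coherence
selection of the topic number over a grid.

## Worked example

The `analysis/` directory holds the five numbered stage drivers
(`01_simulate.R` ... `05_topics.R`); running them in order reproduces a
complete study on a synthetic corpus under `results/`. Condensed, the same
flow in code:

```r
library(patentscape)

cfg <- synth_preset_demo(seed = 42)          # 3 years x 200 docs x 8 diseases
sim <- simulate_study(cfg, "results/synthetic_study")

res <- filter_corpus(sim$corpus, sim$criteria)
res$report
#> Patent filter report
#>   documents read:        600
#>   pass date window:      468
#>   pass classification:   488
#>   biomedical (both):     356 (59.3%)

X <- normalize_measures(sim$measures)
as.data.frame(subset(roi(X), year == 2002))[1:4, c("phecode", "roi")]
#>   phecode       roi
#> 1     001  2.844581
#> 2     002  1.964546
#> 3     003 -1.001974
#> 4     004 -1.867530
as.data.frame(phi(X))
#>   year       phi
#> 1 2000 0.2474234
#> 2 2001 0.2550595
#> 3 2002 0.2377556
```

The generator planted folds (3, 2, 1, 0.5, ...) between burden share and
resource share: disease 001 was built three-fold understudied and its ROI
comes back at 2.84 under Poisson count noise (the noiseless tables recover
3.0 exactly); disease 004 was built at fold 0.5 and returns −1.87,
i.e. resources about double its burden share. PHI near 0.25 says a
quarter of the resource mass would have to move to match the burden
distribution. The topic stage then selects the planted topic number by
coherence and prints each topic's top keywords per year slice
(`analysis/05_topics.R`).

## Layout

- `R/` - the package: corpus I/O and filtering, concept normalization,
  coverage, indices, topic modeling, synthetic generator, pipeline
  orchestration (`run_pipeline` from a YAML config).
- `analysis/` - numbered narrative drivers for the study stages.
- `tests/testthat/` - unit, property and recovery tests.
- `vignettes/patent-disease-landscape.Rmd` - methods and design notes.
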