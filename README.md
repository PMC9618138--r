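# ecotraitmap

Functional trait axes and functional diversity, inferred directly from
ecological monitoring data.

Monitoring programs record which species occur in which samples and at
what biomass, but not the physiological traits needed to compute
functional diversity. `ecotraitmap` closes that gap for community
ecologists and microbiome researchers working with species × sample
abundance tables: it learns a trait space ("i-traits") from co-occurrence
alone and quantifies functional diversity in it, with no trait catalogue
required.

## Method at a glance

Given a nonnegative biomass matrix **B** (species × samples):

1. **Similarity** `S_ij` = Spearman correlation between the biomass
   vectors of species *i* and *j* across samples (zeros = tied ranks).
2. **Trusted links**: keep `S_ij` iff *j* is among the top *k* (= 10)
   most similar species of *i*, or vice versa (union kNN); negative
   retained weights are clipped to 0. *k* is the only tunable parameter.
3. **Diffusion map**: on the giant component, eigendecompose the graph
   Laplacian `L = D − S`. The *n*-th i-trait of the species is
   `v_n / λ_n` (unit eigenvector over eigenvalue, zero mode dropped);
   `λ_n` is inversely proportional to axis importance. The functional
   dissimilarity is the diffusion distance
   `d_ij² = Σ_n (v_{n,i} − v_{n,j})² / λ_n²`.
4. **Diversity**: for a sample with biomass shares `p`, Rao's quadratic
   entropy `Q = Σ_i Σ_j p_i p_j d_ij`.

A built-in metacommunity simulator (200 species competing for three
essential resources on a 10 × 12 patch lattice, R\* trade-off triangle,
Monod–Liebig growth, diffusive dispersal; compiled adaptive RK
integrator) provides tables whose true functional geometry is known, and
a validation pipeline scores how well diversity computed from the
inferred distances reconstructs diversity computed from the true R\*
distances.

## Worked example

Simulate a small known-truth dataset, infer the trait space, and check
the reconstruction:

```r
library(ecotraitmap)
set.seed(7)
traits <- sampleTraits(60)                      # R* triplets, known truth
runs <- lapply(1:40, function(i)
    simulateMetacommunity(traits, buildMetacommunity(c(6, 8))))
tab <- collectSamples(runs)
tab
#> AbundanceTable: 60 species x 1920 samples
#>   occupancy: 68.4% of cells > 0
#>   sample metadata: run, S1, S2, S3

ts <- inferTraits(tab, k = 10, nAxes = 10)
ts
#> TraitSpace: 60 species, 10 i-trait axes
#>   eigenvalues: 0.755, 0.87, 1.09, 1.22 ...

head(sampleDiversity(tab, ts), 3)
#>     sample_id         Q coverage n_effective_species flagged
#> 1 run001_p001 0.4374613        1                  45   FALSE
#> 2 run001_p002 0.3509401        1                  51   FALSE
#> 3 run001_p003 0.2780708        1                  55   FALSE

distanceConcordance(groundTruthDistance(traits), diffusionDistance(ts))
#> [1] 0.6453427
```

`Q` is each sample's Rao entropy in diffusion-distance units (here
higher in patches whose biomass is spread over distant species);
`coverage` is the biomass fraction belonging to embedded species; the
concordance is the Spearman correlation between all inferred and true
pairwise distances (0.65 at this deliberately small data volume — it
rises towards ~0.96 at the full validation scale).

Trait axes can be interpreted post hoc by correlating them with
biomass-weighted environmental preferences:

```r
tec <- traitEnvCorrelation(ts, tab, covariates = c("S1", "S2", "S3"),
                           nAxes = 2)
tec[order(-tec$abs_rS), ][1:2, ]
#>   axis covariate         rS    abs_rS      p_value n_species
#> 5    1        S3  0.6974159 0.6974159 0.000000e+00        60
#> 4    2        S2 -0.6831342 0.6831342 2.637546e-09        60
```

Here the leading axes align with resource-supply preferences — the
simulated analogue of finding that the first i-trait of a phytoplankton
community tracks nutrient concentration. Axis signs are arbitrary, so
`abs_rS` is the headline statistic, and such alignments are
hypothesis-generating, not causal.

A thin command-line wrapper over these functions is provided in
`inst/scripts/ecotraitmap.R` (`embed`, `diversity`, `simulate`,
`interpret` subcommands). The methods vignette
(`vignettes/inferring-trait-spaces.Rmd`) documents the model,
parameters, numerical choices and limitations.

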