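# spatsfs

Site frequency spectra of rare deleterious variants under geographically
concentrated sampling.

## The problem

How broadly a genetic study samples in space changes what it sees of rare,
deleterious variation. Alleles under negative selection are young and
their carriers are spatially clustered around the mutation's origin, so a
narrow sample (say, recruitment around one city) finds fewer distinct
variants but sees each at inflated frequency, while a broad sample finds
many more variants, mostly as singletons, each diluted by the non-carriers
it inadvertently includes. `spatsfs` is for population and statistical
geneticists who want to quantify these *discovery* and *dilution* effects
— when designing a sampling scheme, interpreting rare-variant burdens, or
assessing bias in selection-coefficient inference from spatially
concentrated samples.

## The model

Carriers of a deleterious allele live on an `L × L` torus with population
density `ρ` (total `N = ρL²`). Mutations arise at rate `μ` per site per
generation at uniform random positions (infinite sites); carriers
reproduce at rate `1 − s`, die at rate 1, and disperse by Brownian motion
with RMS displacement `σ` per generation. Sampling weights individuals by
a Gaussian kernel of width `w` (or uniformly). With the characteristic
length `ℓc = σ/√(2s)` — the spatial spread of a carrier cloud over the
allele's ~1/s-generation lifetime — the count `K` of an allele in a sample
of size `n` follows

    K ~ NegBin(θ_E, γ_E / (γ_E + n)),

where, for concentrated sampling (`w ≪ L`),

    θ_E = μ ρ ℓc² λ,   γ_E = s ρ ℓc² λ,   λ = 4π / (e^x E₁(x)),   x = (w/ℓc)²,

and `θ_E = Nμ`, `γ_E = Ns` for uniform sampling. `ρℓc²λ` is the effective
population sampled; both parameters grow with `w` (discovery and dilution)
while their ratio — the mean allele frequency `μ/s` — is exactly invariant
to the sampling design. The package provides the closed forms, a Gillespie
simulator of the underlying spatial branching process that validates them,
and an SIR (sampling importance resampling) pipeline that builds
Gaussian-breadth subsamples from a cohort of located individuals,
including a synthetic-cohort generator.

## Worked example

A human-scale reference habitat: `σ = 10`, `ρ = 20`, `μ = 1e-9`, `s = 0.01`,
`L = 1000`, a sample of `n` = 10,000, and 50,000 surveyed sites:

```r
library(spatsfs)
pop <- pop_params(sigma = 10, rho = 20, mu = 1e-9, s = 0.01, L = 1000)
pop
#> Population parameters (2-D torus habitat)
#>   sigma = 10  rho = 20  mu = 1e-09  s = 0.01  L = 1000
#>   N = rho * L^2 = 2e+07   ell_c = sigma/sqrt(2s) = 70.7107

narrow <- effective_params(pop, sampling_kernel("gaussian", c(500, 500), width = 50))
narrow
#> Effective SFS parameters (gaussian kernel)
#>   theta_E = 0.0013616   gamma_E = 13616   theta_E/gamma_E = 1e-07
#>   ell_c = 70.7107   lambda = 13.616

unif <- effective_params(pop, sampling_kernel("uniform"))
st <- lapply(list(narrow, unif), expected_summary_stats, pop = pop,
             n = 1e4, M = 5e4)
out <- data.frame(design = c("gaussian w=50", "uniform"),
                  p_variant = sapply(st, `[[`, "p_variant"),
                  p_singleton = sapply(st, `[[`, "p_singleton"),
                  mean_freq_variant = sapply(st, `[[`, "mean_freq_variant"),
                  mean_freq_all = sapply(st, `[[`, "mean_freq_all"),
                  cmaf = sapply(st, `[[`, "cmaf"))
print(out, digits = 3)
#>          design p_variant p_singleton mean_freq_variant mean_freq_all  cmaf
#> 1 gaussian w=50  0.000750    0.000576          0.000133         1e-07 0.005
#> 2       uniform  0.000975    0.000951          0.000103         1e-07 0.005
```

Reading the numbers: the uniform design is expected to discover 30.1% more
variant sites than the 50-unit Gaussian design (`p_variant`, discovery),
but each variant site segregates at a 23.2% lower mean sample frequency
(`mean_freq_variant`, dilution). The mean frequency over *all* sites is
`μ/s = 1e-7` in both designs — the two effects cancel exactly — and with
it the expected cumulative minor-allele frequency (`cmaf`), the
burden-test dosage scale, is design-invariant. The per-entry spectrum
ratio locates where the regimes flip:

```r
r <- sfs_ratio(theory_sfs(narrow, 1e4, 200), theory_sfs(unif, 1e4, 200))
attr(r, "crossover")
#> [1] 2
```

— the narrow sample has relatively fewer singletons but relatively more
sites at every allele count from 2 up.

The simulator and cohort pipeline follow the same grammar
(`sim_config()` → `run_branching()` → `estimate_effective_params()`;
`generate_synthetic_cohort()` → `resample_spec()` → `resampling_report()`);
the methods vignette (`vignettes/spatial-sampling-sfs.Rmd`) walks through
both, including why the generator's default habitat and selection classes
look the way they do. A command-line interface wrapping the same functions
is installed at `inst/cli/spatsfs.R`
(`Rscript <path>/spatsfs.R theory sfs --sigma 10 ... --out sfs.tsv`).

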