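# countem

Unbiased population size estimation for planar point patterns by systematic
quadrat counting.

## The problem and the method

Counting every particle in a large image — spectators in a stadium, birds in
a colony photograph, labelled cells in a micrograph — is slow and
error-prone, while eyeballing a density is biased. `countem` implements the
stereological alternative: superimpose a periodic grid of square quadrats
(side *t*, period *T*, tilted by a fixed angle θ) **uniformly at random** on
the image, count only the *Q* particles captured by the quadrats under the
forbidden-line rule, and estimate the population size as

    N̂ = (T/t)² · Q = Q / f,      f = t²/T²

Because the random grid offset gives every particle inclusion probability
exactly *f*, the estimator is design-unbiased for **any** population size
and spatial arrangement: the only error is sampling variance.

Choosing *t* and *T* in pixels is awkward, so the grid is parametrized by
two intuitive numbers instead:

* **f** — the sampling fraction (fraction of the plane covered by quadrats);
* **n₀ = BxBy/T²** — the initial number of quadrats over the bounding box;

with `T = sqrt(BxBy/n0)` and `t = T·sqrt(f)`. The protocol: start from
`n0 = 100, f = 0.04` (or pick *f* from the suspected order of magnitude of
N), place the grid, and inspect *Q* and the number of nonempty quadrats *n*:

| sample                | expected error  |
|-----------------------|-----------------|
| Q ≳ 50 and n ≳ 20     | CE ≲ 15%        |
| Q ≳ 100 and n ≳ 30    | CE ≲ 10%        |
| Q ≈ 200 and n ≈ 50    | CE ≈ 5%         |

If *Q* is too low, increase *f*; if *n* is too low, increase *n₀*. The
empirical coefficient of error CE(N̂) = sd(N̂)/N of any configuration can be
measured by Monte Carlo replication of the grid placement over a systematic
K×K subgrid of offsets in the fundamental T×T tile (default K = 32, i.e.
1024 replicates).

## Worked example

```r
library(countem)

bb  <- bounding_box(640, 480)                     # image size in pixels
pat <- rpattern_uniform(1120, bb, seed = 1)       # synthetic ground truth

# one protocol pass: f chosen aiming at Q ~ 100
est <- estimate_population(pat, f = 0.0893, n0 = 100, seed = 2)
est
#> population size estimate: N-hat = 1052.63
#>   sampled Q = 94 in n = 61 nonempty quadrats (f = 0.0893, n0 = 100)
#>   expected CE band: about 15% or better
#>   advice: increase-f

# how precise is this configuration really? replicate the placement
g <- quadrat_grid(f = 0.0893, n0 = 100, bbox = bb)
resample_ce(pat, g, K = 32, seed = 3)
#> grid-offset resampling: K^2 = 1024 replicates (subgrid design)
#>   E_e(N-hat) = 1119.10 (true N = 1120), mean Q = 99.9, mean n = 63.8
#>   Var_e = 8734.12, CE_e = 8.34%
```

Reading the output: one random placement captured `Q = 94` particles in
`n = 61` nonempty quadrats, giving the single-pass estimate
`N̂ = 94/0.0893 ≈ 1053` (true N = 1120, a 6% error). The sample just misses
the Q ≥ 100 threshold, so the advisor suggests a slightly larger `f`. The
1024-fold replication confirms the estimator is unbiased (mean 1119.1 vs
1120) with an empirical CE of 8.3% — inside the ≲10% band the Q/n table
promises.

Patterns are plain CSV files with an `x,y` header (see `read_pattern()` /
`write_pattern()`), and `inst/cli/countem.R` exposes `simulate`, `estimate`,
`resample` and `sweep` subcommands for shell use:

```sh
Rscript inst/cli/countem.R estimate --pattern pat.csv --f 0.09 --n0 100 --seed 2
```

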