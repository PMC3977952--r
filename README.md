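# countseg

Exact multiple change-point detection for one-dimensional count series —
per-base RNA-seq or DNA-seq coverage — by pruned dynamic programming under
a negative binomial model. For analysts who need transcript boundaries,
copy-number breakpoints or other abrupt coverage shifts located at
nucleotide resolution from the *raw* counts: no comparison profile, no
Gaussian normalization.

## The method in brief

Counts $y_1,\dots,y_n$ in segment $r$ are modelled as i.i.d.
NB$(\phi, \theta_r)$ in the exponential-family parametrization, with mean
$\phi(1-\theta)/\theta$: the success probability $\theta_r$ shifts at
unknown change-points while the dispersion $\phi$ is global (Poisson and
Gaussian losses are also available). The optimal partition into $k$
segments minimizes $\sum_r \min_\theta \sum_{t\in r} \gamma(y_t,\theta)$
with convex point loss
$\gamma(y,\theta) = -\phi\log\theta - y\log(1-\theta)$.

- **`pdp_segment()`** — a functional-pruning dynamic programming sweep
  (C++ core) returns the *exact* optimal costs $C_{k,n}$ and breakpoints
  for every $k \le K_{\max}$. Each candidate last change-point carries its
  segment cost as two running coefficients plus the interval of $\theta$
  values where it is currently optimal; candidates whose interval empties
  are pruned forever, giving near-linear practical complexity.
- **Plateau compression** — maximal runs of identical counts (long zero
  stretches, in particular) collapse into single weighted points without
  changing any optimal cost.
- **`estimate_phi()`** — sliding-window median of the moment estimator
  $\bar y^2/(s^2 - \bar y)$, with adaptive window doubling.
- **`select_K()`** — picks $\hat K$ by the oracle penalty
  $\beta K (1 + 4\sqrt{1.1 + \log(n/K)})^2$, with $\beta$ calibrated from
  the data by the slope heuristic (AIC/BIC also available).
- **`rand_index()` / `hellinger_profile()`** — segmentation quality
  against a truth labeling, and Hellinger-distance comparison of two
  segmentations under fitted per-segment NB distributions.
- **`simulate_profile()`** — seeded piecewise-constant NB profiles with
  alternating high/low signal and known truth.
- **`best_segmentation_with_breakpoint()`** — cost of the best
  segmentation constrained to a fixed change-point location, for
  sharpness diagnostics.

See `vignettes/count-segmentation.Rmd` for the full model, numerical
policies and design rationale.

## Worked example

```r
library(countseg)

sim <- simulate_profile(n = 2000, K = 8, phi = 2.3, seed = 42)
fit <- pdp_segment(sim$y, model = "nbinom", Kmax = 44)
fit
#> <pdp_fit> nbinom loss, n = 2000 (compressed to 1384, factor 1.45), Kmax = 44
#>   phi = 1.327 (estimated)
#>   optimal costs C[1..44]: 5342.03, 4798.15, 4600.96, 4284.13, 4162.47 ...

ktab <- select_K(fit, criterion = "oracle")
ktab
#> <criterion_table> oracle criterion, K_hat = 8 (beta = 0.05564)
#>   K     cost     shape criterion
#>   1 5342.027  163.8123  5351.141
#>   2 4798.154  303.5249  4815.041
#>   ...

segment_table(fit, attr(ktab, "K_hat"))
#>   segment start  end n_r   mean theta_hat
#> 1       1     1  325 325  9.012     0.128
#> 2       2   326  569 244  0.697     0.656
#> 3       3   570  646  77  8.364     0.137
#> 4       4   647 1114 468  0.626     0.680
#> 5       5  1115 1191  77 10.948     0.108
#> 6       6  1192 1201  10  0.300     0.816
#> 7       7  1202 1280  79  9.177     0.126
#> 8       8  1281 2000 720  0.571     0.699

sim$true_breaks
#> [1]  325  569  646 1114 1190 1201 1280
rand_index(labels_from_breakpoints(sim$true_breaks, sim$n),
           labels_from_breakpoints(get_breakpoints(fit, 8), sim$n))
#> [1] 0.9999579
```

The run compressed 2000 positions to 1384 weighted points, estimated the
dispersion from the data, recovered the true number of segments
($\hat K = 8$), and placed every breakpoint within one position of the
truth (Rand index ≈ 1). The `mean` column is the fitted coverage level
$\phi(1-\hat\theta_r)/\hat\theta_r$ per segment; high-mean segments are
the "transcribed" regions of the simulated profile.

A shell interface wrapping the same functions ships in
`inst/cli/countseg.R`:

```sh
Rscript inst/cli/countseg.R simulate --n 2000 --k 8 --phi 2.3 --seed 42 --out sim
Rscript inst/cli/countseg.R segment --input sim_counts.txt --model nbinom --out run
Rscript inst/cli/countseg.R evaluate --seg-a run_segments.tsv --truth sim_truth.json
```

writing BED + TSV segment tables and a JSON report with the full per-K
criterion table.

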