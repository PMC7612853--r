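# rftec

Expected Euler characteristics of Gaussian random field excursion sets:
closed-form Random Field Theory (RFT) predictions, a lattice field
simulator, exact cluster/topology counting, and the Monte Carlo experiments
that compare them.

## Who this is for

RFT underpins cluster-level false-positive control in neuroimaging: a
statistic map is thresholded at a cluster-defining threshold (CDT) `u`, and
the expected number of suprathreshold clusters under the null is
approximated by the expected Euler characteristic (EC) of the excursion set
of a smooth stationary Gaussian field. `rftec` is for anyone who wants to
verify that machinery end to end — methodologists checking an RFT
implementation, or readers of simulation studies who want to see, with
reproducible code, whether theory and simulation agree (and exactly how a
wrap-around simulation artifact can make them *dis*agree).

## The quantities it computes

For a unit-variance stationary isotropic Gaussian field obtained by
smoothing white noise with a Gaussian kernel of FWHM `f` voxels, the
roughness is `λ = 4·log(2)/f²`, and on a box `S` with sides `c₁,…,c_D`:

* **Lipschitz–Killing expansion** (the form in modern software):
  `E[χ(A_u)] = Σ_{d=0}^{D} 𝓛_d·ρ_d(u)`, with `𝓛_d = λ^{d/2}·μ_d(S)`
  (`μ_d` the intrinsic volumes of the box) and the Gaussian EC densities
  `ρ₀(u) = 1−Φ(u)`, `ρ₁(u) = (2π)⁻¹e^{−u²/2}`,
  `ρ₂(u) = (2π)^{−3/2}u·e^{−u²/2}`, `ρ₃(u) = (2π)⁻²(u²−1)e^{−u²/2}`.
* **Volume-only (original) formula** for a field with standard deviation σ:
  `E[χ(A_u)] = μ(S)(2π)^{−(D+1)/2}|Λ|^{1/2}σ^{−(2D−1)}e^{−u²/2σ²}
  Σ_j (−1)^j a_j σ^{2j} C(D−1,2j) u^{D−1−2j}`, `a_j = (2j)!/(j!2^j)`.
  At σ = 1 this is exactly the top-order term `𝓛_D·ρ_D(u)` of the
  expansion; the lower-order terms it omits are the boundary corrections.
* **Torus expectation** `𝓛_D·ρ_D(u)` for periodic boundary conditions,
  where no boundary terms exist.

The simulator (`generate_field()`) draws i.i.d. standard normal noise on a
buffered grid (buffer `⌈1.7f⌉`), convolves with the separable discrete
Gaussian kernel, crops the central block and normalises by the kernel's
root-sum-of-squares, making every voxel exactly standard normal.
`count_clusters()` / `count_clusters_periodic()` label components by
union-find under 8/26- or 4/6-connectivity, with or without wrap-around,
and `discrete_euler_characteristic()` computes χ from the matched cubical
complex.

## Worked example

Theory for a 250×250 lattice smoothed at FWHM 5, thresholded at u = 3:

```r
library(rftec)
expected_ec_lkc(box_domain(c(250, 250)), 5, u = 3)
#> expected Euler characteristic at u = 3
#>   volume-only (original) : 14.6674
#>   LKC expansion          : 14.9631
#>   per-order terms L_d * rho_d(u):
#>     d = 0 : 0.0013499
#>     d = 1 : 0.2944
#>     d = 2 : 14.6674
```

The boundary terms (d = 0, 1) contribute 0.296 of the 14.96 expected
clusters — that is what the volume-only formula misses on a bounded box.

A small Monte Carlo comparison (mean cluster counts over 200 simulated
fields, with standard errors, next to both predictions):

```r
cfg <- experiment_config(D = 2, dims = c(100, 100), fwhms = c(5, 10),
                         cdts = c(2, 2.5, 3), n_reps = 200, seed = 7)
run_grid(cfg)
#>   fwhm cdt mc_mean_clusters      mc_se mc_mean_ec theory_eq1 theory_eq2 n_reps
#> 1    5 2.0           19.405 0.27945546     19.400 19.0597269  20.517087    200
#> 2    5 2.5            7.730 0.17632627      7.730  7.7347342   8.206694    200
#> 3    5 3.0            2.430 0.10112682      2.430  2.3467765   2.465886    200
#> 4   10 2.0            5.290 0.13216215      5.290  4.7649317   5.504987    200
#> 5   10 2.5            2.000 0.09563330      2.000  1.9336835   2.172768    200
#> 6   10 3.0            0.605 0.05440288      0.605  0.5866941   0.646924    200
```

Counts fall monotonically with FWHM and track the LKC prediction
(`theory_eq2`); the residual few-percent shortfall at FWHM 5 is the
lattice-sampling deficit discussed in the vignette — clusters narrower than
a voxel cannot be seen on the lattice. The mean discrete EC and the mean
cluster count coincide at these thresholds because suprathreshold clusters
are almost always hole-free blobs.

The wrap-around forensics — simulate on a torus, then (incorrectly) count
clusters as if the image edge were a boundary:

```r
cfg <- experiment_config(D = 2, dims = c(100, 100), fwhms = c(5, 10, 20),
                         cdts = 2, n_reps = 800, seed = 5, mode = "periodic")
forensic_torus_grid(cfg)
#>   fwhm cdt naive_mean   naive_se periodic_mean periodic_se theory_torus n_reps
#> 1    5   2   19.11375 0.14230716      18.10875  0.13220203    19.059727    800
#> 2   10   2    5.37875 0.08034499       4.75125  0.06755958     4.764932    800
#> 3   20   2    1.59125 0.04705565       1.24500  0.03374748     1.191233    800
```

Naive labeling overshoots the correct torus count in every cell, and the
*fraction* of double-counted clusters grows with smoothness (5.6% → 13.2% →
27.8%) even as the absolute excess shrinks — smoother fields have fewer,
broader clusters, so a larger share of them straddles the seam. That is the
mechanism by which a wrap-around simulation counted with edge-based
labeling inflates cluster counts ever more strongly at high smoothness and
can destroy the theoretically monotone decrease of counts with FWHM.

There is also a thin CLI over the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "rftec", package = "rftec"))') \
  theory --dims 250,250 --fwhm 5 --cdt 3
```

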