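# liverEIT

Electrical impedance tomography (EIT) of hepatic steatosis on 2-D abdomen
phantoms: forward simulation, regularized Gauss–Newton reconstruction, and
cohort correlation analysis.

## The problem

Fatty infiltration makes liver tissue less electrically conductive, so a belt
of surface electrodes injecting small alternating currents around the upper
abdomen can, in principle, grade liver fat without a scanner. MRI
proton-density fat fraction (PDFF, %) is the non-invasive reference standard
for steatosis but is costly; EIT is portable and operator-independent. The
package is aimed at researchers who want to study that measurement chain
quantitatively: it simulates the physics, reconstructs absolute conductivity
maps, and reproduces the cohort-level statistics that link liver conductivity
(S·m⁻¹) to fat fraction on a printed per-subject study table that ships with
the package.

## The method

The forward problem is the conductivity equation ∇·(−σ∇V) = 0 on a 2-D
abdominal cross-section, discretized with linear triangular finite elements
(piecewise-constant σ per element) and either a point or a complete electrode
model (contact impedance + shunting). Stimulation follows the "skipping 4"
protocol: each of the 32 electrodes in turn drives 1–4 mA against the
electrode 5 positions away, and differential voltages are recorded on every
equally spaced pair not touching a drive electrode.

Reconstruction minimizes the Tikhonov-regularized data misfit

    Φ² = ‖V₀ − f(σ)‖² + λ‖Γσ‖²

by iterated Gauss–Newton updates

    σₙ₊₁ = σₙ + (JᵀJ + λΓᵀΓ)⁻¹ Jᵀ (V₀ − f(σₙ)),

where J is the adjoint-method Jacobian of the forward map and Γ is a
*weighted Laplacian* on the element adjacency graph: full weight between
neighbouring elements of the same organ, reduced weight across anatomical
boundaries, so the prior smooths within organs but lets conductivity jump at
the (a-priori known) liver outline. The update is followed by a positivity
floor and a backtracking line search; iteration stops when the relative
change of σ falls below tolerance. Output is *absolute* conductivity — the
scale is fixed by a 1-D homogeneous fit that also initializes the iteration.

A synthetic-cohort module generates overweight subjects with PDFF spanning
1–28 %, a monotone-decreasing linear conductivity map σ = 0.346 − 0.0021·PDFF
(S·m⁻¹, the least-squares fit of the packaged table) plus measurement noise,
and demographics drawn independently of PDFF. The statistics module computes
the study's Pearson-correlation grid with slope confidence intervals and a
Bonferroni correction (m = 4 demographic tests per outcome), under the
study's exclusion-rule variants (n = 16 and n = 18).

## Worked example

```r
library(liverEIT)
spec <- referencePhantom()            # background 0.45 S/m, liver 0.30 S/m
mesh <- buildPhantom(spec, targetElementSize = 2.5)
mesh
#> TriMesh: 513 nodes, 960 elements, 64 boundary edges, 32 electrodes
#>   regions: background (776), liver (184)
#>   total area 676.97 cm^2

pat   <- makeSkipPattern(32, skip = 4, current = 2)
clean <- solveForward(mesh, trueConductivity(mesh), pat)
noisy <- addNoise(clean, "additive",
                  sd = relativeNoiseSD(clean, 0.001), seed = 1)
rec   <- reconstruct(mesh, noisy)
rec
#> ReconstructionResult: 10 iterations (converged), lambda 4.33e-07, sigma0 0.4298 S/m
#>   objective ||Vo - f(sigma)||: 0.002912 -> 4.992e-05 V
#>   sigma range [0.2865, 0.4607] S/m

round(liverConductivity(rec, mesh), 4)
#>   mean     sd
#> 0.3024 0.0087
```

The reconstructed liver mean (0.3024 S·m⁻¹) recovers the phantom's true
liver conductivity (0.30 S·m⁻¹) to 0.8 % from voltages carrying 0.1 %
measurement noise; the spatial SD (0.0087) plays the role of the per-subject
± value of the study table.

The statistics stage on the packaged table reproduces the headline inverse
correlation between liver conductivity and fat fraction:

```r
reports <- runStudyAnalysis(loadStudyTables("study_n16"))
subset(reports, outcome == "eit_mean" & variable == "pdff")
#>     outcome variable  n          r           p        slope ...
#> 11 eit_mean     pdff 16 -0.6914059 0.003011091 -0.002101386 ...
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "livereit.R", package = "liverEIT")` with subcommands
`simulate`, `reconstruct` and `stats`.

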