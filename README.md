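# gwcm — Genocchi wavelet collocation for fractional-order SIR models

`gwcm` solves the SIR epidemic model under the Caputo fractional derivative
of order γ ∈ (0, 1],

    D^γ S(τ) = -p1 S(τ) I(τ) + p3 I(τ)
    D^γ I(τ) =  p1 S(τ) I(τ) - (p2 + p3) I(τ)
    D^γ R(τ) =  p2 I(τ)

with infection rate `p1`, removal rate `p2` and a recovery-to-susceptible
return rate `p3`, by a **Genocchi wavelet collocation method** (GWCM). It is
aimed at epidemic/biological modellers who want a spectral, memory-aware
(non-local) alternative to time-stepping for short-horizon compartment
models, and at numerical analysts studying wavelet operational-matrix
methods.

## Method in brief

The γ-derivatives of the states are expanded on N = 2^(k−1)·M Genocchi
wavelets ψ_{n,m}(τ) — unit-L²-norm Genocchi polynomials G_{m+1} dilated to
2^(k−1) blocks of [0, 1):

    D^γ S(τ) ≈ Aᵀψ(τ),  D^γ I(τ) ≈ Bᵀψ(τ),  D^γ R(τ) ≈ Cᵀψ(τ).

Integrating once through the **operational matrix of integration** P and its
correction term ψ̄ (the exact identity ∫₀^τ ψ = Pψ(τ) + ψ̄(τ)) gives

    S(τ) = S₀ + Aᵀ[Pψ(τ) + ψ̄(τ)],   and likewise for I, R,

and applying the Caputo power rule termwise to the integrated representation
turns the model into 3N algebraic equations at the collocation points
τ_j = (2j − 1)/(2^k M), solved by Newton–Raphson. The basis, the matrix P
(entries like 1/2, 1/(2√3), √(31/34)/3, …) and the correction coefficient
√(5461/53898) are constructed in **exact rational/radical arithmetic**;
floating point enters only at the solve. A classical fixed-step RK4
integrator (`sir_rk4`, via deSolve) provides the γ = 1 reference.

## Worked example

```r
library(gwcm)
fit <- solve_sir(sir_parameters(gamma = 1))   # defaults: p1=0.001, p2=0.072,
print(fit)                                    # p3=0.005, S0=620, I0=10, R0=70
#> Genocchi wavelet collocation fit of the fractional SIR model
#> SIR parameters: p1 = 0.001, p2 = 0.072, p3 = 0.005; S0 = 620, I0 = 10, R0 = 70; gamma = 1
#> k = 1, M = 6 (N = 6)
#> Newton-Raphson: 3 iterations, converged, final residual 5.232e-15
#> A: -8.2785644628 -1.2508627943 -0.1945699228 -0.0261800002 -0.0023314233  0.0003036606
#> B:  7.3012330161  1.0991095158  0.1695437047  0.0222968519  0.0018113254 -0.0003451728
#> C: 9.773314e-01 1.517533e-01 2.502622e-02 3.883148e-03 5.200979e-04 4.151221e-05

sir_trajectory(fit, c(0, 0.5, 1))
#>   tau             S             I             R
#> 1 0.0 620.000000000 10.0000000000 70.0000000000
#> 2 0.5 616.478239257 13.1082720059 70.4134887367
#> 3 1.0 611.896950725 17.1480946085 70.9549546660
```

`A`, `B`, `C` are the wavelet coefficients of dS/dτ, dI/dτ, dR/dτ; their
columnwise sum is ~0 (discrete conservation of the population N = 700, which
holds along the whole trajectory to ~1e-13). Over one time unit the outbreak
moves ≈ 8 individuals out of the susceptible pool, infections grow from 10
to ≈ 17.15 and ≈ 0.95 individuals recover. Comparing against RK4 and the
packaged reference tables:

```r
cmp <- comparison_table(fit)
max(cmp$abs_diff_rk4[!cmp$flagged])       # 8.132e-08
max(cmp$abs_diff_fixture[!cmp$flagged])   # 2.901e-06
```

Fractional orders change the memory of the dynamics:

```r
fit07 <- solve_sir(sir_parameters(gamma = 0.7))
```

A command-line front end is installed with the package
(`inst/scripts/gwcm-sir`):

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/gwcm-sir", package="gwcm"))')" \
  --gamma 0.5,1 --out runs --compare
```

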