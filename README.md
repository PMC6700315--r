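# txtlsim

Kinetic modeling of gene expression in an all-*E. coli* cell-free
transcription–translation (TXTL) system, for synthetic biologists who
prototype promoters, UTRs and gene circuits in lysate-based reactions and
need to know when shared resources — ribosomes above all — become
limiting.

## The model

Expression of a reporter (deGFP) from a sigma-70 promoter is described by
three ODEs with resource conservation:

```
dm/dt   = kcat_m [P70] · E0·S70 / (KM70(K70+E0) + E0·S70)  −  kd_m · m/(KM_m+m)
dGd/dt  = kcat_p m · R0/(KM_R+R0)  −  k_mat Gd
dGm/dt  = k_mat Gd

E_tot = E0 + E70 + Em          (core RNA polymerase)
R_tot = R0 + R0·m/(KM_R+R0) · (1 + kcat_p·Lm/Cp)    (ribosomes)
```

The polymerase law is solved for the free enzyme `E0` by bracketed root
finding (once per run — the template concentration is constant); the
ribosome law is a quadratic in the free pool `R0`, solved in closed form
at every integration step. In the steady state mRNA sits at
`m_ss = k_TX/k_deg,m · [P70]` and mature reporter accumulates at
`kcat_p·kcat_m/k_deg,m · [P70]` nM/s — until the ribosome demand
`m_ss·(1 + kcat_p·Lm/Cp)` crosses `R_tot`, which with the best-fit
constants happens near 5 nM plasmid and caps the rate. A power-law "load
calculator", `[DNA] = 250·P^−0.987·U^−0.352·Lm^−0.583` nM, predicts that
limiting DNA concentration from relative promoter strength `P`, UTR
strength `U` and gene length `Lm`, and budgets ribosome load across
co-expressed constructs.

The package covers simulation, steady-state analysis, rate-curve
construction and regime labelling, fitting (mRNA lifetime, maturation
rate, catalytic constants, part strengths), one-at-a-time sensitivity
scans, the load calculator (including its re-derivation from the model),
and a seeded synthetic-data generator emulating plate-reader kinetics.

## Worked example

```r
library(txtlsim)

p <- txtl_params()                    # best-fit constants, 1 nM plasmid
mrna_steady_state(p)
#> [1] 76.24458
linear_regime_protein_rate(p)
#> [1] 0.4727273

tr <- simulate_kinetics(p, t_end = 4 * 3600)
max_synthesis_rate(tr)
#> [1] 0.4566931

rate_vs_plasmid(p, c(0.5, 1, 2, 5, 10, 20, 30), method = "steady_state")
#> # A tibble: 7 × 3
#>   plasmid_nM max_rate_nM_per_s regime
#>        <dbl>             <dbl> <chr>
#> 1        0.5             0.228 linear
#> 2        1               0.457 linear
#> 3        2               0.919 linear
#> 4        5               2.16  linear
#> 5       10               2.34  saturated
#> 6       20               2.35  saturated
#> 7       30               2.35  saturated

saturation_onset(p)
#> [1] 4.911413

limiting_dna(tibble::tibble(P = 1, U = 1, Lm = 800))$limiting_dna_nM
#> [1] 5.075029
budget_constructs(tibble::tibble(P = 1, U = 1, Lm = 800,
                                 planned_conc = 1))$load_fraction
#> [1] 0.1970432
```

Reading the numbers: at 1 nM plasmid the mRNA pool settles near 76 nM and
mature reporter accumulates at ~0.46 nM/s, proportional to plasmid; the
rate stops growing past ~5 nM plasmid because free ribosomes are depleted
onto the mRNA (`resource_depletion_profile()` shows the collapse while
free polymerase stays ample). The reference construct's limiting DNA
concentration is ~5 nM, so planning 1 nM of it consumes ~20% of the
ribosome budget of the reaction.

Fitted objects (`fit_exponential_decay()`, `fit_kcats_to_rate_curve()`,
…) support `tidy()` and `glance()`; traces, rate curves, scans and
depletion profiles have `autoplot()` methods.

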