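# fibrintrap

Coupled kinetic models of thrombin–fibrin interaction during fibrin
polymerization, for coagulation biophysicists and modelers who want to ask:
how long does thrombin stay bound at a fibrin junction, how does the
γ′ fibrinogen variant reshape fibrinopeptide release and fiber structure,
and how much thrombin ends up physically trapped inside growing fibers?

The package has two cores:

**1. A single-molecule stochastic binding model.** One thrombin molecule at
a fibrin monomer–monomer junction is a continuous-time Markov chain. At an
*AA junction* (γA/γA fibrin) the states are removed `R` (absorbing), free
`T`, and E-domain-bound `B_E1`, with the two E-domain sites doubling the
binding rate. At an *AP junction* (γA/γ′ fibrin) thrombin can additionally
bind the γ′ site (`B_G`), an E-domain adjacent to it (`B_E`), and bridge
both bivalently (`B`) through sequential transitions `B_E → B`, `B_G → B`.
Trajectories are simulated with the Gillespie direct method (`ssa_run()`,
compiled inner loop) and checked against the exact mean-first-passage
solution of the absorbing chain, `ctmc_mean_absorption()`, which solves
`-Q_TT t = 1` on the transient states. Wild-type fibrin is the 85:15
AA:AP weighted average.

**2. A mass-action ODE model of polymerization.** Twenty-nine species
couple two-step enzymatic FpA/FpB cleavage (`T + f_ab ⇌ Ef_ab → f_b + T`,
`T + f_b ⇌ Ef_b → f + T`), oligomer formation and growth (`f_2 … f_10`),
protofibril formation at a critical length of 11 monomers, lateral
aggregation into fibers, steric inhibition of end-to-end binding by γ′
chains (multiplier `S_bind·(P_pp + P_gp) + P_gg`), and thrombin binding to
polymerized fibrin with dissociation-upon-FpB-cleavage (fraction `R_biv`
of bivalently bound thrombin released). Structure metrics turn
trajectories into protofibril number per fiber `m = P_fr/f_r`, clot time
(half-maximal fiber mass), and the trapped-thrombin fraction
`φ_trap = I(m)·φ_Tfiber`, where `I` is the inaccessible fraction of a
hexagonally packed fiber cross-section whose outer two layers are
thrombin-accessible. A multistart constrained least-squares workflow
(`fit_clot_times()`) fits the nine polymerization parameters to
clot-time-ratio data and screens candidates with two qualitative criteria
(protofibril number must fall with thrombin and with γ′ content).

## Worked example

```r
library(fibrintrap)

# How long does one thrombin molecule survive at each junction type when
# removed from the free state at 0.01/s?
kr <- 1e-2
aa <- ctmc_mean_absorption(junction_model("AA", kr))
ap <- ctmc_mean_absorption(junction_model("AP", kr), "B_E")
c(AA_min = aa$total / 60, AP_h = ap$total / 3600,
  WT_min = (0.85 * aa$total + 0.15 * ap$total) / 60)
#>    AA_min      AP_h    WT_min
#>  4.053571  1.620783 18.032586

round(ap$category_fractions, 3)
#>  free   low  high
#> 0.017 0.012 0.971
```

Thrombin survives ~4 minutes at an AA junction but ~1.6 hours at an AP
junction — bivalent γ′ binding shields it from removal (97% of its time in
bivalent-associated states) — and ~18 minutes at a wild-type mix.

```r
# Polymerize dilute fibrinogen with 0.1 nM thrombin, with and without γ′
sc <- scenario_fpb_cleavage(r_values = c(0, 1, 2))
sc$summary
#>   r FpA_done_min FpB_done_min free_thrombin_pct_final
#> 1 0     34.12359    140.45543               82.679106
#> 2 1     35.42064     65.11877               10.638780
#> 3 2     37.98253     50.68223                5.732703
```

FpA release is insensitive to γ′ content (~35 min in all cases), but FpB
release accelerates more than twofold as the γ′:E ratio rises from 0 to 2,
and the fate of thrombin flips: without γ′ about 83% remains free after
polymerization, with γ′ nearly all of it ends up bound — the dual
localize-then-sequester role of the γ′ sites.

```r
# One full simulation with structure metrics
sim <- polymerize(thrombin_nM = 1, fibrinogen_uM = 3.29, r = 0.3,
                  t_end = 1800)
summary(sim)
#> Final state:
#>            FpA_pct            FpB_pct  free_thrombin_pct
#>            100.000             99.987              3.335
#> protofibril_number           phi_trap
#>            148.950              0.510
#> Clot time (s): 284.9783
#> Max relative conservation drift: thrombin 2.46e-12 , fibrinogen 2.16e-15
```

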