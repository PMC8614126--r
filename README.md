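# seamsim

Simulation of two-stage adaptive seamless (phase II/III) clinical trial
designs with interim **treatment selection** (multi-arm comparisons against a
common control) or **subgroup selection** (adaptive enrichment of a
pre-defined subgroup nested in the full population).

The package is for trial statisticians planning such designs: it computes the
operating characteristics — power per hypothesis, selection frequencies,
futility rates, expected sample size — by fast Monte Carlo simulation, and it
implements the confirmatory analysis those designs rely on, so the same code
base answers both "how often would this design work?" and "how is the final
test computed?".

## The statistical core

For the family of one-sided null hypotheses H_k : θ_k = 0 (θ_k the effect of
arm k versus control, or of the treatment in population k), strong familywise
error control under *any* data-driven interim adaptation is obtained by
embedding combination tests in a closed testing procedure:

* every intersection hypothesis H_K, K ⊆ {1..K}, is tested at level α by
  combining independent stage-wise p-values with the inverse normal rule
  C_K = w1 Φ⁻¹(1−p_K1) + w2 Φ⁻¹(1−p_K2), w1² + w2² = 1 (Fisher's product
  rule is available for treatment selection);
* stage-wise intersection p-values come from Dunnett tests (multi-arm,
  equicorrelation 1/(1+λ) from the shared control), or for subgroup designs
  from the Spiessens–Debois test 1 − Φ₂(z_max, z_max; √(I_S/I_F)), Simes or
  Bonferroni;
* after selection, the stage-2 p-value of H_K is that of H_{K∩I₂} (I₂ the
  continuing set; p = 1 when empty), and dropped hypotheses are never
  rejected;
* H_k is rejected iff every H_K with k ∈ K is rejected.

Trials are simulated at the level of standardized statistics
Z ~ N(θ√I, 1) with the joint covariance induced by shared patients and
controls (between-arm 1/(1+λ); early–final ρ; subgroup–full √(I_S/I_F);
independent stage-2 increments), so runtime does not grow with patient
numbers. Normal, binary (event rates → log odds ratios) and time-to-event
(exponential expected events → log hazard-ratio statistics) outcomes are
supported for both the early (selection) and final (testing) endpoint.
See `vignettes/seamless-designs.Rmd` for the full model.

## Worked example

A multi-arm COPD dose-finding trial: four doses versus placebo, selection of
the best two doses at the interim on an early lung-function outcome
(standardized effects 0.68–0.95), confirmatory testing on the final outcome
(standardized effects 0.13–0.23), within-patient correlation 0.4, 100
patients per arm in stage 1 and 300 in stage 2, one-sided α = 0.025:

```r
library(seamsim)
design <- treatsel_design(
  n = list(stage1 = 100, stage2 = 300),
  effect = list(early = c(0, 0.68, 0.82, 0.95, 0.91),
                final = c(0, 0.13, 0.17, 0.23, 0.20)),
  outcome = list(early = "N", final = "N"),
  corr = 0.4, select = 2, ptest = c(3, 4))
simulate_treatsel(design, nsim = 10000, seed = 2026)
```

```
simulation of test statistics:
expectation early = 4.8 5.8 6.7 6.4
expectation final stage 1 = 0.9 1.2 1.6 1.4 and stage 2 = 1.6 2.1 2.8 2.4
weights: stage 1 = 0.5 and stage 2 = 0.87

number of treatments selected at stage 1:
          n   %
1         0   0
2     10000 100
3         0   0
4         0   0
Total 10000 100

treatment selection at stage 1:
     n     %
1  404  4.04
2 3329 33.29
3 8623 86.23
4 7644 76.44

hypothesis rejection at study endpoint:
      n     %
H1  185  1.85
H2 2134 21.34
H3 7288 72.88
H4 5658 56.58

reject H3 and/or H4 = 8543 : 85.43%
expected total sample size = 1400
```

The header lists the expected z statistics implied by the design (early
outcome at the interim; final outcome by stage) and the pre-specified
combination weights √(100/400) and √(300/400). The tables then give, over
10,000 simulated trials, how many arms continued (always two here), how often
each dose was selected, and how often each elementary null hypothesis was
rejected by the closed test. The last lines report the probability of
claiming efficacy for at least one of the two highest doses (the `ptest`
set), about 85%, and the expected total number of patients (fixed at 1,400
for this always-select-two rule).

Subgroup designs work the same way through `subpop_design()` and
`simulate_subpop()`; ready-made configurations, including an oncology
enrichment trial with time-to-event outcomes, ship with the package
(`list_fixtures()`, `load_fixture("oncology-subgroup")`). A thin command-line
driver is provided as `exec/seamsim`:

```sh
Rscript exec/seamsim subpop --fixture oncology-subgroup --nsim 10000 --seed 1
Rscript exec/seamsim treatsel --fixture copd-setting2 --grid thresh=0:6:0.5 --out grid.csv
```

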