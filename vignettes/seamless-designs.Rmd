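---
title: "Simulating two-stage adaptive seamless designs with treatment or subgroup selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating two-stage adaptive seamless designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seamsim)
```

## The design problem

An adaptive seamless phase II/III trial combines, in a single protocol, a
selection stage and a confirmatory stage. In the multi-arm variant, $K$
experimental treatments are compared with a shared control; an interim
analysis drops the less promising arms and the surviving arms continue to a
confirmatory test. In the enrichment variant, a single treatment is compared
with control in a pre-defined subgroup $S$ (prevalence $\tau$) nested in the
full population $F$; the interim analysis decides whether stage 2 recruits
both populations, the subgroup only (possibly with an enlarged subgroup
sample size), the full population only, or stops for futility.

Because the same stage-1 patients inform both the adaptation and the final
analysis, naive testing inflates the familywise error rate (FWER). The
package implements the standard remedy: stage-wise $p$-values are combined
with a pre-specified combination function whose null distribution is known
*whatever* adaptation occurred (the $p$-clud property of independent
stage-wise increments), and multiplicity over the hypothesis family
$H_k : \theta_k = 0$ is handled by closed testing — $H_k$ is rejected only if
every intersection hypothesis $H_{\mathcal K}$, $k \in \mathcal K$, is
rejected at level $\alpha$. This controls the FWER in the strong sense for
any data-driven selection rule.

Interim selection is often based on an *early* outcome (for example trough
FEV1 at 15 days in a COPD trial, or progression-free survival in oncology)
while hypothesis testing uses the final outcome; the within-patient
correlation $\rho$ between the two outcomes is a key operating-characteristic
driver and is an explicit model parameter.

## The simulation model

Trials are simulated at the level of standardized statistics, never patient
records: every test statistic is taken to be normal with unit variance,
$Z \sim N(\theta \sqrt{I}, 1)$, where $I$ is the Fisher information of the
treatment-effect estimate. Simulation cost is therefore independent of the
sample sizes. The expected statistics per outcome type are

* **normal (N)** — effects are standardized mean differences;
  $E[Z] = \sqrt{n/2}\,(\mu_k - \mu_0)$ with $n$ patients per arm ($I = n/2$);
* **time-to-event (T)** — under an exponential model with unit follow-up, the
  expected total event count for arm $k$ versus control is
  $o_k = n(1 - e^{-h_0}) + n(1 - e^{-h_k})$ and
  $E[Z] = \sqrt{o_k/4}\,\Delta$ ($I = o_k/4$). Two dialects are supported and
  are explicit fields, never inferred: the treatment-selection driver takes
  effects as *minus log hazard rates* ($h = e^{-\mu}$,
  $\Delta = \mu_k - \mu_0$, positive good), the subgroup driver takes *hazard
  ratios* against a unit control hazard ($\Delta = \log \mathrm{HR}$,
  negative good);
* **binary (B)** — effects are event rates (lower better), converted to minus
  log odds $\mu = \log\{(1-r)/r\}$; $E[Z]$ is the log odds ratio divided by
  the standard error from the expected $2\times 2$ cells,
  $I^{-1} = 1/o_k + 1/(n-o_k) + 1/o_0 + 1/(n-o_0)$.

Internally all statistics are canonicalized so that **larger is better**; the
hazard-ratio dialect is sign-flipped on ingestion and reports flip back for
display. The early--final correlation `corr` is interpreted on this canonical
scale.

The joint distribution is multivariate normal with the correlations induced
by shared patients and shared controls:

* statistics of different comparisons with a common control:
  $1/(1+\lambda)$ for 1:$\lambda$ allocation (the drivers fix $\lambda = 1$;
  the covariance builder accepts general $\lambda$);
* early and final stage-1 statistics of the *same* arm: $\rho$ (same
  patients, equal per-patient information); of *different* arms:
  $\rho/(1+\lambda)$ (shared control only);
* subgroup versus full population, same stage and outcome:
  $\sqrt{I_S/I_F}$, the nesting-induced correlation. For normal outcomes with
  equal per-patient information this is exactly $\sqrt{\tau}$; for
  time-to-event and binary outcomes the package uses the
  information ratio implied by the event counts, which reproduces the
  benchmark interim branch frequencies slightly better than $\sqrt\tau$ and
  reduces to it when event rates are equal. Cross terms (different outcome
  *and* population) are $\rho\sqrt{r_E r_F}$ with $r_e$ the per-outcome
  population correlation, the exact Kronecker product structure when
  $r_E = r_F$;
* stage-2 statistics are *increments* computed from stage-2 patients only,
  hence independent of everything at stage 1. The statistic that pooled data
  would give is recovered by information weighting,
  $(\sqrt{I_1} Z_1 + \sqrt{I_2} Z_2)/\sqrt{I_1 + I_2}$
  (`cumulative_final_statistic()`), whose correlation with $Z_1$ is the
  group-sequential $\sqrt{I_1/I_2}$ for nested analyses.

Storing independent increments and always feeding *stage-wise* $p$-values to
the combination test keeps the $p$-clud independence property true by
construction.

All model covariances are validated against a patient-level simulation
oracle in the test suite (small $n$, hundreds of thousands of simulated
trials, normal outcomes): the statistics-level model is exact there, not an
approximation. What the generator does **not** emulate: censoring processes
and calendar-time event accrual for survival outcomes (stage-wise survival
$p$-values can violate $p$-clud in ways this model cannot show), non-normal
small-sample behaviour, and overrunning patients recruited between the
interim cut-off and the decision. Passing tests therefore demonstrate the
operating characteristics of the *asymptotic* design, not robustness to
those finite-sample complications.

## Interim selection rules

For treatment selection (`select_treatments()`), on the early statistics:
select all; the best 1, 2 or 3; the $\epsilon$-rule (all arms within
$\epsilon$ of the maximum — $\epsilon = 0$ is best-1, large $\epsilon$ keeps
all); one arm at random; or all arms above a threshold, where an empty set is
a futility stop. Ties in the best-$M$ rules are broken uniformly at random
from the simulation RNG stream (a measure-zero event for continuous
statistics, but defined and seedable for crafted inputs).

For subgroup selection, two rules map the early statistics to a continuation
branch. The *threshold* rule uses the difference
$\Delta = Z_F - Z_S$ on the canonical scale: subgroup only when
$\Delta \le l_1$, full population only when $\Delta > l_2$, otherwise both;
the order of the difference and the tie conventions ($\le l_1$, $> l_2$)
follow the documented behaviour of the limiting cases — with limits $(0,0)$
exactly the population with the larger interim statistic continues, with
very wide limits both always continue. The *futility* rule operates on the
natural smaller-is-better scale $S = -Z$ (for hazard-ratio outcomes this is
the untransformed statistic): both populations continue when $S_S < l_1$ and
$S_F < l_2$, one population when only its inequality holds, and the trial
stops for futility when neither does. For larger-is-better outcomes the
driver applies the same rule to $-Z$, so limits are always stated on the
smaller-is-better scale.

## Confirmatory analysis

Stage-wise $p$-values for an intersection $\mathcal K$ come from one-sided
intersection tests: Dunnett's test for multi-arm comparisons (exploiting the
$1/(1+\lambda)$ equicorrelation), and for subgroup designs the
Spiessens–Debois test ($1 - \Phi_2(z_{\max}, z_{\max}; \sqrt{I_S/I_F})$),
Simes, or Bonferroni. Stages are combined by the inverse normal rule
$C = w_1 \Phi^{-1}(1-p_1) + w_2 \Phi^{-1}(1-p_2)$ with pre-specified weights,
$w_1^2 = n_1/(n_1+n_2)$ by default from the *planned* full-population stage
sizes — deliberately never recomputed after enrichment, since combination
weights must be fixed in advance. Fisher's product rule
($p_1 p_2 \le e^{-\chi^2_{4,1-\alpha}/2}$) is available for treatment
selection. There is no interim efficacy stop: the only stage-1 exits are
selection and futility, and the final test uses the critical value
$\Phi^{-1}(1-\alpha)$ with one-sided $\alpha = 0.025$ by default.

Dropped hypotheses follow the rule that the stage-2 $p$-value of
$H_{\mathcal K}$ is the $p$-value of $H_{\mathcal K \cap I_2}$, where $I_2$
is the set carried into stage 2; when the intersection is empty (and
follow-up of dropped arms is discontinued) the stage-2 $p$-value is 1, and a
dropped hypothesis is never rejected. The stage-1 $p$-value always uses all
of $\mathcal K$, since every arm has stage-1 data. We also examined the
alternative reading in which dropped statistics enter as $-\infty$ but the
Dunnett dimension stays $|\mathcal K|$; at 400,000 replicates it depresses
the power of the always-best-two reference design by about five percentage
points below the benchmark value, while the rule above reproduces it, so the
reduced-intersection rule is the one implemented. Under complete follow-up
(`fu = TRUE`) dropped arms keep contributing: their stage-2 statistics are
drawn with stage-1 information (the continued follow-up of already-recruited
patients adds roughly a stage-1-sized cohort of final outcomes), and
intersection tests retain their full dimension; dropped hypotheses remain
unrejectable.

## Numerical choices

* $\Phi^{-1}(1-p)$ is clipped to $\pm 8.2$ so the $p \in \{0, 1\}$
  conventions stay finite; the cap changes no decision at any
  $\alpha \ge 10^{-15}$.
* Equicorrelated multivariate normal CDFs (Dunnett, Spiessens–Debois) use the
  one-factor reduction $\int \phi(x) \Phi\{(z - \sqrt{r}x)/\sqrt{1-r}\}^m dx$
  evaluated by a fixed 128-node Gauss–Legendre rule on $[-8.5, 8.5]$:
  deterministic, vectorised over replicates, absolute error below $10^{-6}$
  (tested against an independent CDF oracle at $10^{-5}$). The drivers
  enforce $K \le 7$.
* Covariance matrices are validated for symmetry and positive
  semi-definiteness at construction; a semi-definite matrix (e.g. perfect
  correlation) falls back to an eigenvalue factorisation.
* With varying prevalence, one binomial draw of subgroup membership out of
  the per-arm stage-1 sample size is taken per simulated trial; the realized
  fraction replaces $\tau$ in means and correlations for both stages and is
  clamped away from 0 and 1 so that the nested model remains defined.
* Enrichment default: a subgroup-only continuation without a planned
  `enrich` size recruits as originally planned, so the subgroup information
  is $n_2 \tau$ per arm.

## Problem sizes and what the tests show

The shipped example configurations (a COPD dose-selection trial in three
variants and an oncology enrichment trial) run at 10,000 replicates each,
matching the benchmark analyses; each takes on the order of a second. The
FWER properties are checked at 100,000 replicates under the global null for
every method and selection rule in the fixture registry, with the bound
$\alpha + 3\sqrt{\alpha(1-\alpha)/n_{\mathrm{sim}}}$. Patient-level oracle
comparisons use $2$–$3\times 10^5$ replicates at per-arm sizes of 4–20,
where Monte Carlo error on a covariance entry is well below the asserted
0.015–0.02. Benchmark Monte Carlo percentages are reproduced within three
standard errors of the difference of two independent 10,000-replicate
estimates, since seeds do not transfer across implementations.

## Known limitations

Exactly two stages; one subgroup nested in one full population (no multiple
or overlapping subgroups, no simultaneous treatment-and-subgroup selection);
no early efficacy stopping or $\alpha$-spending boundaries; no sample-size
reestimation; no treatment-effect estimation or selection-bias correction;
no survival-specific combination-test extensions; equal control and
experimental sample sizes in the drivers. The conditional-error-function
subgroup method is out of scope; the combination-test methods implemented
here are self-contained.
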