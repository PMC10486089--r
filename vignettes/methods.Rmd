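---
title: "Methods: claims-based asthma ascertainment, weighted agreement, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based asthma ascertainment, weighted agreement, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures `claimsagree` implements,
the numerical and design choices that were genuinely open, and what the
synthetic cohort does and does not emulate.

## The measurement problem

Neither administrative health data nor self-report is a gold standard for
asthma status. Administrative data record *health-care contacts* coded for
asthma (a person whose asthma never led to a billed visit is invisible);
self-report records *recall* of a diagnosis (subject to memory, wording, and
confusion with other respiratory conditions). The package quantifies the
agreement between the two and models its determinants, under a survey design
that deliberately over-sampled people with childhood asthma.

## Event normalization and diagnosis matching

Events are matched to asthma by 3-character rubric prefix after stripping
punctuation: ICD-9 `493` for physician claims throughout, and for
hospitalizations up to the end of 2005; ICD-10 `J45` for hospitalizations
from 2006, when the hospital discharge stream switched revisions. We match on
the 3-character rubric only, because finer codes (`4930`, `J45.0`) denote the
same condition. The claims stream never switched to ICD-10 during the study
period, so a `J45` claim, or a hospitalization coded in the wrong revision
for its date, is a coding-dialect anomaly: configurable as warn-and-accept
(default) or reject. Duplicate same-day encounters are collapsed to one,
keeping the hospitalization when both kinds coincide — hospitalization is the
stronger signal and this mirrors how the source data were counted.

## The ascertainment family

A person is a case under window length $k$ if, inside the lookback (claims
era start 1983 to the person's interview), they have $\ge 2$ distinct-day
asthma claims with some pair at most $\lfloor k \times 365.25 \rfloor$ days
apart, or $\ge 1$ asthma hospitalization. Two interpretations of "within
$k$ years" were possible (calendar anniversaries vs day counts); we use the
day-difference rule because it is leap-safe, unambiguous, and monotone in
$k$: enlarging the window can never declassify a case, so crude prevalence
must be non-decreasing across $k \in \{1, 2, 3, 5, 30\}$ — a property the
test suite asserts. With a 30-year lookback, $k = 30$ is equivalent to "any
two claims", which is also how the pre-1995 sampling definition
(`window_years = Inf`, lookback end 1994-12-31) is expressed. The
minimum-consecutive-gap implementation is tested against an all-pairs brute
force on 10,000 random date sets.

Coverage gaps do not mask events; persons with gaps are instead excluded
wholesale in the corresponding sensitivity analysis, matching how the
original analysis treated them.

## Design weights and the effective sample size

With $N_s$ cohort members and $n_s$ respondents in stratum $s$ (BCG ×
childhood asthma), each respondent carries $w_s = N_s / n_s$. Weights are
deliberately *not* normalized to mean 1: their total reproduces the cohort
size, and all confidence intervals use the actual respondent count
$n = \sum_s n_s$ as the effective sample size. This matches the convention
that the variance is based on the real number of interviews, and it means
CIs do not pretend the survey is as informative as the cohort. Nonresponse
(participation 56%) is folded into the realized $n_s$ rather than modelled
with response propensities.

## Agreement statistics

On weighted cell proportions $p_a, p_b, p_c, p_d$:

* overall agreement $p_o = p_a + p_d$, CI $p_o \pm 1.96\sqrt{p_o(1-p_o)/n}$;
* $\kappa = (p_o - p_e)/(1 - p_e)$ with
  $p_e = (p_a{+}p_b)(p_a{+}p_c) + (p_c{+}p_d)(p_b{+}p_d)$, CI from the
  Fleiss–Cohen–Everitt large-sample variance evaluated at the weighted
  proportions;
* $P_{pos} = 2p_a/(2p_a+p_b+p_c)$ and $P_{neg} = 2p_d/(2p_d+p_b+p_c)$.

The exact standard error the original analysts used for $P_{pos}/P_{neg}$ is
not derivable from their report; we use the same binomial normal
approximation as for $p_o$ (a pragmatic, slightly conservative choice for
proportions near 1) and provide a person-bootstrap alternative
(`agreement_boot()`) for users who prefer a resampling interval. All
intervals are clipped to their valid ranges. Persons with missing
self-report are dropped pairwise; administrative status is complete by
construction and a missing value there is an error, not a deletion.

Degenerate inputs are errors rather than numbers: an empty table, or margins
so one-sided that $p_e = 1$ (kappa undefined).

## Weighted logistic regression and selection

The agreement outcome (both sources concur) is modelled with
design-weighted logistic regression. Coefficients solve the weighted score
equations via IRLS; the covariance is the linearization sandwich
$B^{-1} M B^{-1}$, with $B$ the weighted information and $M$ the outer
product of per-person weighted scores. This accounts for the weights but not
for the stratification of the design (the original report is silent on
whether its Taylor variance did); ignoring the stratification is slightly
conservative. Coefficients are invariant to rescaling all weights, which the
tests assert. Separation and rank deficiency raise errors naming the
offending variable rather than returning absurd estimates; during
univariable screening a separating candidate is dropped with a warning
instead of aborting the whole selection.

Purposeful selection uses multi-degree-of-freedom Wald tests on the sandwich
covariance: candidates with univariable $p < 0.25$ enter the initial
multivariable model; those with multivariable $p < 0.25$ are refit as the
final model. The threshold is deliberately liberal (screening, not
inference) and strict `<` is the default with `<=` available, since either
reading of the criterion is defensible.

## Multiple imputation

Missingness is confined to categorical covariates. Rather than a
multivariate MCMC imputer, missing values are drawn from the weighted
category distribution of complete cases within each (outcome × stratum)
cell — a dependency-light, seedable imputer adequate for purely categorical
covariates whose missingness is generated (and assumed) unrelated to the
unobserved values. Fits over the $m = 20$ completed datasets are pooled by
Rubin's rules: pooled covariance $\bar W + (1 + 1/m) B$. With no missing
data the pooled fit equals the single fit exactly; with $m = 1$ the between
component is defined as zero. In the pipeline, selection is run on the first
completed dataset and the selected model is then pooled over all 20 — the
original report does not specify how selection interacted with its
imputations, and selecting once keeps the selected model identical across
imputations so Rubin's rules apply cleanly.

## Sensitivity scenarios

The sampling frame excluded persons who failed the asthma definition but had
exactly one asthma claim in 1983–1994 — 5.9% of the eligible non-asthma
pool. The re-inclusion scenario adds the implied number of such persons
($0.059/0.941$ per retained non-asthma respondent, rounded to whole
persons), administratively negative by construction, splitting them between
self-report yes/no by a `report_fraction` (1 = worst case, 0.5 =
intermediate). They carry non-asthma-stratum weights, allocated
proportionally across the two non-asthma strata (the original allocation is
unstated; proportional is the neutral choice). Kappa is monotone
non-increasing in `report_fraction`, property-tested over random tables.

Service-history stratification uses integer ages at event dates anchored at
the cohort's mid-year birthday (all members share a birth year; exact
birthdates are synthetic), duration = days between first and last asthma
service / 365.25, and reports empty bins as empty, never as 0%.

## The synthetic cohort

The generator emulates: a single-birth-year cohort (default 80,000; the
analyses and acceptance checks here use 20,000 — about a quarter scale —
which keeps a full run in seconds while leaving hundreds of persons per
design stratum); four latent asthma classes (never 80%, transient childhood
11%, persistent 6%, adult onset 3%); Poisson claims during the active
disease window thinned to the 1983+ claims era, with a gamma frailty (shape
0.7) on each person's claim rate to give realistic utilization
overdispersion; hospitalizations from 1987; ICD revision switching in 2006;
a stray single 1983–1994 claim for 5.9% of never-asthma persons (the group
the real frame excluded); self-report sensitivity rising logistically with
service duration and hospitalization; survey participation 56%; Table-1-like
categorical covariates with their observed missingness; and an
allergy-services indicator enriched among discordant persons so the
determinant analysis has a recoverable signal with OR < 1.

Class probabilities, claim rates and the self-report coefficients were
calibrated once so that the sampled survey reproduces the study-like
envelope — crude prevalence ≈ 49–55% rising in $k$, design-corrected
prevalence ≈ 13–15%, corrected self-report prevalence ≈ 16–19%, kappa in the
good band, and a rising duration→agreement gradient — and then frozen; they
are configuration, not empirical claims.

What the generator does **not** emulate: real billing behaviour (visit
clustering by exacerbation, provider effects), diagnostic miscoding rates,
the BCG–asthma association (BCG is independent of disease), informative
missingness, and any dependence structure among covariates. Consequently,
passing recovery tests shows the *estimators* are correct under the stated
design, not that the pipeline is robust to real-data pathologies outside
that model.

## Problem sizes and determinism

Default analysis scale: cohort 20,000; 411 participants per stratum
(≈ 1,644 interviews); Monte-Carlo checks use 200 replicate surveys (or 200
simulation seeds) and report means against generated ground truth. Every
random stage flows from a single integer seed; a rerun with the same
configuration is byte-identical, and the run manifest records the seed and a
hash of the configuration.

## Known limitations

* The kappa CI uses the large-sample variance at weighted proportions with
  the respondent count; it has no finite-population or stratification
  correction.
* The imputer conditions on outcome and stratum only, not on other
  covariates; with strongly inter-correlated covariates and informative
  missingness it would understate between-imputation variance.
* The re-inclusion scenario treats the hypothetical persons' weights as
  fixed at current stratum weights rather than re-deriving the design.
* Window lengths are interpreted in days; analyses that defined windows on
  calendar years would differ at the margins.
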