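---
title: "Quantifying loss-of-function mutation rates from sucrose counterselection data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying loss-of-function mutation rates from sucrose counterselection data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sutox)
```

## The assay and its estimator

The sucrose-toxicity (SuTox) assay measures the fidelity of a DNA synthesis
process by positive selection. A cassette carrying *sacB* — whose product,
levansucrase, is lethal to *E. coli* on sucrose — is replicated by the
process under study (growth in an *E. coli* strain, PCR, or rolling-circle
amplification), cloned into a vector, and transformed. Plated without
sucrose, every transformant grows: this counts total molecules sampled.
Plated on sucrose, only cells whose *sacB* copy acquired a loss-of-function
(LOF) mutation during synthesis survive. The sucrose:plain ratio of
colony-forming units (CFU) therefore estimates the fraction of synthesized
molecules carrying a LOF mutation in the target.

Because different processes replicate the template a different number of
times, the mutant fraction is normalized by the number of **DNA
doublings**, $d = \log_2(m_\text{out}/m_\text{in})$, giving the central
estimator

$$\hat r \;=\; \frac{N_\text{mut}}{N_\text{tot}\, d}$$

the LOF rate per molecule per doubling. Dividing by the mutational target
length $L$ (the *sacB* ORF plus promoter, 1,533 bp by default) gives a
per-bp rate, and multiplying that by $1000 \times 100$ expresses it in
percent per kb — the unit used for cross-method comparison.

Three conventions precede the division, and each silently changes values,
so `run_estimation()` logs every application:

* **Normalization.** Each raw plate count is scaled by its dilution factor
  and divided by the plated fraction, estimating the CFU of the whole
  transformation. Any dilution shared by the sucrose and plain plates (and
  their controls) cancels in the rate — a property the test suite checks.
* **Background subtraction.** CFU on the no-insert negative-control
  transformation are subtracted from both media, after normalizing both
  sides. A control exceeding its sample clamps to zero rather than going
  negative: the subtraction is an expectation correction, and a negative
  mutant count is not physical.
* **Detection limit.** A replicate with zero net sucrose CFU after
  subtraction is *below the detection limit* (BDL) and is scored as if 0.5
  CFU had been observed, giving a strictly positive floor rate and a
  `bdl_flag`. Only an exact zero triggers the rule; fractional positive
  counts, which normalization can produce, pass through. The floor is the
  standard half-count convention for censored counts: it preserves the
  replicate in group means while marking that the true rate is only
  bounded from above.

### Input-mass conventions

In vivo synthesis starts from the single plasmid molecule that transformed
the founder colony, so the input mass is the mass of one plasmid:
$L_\text{plasmid} \times 650\,\mathrm{g\,mol^{-1}} / N_A$. The 650 g/mol
per base pair figure is the standard dsDNA average; it is a package
constant exposed as the `bp_molar_mass` argument wherever it enters. In
vitro reactions start from a weighed template, but only the amplified
region is copied, so the effective input is the template mass times the
amplicon's fraction of the plasmid length. RCA is normalized identically
to PCR via $\log_2$ of the mass ratio even though its amplification is
partly linear; per-doubling rates for RCA are therefore a convention, not
a mechanistic quantity, and should only be compared under that same
convention.

## Group comparison

Fold changes divide each group's mean per-doubling rate by a selectable
reference group's mean (different references suit different questions —
the least-error in vivo strain for headline ratios, a standard lab strain
for significance testing). Significance uses a one-way ANOVA on the
untransformed per-replicate rates followed by Dunnett's many-to-one
contrasts against the reference (two-sided, single-step adjusted, via
**multcomp**). Untransformed rates are used because the assay's headline
claims are about ratios of means; with heavy-tailed (jackpot) replicate
variance a log transform could be defended, but it would change the
hypothesis being tested, so the package leaves transformation to the
caller. Designs with fewer than two groups or replicates, or with zero
within-group variance, are rejected with classed errors rather than
returning meaningless statistics.

## Construct-level risk

For manufacturing decisions the per-kb rate is propagated to whole
constructs. Two modes are provided:

* **linear** (default): $P(\text{LOF}) = (r/100) \times L_{kb}$, and for a
  co-transfection of several constructs
  $P(\text{all intact}) = 1 - \sum_i P_i$. This is the first-order
  arithmetic used in the assay's published worked examples; it errors once
  a probability would reach 1.
* **poisson**: LOF hits as a Poisson process along the construct,
  $P(\text{LOF}) = 1 - e^{-(r/100) L_{kb}}$ and
  $P(\text{all intact}) = \prod_i (1 - P_i)$. Statistically exact for
  independent hits and always a valid probability; it never exceeds the
  linear value ($1 - e^{-x} \le x$) and converges to it as
  $rL \rightarrow 0$.

`reproduce_examples()` recomputes the package's worked examples from its
shipped rate table and reports each alongside its rounded value under one
precision rule (`report_percent()`: two decimals at or above 99%, one
decimal between 1% and 99%, two decimals below 1% — chosen so that
near-certain intactness is not flattened to 100% and small risks keep two
informative digits).

## The forward simulator

Every stage above is validated against a forward simulation of the assay
with known ground truth, since raw plate counts for real runs are rarely
published.

**Replication** is a population-count branching process. Mutation is
modelled at whole-molecule granularity: a copy event produces a LOF
molecule with probability $q = 1 - (1-\mu)^L$, where $\mu$ is the true
per-bp rate — the assay observes only the LOF phenotype, so per-base
sequence simulation would add cost without information. Each cycle, every
molecule replicates with probability `per_cycle_efficiency` (1 for in vivo
growth), and a replicating molecule is replaced by two daughters. Both
daughters carry one newly synthesized strand under semiconservative
replication, so each is independently at risk $q$; strand-level
bookkeeping (heteroduplex resolution) is otherwise ignored. LOF is
absorbing — daughters of a mutant are mutant — because reversion is
negligible at these rates. Under this model the expected mutant fraction
after $d$ cycles at efficiency 1 is exactly

$$f_d = 1 - (1-q)^d,$$

which `expected_mutant_fraction()` provides as the closed-form oracle
(restricted to $q \le 0.01$, where the branching expectation and the
per-lineage form coincide to the accuracy the tests use). Per-generation
binomial draws preserve Luria–Delbrück jackpot variance at the population
level without storing lineage trees. Populations are capped (default
$10^9$ molecules) and a run that would exceed the cap errors with advice
to rescale, rather than silently losing integer resolution.

Note the estimator's per-doubling normalization assumes $f_d \approx qd$;
at large $qd$ the saturation of $f_d$ biases $\hat r$ low by roughly
$(d-1)q/2$ relative. At a Phi29-like rate ($q \approx 0.009$, $d = 20$)
this is about 8% — visible in the recovery checks and inherent to the
per-doubling convention itself, not to the implementation.

**Plating** uses standard plating statistics, stated here as the module's
own assumptions: the transformants reaching each plate are Poisson with
mean `transformants_mean × plated_fraction / dilution_factor`; sucrose
survivors are a binomial thinning of that draw at the population mutant
fraction; every plate, including the matched negative controls, receives
independent Poisson background colonies. Sampling is with replacement,
valid while transformants are a small fraction of the molecule
population; a guard errors when the expected transformants exceed 1% of
it.

**Determinism.** A single integer master seed; replicate $r$ reseeds the
generator with $(\texttt{seed} + 7919r) \bmod (2^{31}-1)$, so any
replicate can be regenerated independently and identical configurations
are bit-identical.

### Default study conditions

The generator defaults describe a realistic bench-scale run: three
biological replicates, 20 replication cycles, the 1,533 bp target, a
Phi29-like true rate of $5.8 \times 10^{-6}$ per bp per doubling,
$10^5$ expected transformants, a mean of one background colony per plate,
and 500 initial molecules for in vitro methods (in vivo is fixed at one
molecule by the biology). Validation and recovery runs in the tests use
$10^6$ transformants, 10 replicates and zero background — sizes chosen so
sampling noise is well below the tolerances being checked while a full
suite completes in seconds. Recovery *bias* properties are checked at
$q = 2\times10^{-3}$, where the per-doubling convention's saturation bias
(~2%) is within the 5% bound being asserted; the Phi29-scale recovery is
checked against its own, wider stochastic tolerance.

## What the simulator does and does not emulate

It reproduces the statistical structure the estimator relies on: mutant
fractions growing with doublings at a true per-bp rate, jackpot variance,
Poisson plating noise, background colonies and BDL events. It does not
model ligation or gel-extraction losses, primer artifacts, multimer
digestion, sequence-dependent mutability, non-LOF (e.g. silent) mutations,
or RCA's linear-phase kinetics. Passing recovery tests therefore show the
arithmetic chain is faithful to its own model, not that the model captures
every feature of a wet-lab run — in particular, the total mutation rate of
a real process is higher than its LOF rate, and per-doubling RCA rates
inherit the $\log_2$ convention discussed above.

## Numerical and degenerate-input choices

All errors are classed conditions (`sutox_schema_error`,
`sutox_degenerate_replicate`, `sutox_invalid_parameter`, ...) so pipelines
can map them to exit codes. Zero net transformants or zero doublings make
the rate undefined and error rather than returning `Inf`. The linear risk
mode errors at probabilities $\ge 1$ and suggests poisson mode. Machine-
readable outputs always carry full precision; rounding exists only in the
human-readable report layer.
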