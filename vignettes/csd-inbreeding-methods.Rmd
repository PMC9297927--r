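---
title: "Models and methods: CSD inbreeding tests and titer-threshold thelytoky"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: CSD inbreeding tests and titer-threshold thelytoky}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdsim)
```

# The biological question

Haplodiploid wasps normally develop as females from fertilized (diploid)
eggs and as males from unfertilized (haploid) eggs. Under complementary sex
determination (CSD), sex is instead read off the allelic state of one
(sl-CSD) or several (ml-CSD) loci: heterozygosity at one or more loci makes
a female, homo- or hemizygosity at all loci makes a male. Inbreeding raises
homozygosity, so under CSD it should produce *diploid males* and
male-biased sex ratios — the classical experimental signature. `csdsim`
implements the computational machinery for such a test: a
genotype-explicit forward simulator of inbreeding pedigrees, exact
enumeration oracles for what inbreeding is expected to do, the brood-level
bookkeeping statistics used on the experimental side, and a titer-threshold
model of endosymbiont (e.g. *Wolbachia*) induced thelytoky that asks
whether egg diploidization and feminization are one step or two.

# The CSD core

A genotype holds one (haploid) or two (diploid, unordered) allele labels at
each of `k` unlinked loci. Three operations define the model:

* `make_gamete()` — Mendelian segregation, one allele per locus chosen
  uniformly, independent across loci (no linkage is modelled);
* `fuse()` — fertilization, producing a canonicalized diploid genotype;
* `determine_sex()` — the CSD rule above, with a switch
  (`csd_enabled = FALSE`) that turns every diploid female, the null
  hypothesis the study species follow.

`expected_proportions()` gives the classical closed forms for brood
composition at fertilization rate $f$, all-locus homozygosity chance $h$,
and inviable-diploid-male fraction $i$: e.g. with viable diploid males the
proportions are $F=(1-h)f$, $M=1-f$, $D=hf$ and the progeny sex ratio is
$\frac{(1-f)+hf}{(1-h)f+(1-f)+hf}$. When all homozygous diploids die, $i$
equals $hf$ if driven from the genotype model, but it is kept a free
parameter for direct formula use.

# Exact pedigree expectations

`homozygous_fraction_pedigree()` computes, per generation of a cross
scheme, the exact expected fraction of fertilized eggs homozygous at all
loci. Every scheme starts from an outcross of a fully heterozygous female
(A/B at each locus) to an unrelated sire (C), the initialization that
maximizes starting heterozygosity; the two presets then follow the two
experimental regimes (mother–son first, or brother–sister only).

Rather than enumerating the full joint genotype space, the implementation
uses an exact symmetry reduction. Per locus, a breeding pair (diploid
mother, haploid sire) falls into one of four relabelling-invariant classes
— mother heterozygous or homozygous, crossed with the sire allele being
carried by the mother or not. The chance that a fertilized egg is
homozygous at that locus is $1/2$, $0$, $1$, $0$ for the four classes, and
the class transitions under mother–son and brother–sister crosses depend
only on the class. Because loci segregate independently, the joint chain
over $k$ loci is lumpable to class *compositions* (at most
$\binom{k+3}{3}$ states), which makes the computation exact and instant up
to $k = 10$. The only cross-locus coupling is the selection rule that the
next mother must be a female, i.e. heterozygous somewhere; that event is a
function of the composition and is applied by global Bayes conditioning,
which is the infinite-brood limit of how the stochastic simulator selects
daughters. The test suite cross-checks this reduction against an
independent brute-force enumeration over explicit genotype pairs for
$k \le 2$.

Two analytic anchors follow. After a mother–son cross under sl-CSD the
expected homozygous fraction is exactly $1/2$ (the mother is A/B, her son
carries A or B), and $1/2$ is also the ceiling across *all* generations of
both presets: any pair state left after conditioning retains a
heterozygous locus, capping the product of per-locus homozygosity
probabilities at $1/2$. With more loci the fraction starts lower
($(1/4)^k$ at a first brother–sister generation) and climbs toward the
same ceiling; at a fixed generation it is strictly decreasing in $k$.
Pedigrees longer than 8 generations are refused with a pointer to the
Monte Carlo simulator, which has no such limit.

# The stochastic simulator

`run_simulation()` repeats single-lineage replicates: one breeding pair per
generation (the experiments mated single females), brood size and
fertilization drawn per brood from the `brood_model()`, each egg fertilized
independently with the drawn proportion (binomial thinning — the simplest
generative reading of "sampled fertilization proportions"), sexes assigned
by the CSD rule, and the next pair drawn uniformly (mother–son: same
mother plus a haploid son; brother–sister: a female and a haploid male from
the same brood). A lineage with no eligible female or male goes extinct
and contributes nothing from that generation on; survivorship is reported
rather than imputed.

Summaries per generation are the operational sex ratio (all males over all
adults) and the diploid sex ratio (diploid males over diploids), each with
a 95% percentile band (2.5/97.5 percentiles across surviving replicates).
With one brood per lineage per generation, the per-replicate and per-brood
variants of these bands coincide, so the per-replicate band is reported.
Reproducibility: the master seed deterministically derives one sub-seed per
replicate, so results are bit-identical across runs and independent of
summary-stage code.

The default parametric brood model uses a negative binomial brood size
(mean 10, dispersion 5 — overdispersed counts typical of parasitoid
rearing data at the lower end of laboratory brood sizes) and a Beta(13, 7)
fertilization distribution (mean 0.65, matching progeny sex ratios of
roughly a third male in outbred broods). An empirical mode resamples
observed `(brood_size, fertilization)` pairs jointly, preserving their
correlation, for users with control-pedigree data.

One property of small broods deserves emphasis. Under sl-CSD after a
mother–son cross, half the fertilized eggs are expected to be diploid
males, yet the chance that a *single* brood contains none at all is
$\mathbb{E}[(1-f/2)^N]$ — about 4–6% at mean brood size 10 under any
negative binomial dispersion. The lower edge of the percentile band for
the diploid sex ratio therefore touches zero at this brood scale, whereas
with the larger broods of a full-scale experiment (20+ diploids per brood)
the band excludes zero and the absence of diploid males becomes decisive
at the single-brood level. This is exactly why the aggregate
zero-diploid-male probability below, not the band, is the right instrument
for small broods.

# Brood statistics and detection power

The experimental bookkeeping lives in `brood_stats`-style helpers:
all-male broods (male but no female adults) are classified and excluded as
putative unmated mothers before any sex-ratio analysis (`exclude_all_male()`
is idempotent and logs what it removed); proportions carry exact
Clopper–Pearson intervals (small brood counts); two-group comparisons use
the conditional exact test on the 2×2 table by default, since the stated
counts are small-to-moderate, with a pooled-proportion normal test as an
option. Emergence proportions divide adult wasps and non-emerged host
pupae by the total of observed host outcomes (wasps + flies + unemerged
pupae); dividing by the recorded host count instead is available behind a
flag, since either denominator is defensible.

The detection-power calculus is the probability of seeing *no* diploid
males among $n$ tested: $(1-d)^n$ for a diploid fraction $d$ among tested
males, multiplicative over independent batches. `power_from_simulation()`
evaluates it under a simulated CSD scenario. Its default pools the
diploid-male fraction across surviving replicates before applying the
testing plan, matching an experiment that samples tested males across many
independent families; the per-replicate alternative (mean over replicates
of the per-lineage product) answers a different question — the evidence a
single family line provides — and with small broods it is dominated by
families that contain no diploid males by chance, which is why it is not
the default.

# Titer-threshold thelytoky model

Relative endosymbiont titer is $2 \times$ (endosymbiont gene quantity) /
(host single-copy gene quantity), the factor 2 correcting for the two host
gene copies per diploid cell; cycle-threshold input uses
$\mathrm{efficiency}^{\Delta C_t}$ with a default efficiency of 2 (perfect
doubling — ratios, not absolute efficiencies, are what the assay reports).

Egg fate is modelled with monotone logistic dose–responses in log titer,
the minimal family containing the "critical titer" story; a sharp
threshold is the infinite-slope limit. One-step: diploidization (threshold
$t_{dip}$) suffices for female development. Two-step: a separate
feminization response ($t_{fem}$); when $t_{fem} > t_{dip}$, intermediate
titers yield diploid males — the diagnostic window. `classify_mechanism()`
therefore returns `two_step_separated` when diploid males appear at
intermediate doses; when none appear it returns the deliberately joint
verdict `one_step_or_coincident`, because titer manipulation cannot
distinguish a one-step mechanism from a two-step mechanism whose two
thresholds coincide. The strength of that conclusion is quantified by
$(1-d)^n$ over the males tested from mixed-sex broods under a stated
separated-two-step alternative; the default $d = 0.5$ is a moderate
alternative (a sharp separated two-step would make essentially all
mixed-brood males diploid, so 0.5 is conservative), and if the resulting
probability exceeds the significance level the verdict is `inconclusive` —
too few males were tested to say anything.

# Synthetic data

The generators exist so that every pipeline stage is testable without any
external data. `generate_inbreeding_dataset()` simulates the whole
experiment genotype-explicitly: families followed along the scheme,
several set-up females per family per generation, unmated females (45%
inbred / 61% control by default, the magnitudes seen in such experiments)
producing all-male broods, controls remated every generation to novel-
allele stock males, and an optional inbreeding-depression knob — a
geometric per-generation survival multiplier on diploid females only, with
dead daughters counted as non-emerged pupae and sexed female in dissected
broods. That single knob reproduces the female-biased dead-wasp signature
of inbreeding depression without modelling its loci; it is illustrative,
not an estimate, since the effect size is not quantified anywhere. Lineage
loss makes sample sizes decline over generations as in real experiments.
What the generator does *not* emulate: host-quality fluctuations between
generations, superparasitism, family random effects beyond lineage
structure, and strain differences — so passing end-to-end tests shows the
pipeline's logic is sound, not that real data will be as well behaved.

`generate_qpcr_dataset()` and `generate_dose_response_dataset()` provide
the titer-side inputs (lognormal spread around a decreasing logistic
dose–titer curve; clutch and host-fly bookkeeping shaped like a published
dose-response table).

# Numerical and design choices

* Diploid allele pairs are stored sorted, so genotype keys are canonical
  and distribution arithmetic never double-counts.
* Enumeration guards: gamete enumeration up to $2^k$ with $k \le 20$;
  pedigree propagation $k \le 10$, 8 generations; beyond that the
  stochastic simulator is the tool.
* Sharp thresholds define $p = 1$ exactly *at* the threshold titer, and
  $p(0) = 0$ always, so a cured mother can only make haploid sons.
* Empty broods (size 0) are legal, flagged, and treated as extinction
  when a next pair is needed; diploid sex ratios are `NA`, not 0, when a
  brood has no diploids, and such broods drop out of diploid-SR bands.
* Percentile bands use `stats::quantile()` defaults (type 7); with
  thousands of replicates the band definition dominates any interpolation
  detail.
* Test-suite problem sizes are chosen to make sampling error a small
  fraction of each tolerance: 60 000 replicates for the
  oracle-equivalence totals (total-variation tolerance 0.01 against
  brood-level clustering noise), 2 000 replicates for band summaries, 500
  seeds for mechanism recovery, 200 synthetic families for the null
  pipeline.

# Known limitations

* Diploid males, though viable by default, are never chosen as sires —
  matching the mate-selection rule that draws haploid males; their
  reproductive value is outside scope.
* No triploids, no recombination/linkage, no overlapping generations, no
  population-level variants of the pedigree (one pair per lineage).
* The titer model treats dose only through the dose-to-titer map; no
  pharmacokinetics.
* The detection-power formula treats tested males as independent draws at
  the replicate- or pool-level diploid fraction; finite-brood sampling
  without replacement would be slightly tighter.
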