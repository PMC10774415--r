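---
title: "Modelling suppression gene drives and genetic sex conversion in the medfly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling suppression gene drives and genetic sex conversion in the medfly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medflydrive)
```

## The biological model

The Mediterranean fruit fly (*Ceratitis capitata*) determines sex through a
cascade that differs in one crucial way from the *Drosophila* textbook
picture: femaleness is an actively maintained state. An XY zygote becomes
male because the Y-linked factor MoY overrides everything else. An XX
zygote becomes female only if two conditions hold simultaneously — the
mother loaded functional *transformer* (*tra*) product into the egg
(maternal provision, which primes the autoregulatory *tra* splicing loop)
and the zygote itself carries at least one functional *tra* allele to keep
the loop running. Losing either condition sends an XX embryo down the male
pathway, and such XX males are viable and fertile. This package treats
conversions as complete: each individual is MALE or FEMALE, and mosaic or
intersex phenotypes that arise in real transgenics from leaky somatic Cas9
expression are deliberately outside the model (the strategy logic being
evaluated assumes germline-restricted nuclease activity).

On top of the sex-determination rules sit CRISPR-Cas9 homing gene drives. A
drive construct sits inside a target gene (disrupting it) and encodes Cas9
plus one or two gRNAs. In the germline of a carrier, each wild-type target
site is cleaved with probability $c$; a cut is repaired by
homology-directed repair with probability $h$, copying the homologous
chromosome's current state — the construct itself at the drive's home locus
("homing", giving the classic hemizygote transmission $T = (1+ch)/2$), or a
resistance allele if one is present. With probability $1-h$ the cut heals
by end joining, producing a resistance allele that abolishes target-gene
function (R2) with probability $r_2$ or preserves it (R1) otherwise. R1
alleles are the central enemy of suppression drives: they are immune to
further cleavage yet keep the target gene working, so selection amplifies
them once the drive has made functional copies rare.

Four drive architectures are modelled, all constructible with
`driveDesign()`:

* **FEMALE_FERTILITY** — homing into a recessive female-fertility gene.
  Homozygous disruption sterilises females; males are unaffected.
* **TRA_HOMING** — homing directly into *tra*. Spreads while converting
  XX carriers lacking functional *tra* into males.
* **SSC** (sterilising sex conversion) — homing into the female-fertility
  gene while a second gRNA cuts *tra* in trans. Daughters of drive mothers
  lose maternal *tra* provision (the ovary itself is mutagenised) and
  develop as fertile males; females that do arise are increasingly likely
  to be sterile at the fertility locus. Because carriers are mostly male,
  R1 alleles at the fertility gene gain little immediate advantage — the
  drive "pre-empts" counterselection.
* **DUAL_FERTILITY** — homing into one female-fertility gene while cutting
  a second in trans.

Two maternal effects are modelled. *Maternal deposition*: Cas9/gRNA carried
in the egg cleaves zygotic wild-type alleles at all targeted loci with
probability $\min(1, k c)$ per allele, with end-joining-only repair (there
is no construct template in the embryo, so deposition can never home).
*Maternal provision*: in `TRA`-targeting designs, each functional *tra*
allele of a drive-carrying mother is disrupted in the ovary with
probability $c$, independently per offspring; provision fails when no
functional allele escapes. The per-offspring draw reflects nurse-cell
mosaicism — different eggs of the same female can receive different
provision. (In the implementation the per-allele Bernoullis are collapsed
into a single draw with loss probability $c^f$ for $f$ functional alleles,
which is distributionally identical.)

Cas9 activity is conditional on carrying the construct: a wild-type
germline contains no nuclease, so non-carriers transmit strictly
Mendelian. The same cleavage rate $c$ applies at the home and trans-target
loci — the architectures share a single Cas9 whose activity is the swept
quantity.

## The population simulation

`runSimulation()` iterates discrete, non-overlapping generations of a
constant-size population (default $N = 1000$), initialised as 500 wild-type
females, 250 wild-type males and 250 drive-hemizygous males — a 12.5%
starting allele frequency. Every generation, exactly $N$ offspring are
produced; each draws a mother uniformly from the fertile females and a
father uniformly from the fertile males, with replacement. This is full
density compensation: population size never shrinks while any fertile pair
exists, so suppression manifests purely as collapse of a reproductive
class, and *extinction* is recorded at the first generation whose cohort
contains no fertile female (or no fertile male). A collapse observed at
exactly the final generation of the horizon counts as extinct — the cohort
is irreversibly lost even though later generations are not simulated.

Each offspring is assembled in a fixed order: one gamete per parent
(germline cleavage/repair resolved fresh per meiosis), karyotype from the
paternal sex chromosome, maternal deposition applied to the zygote, the
maternal provision draw, then sex and fertility from the genetics rules.
Deposition precedes sex determination, so embryonic *tra* disruption can
itself convert an XX zygote.

Design choices worth making explicit, since the underlying biology does not
dictate them:

* Mating is random with replacement (polygyny and polyandry allowed, no
  mate limitation); there are no fitness costs of carrying the construct
  (none were measurable experimentally), no density model, no age
  structure, no migration.
* When both alleles at a locus are cut in the same meiosis, they resolve in
  uniformly random order and an unresolved cut homolog cannot serve as an
  HDR template, so the first cut always end-joins; the second can copy the
  first's repair product. This makes "homing of an R allele" well defined
  without a template paradox.
* The mean duration to extinction averages over extinct replicates only;
  `summarizeReplicates(time = "censored")` exposes the alternative that
  counts surviving runs at the horizon.

## Randomness and reproducibility

Every run is driven by a single integer seed; `runSimulation()` restores
the caller's RNG state afterwards. Replicates and sweeps derive one
sub-seed per run from a master seed (`replicateSeeds()`), so any replicate
can be reproduced in isolation and a sweep is bitwise reproducible under a
fixed master seed regardless of execution order.

## Parameter sweeps and the extinction surface

`runSweep()` executes a grid over any subset of $\{c, r_2, h\}$ with a
fixed number of replicates per point. Two presets ship, each a 6 × 6 grid
with 10 replicates (360 simulations): cleavage × R2 fraction at fixed
$h = 0.95$ over 20 generations (extinction likelihood), and cleavage × HDR
at fixed $r_2 = 0.99$ (duration to extinction). The grid resolution and
replicate split are package choices; only their product is externally
anchored.

The continuous extinction surface is estimated with local polynomial
regression (`smoothExtinctionSurface()`, backed by `stats::loess`):
tricube distance weights on standardised axes, defaults span 0.75 and
degree 2 — conventional smoother settings, since only the method class is
externally fixed. Fitted extinction fractions are clamped to $[0, 1]$
after fitting. A local fit of degree $d$ needs at least $\binom{d+2}{2}$
points in every window; the function refuses grids/spans that violate
this. Local linear and quadratic fits reproduce constant and linear
responses exactly (to numerical precision), which the test suite uses as a
correctness anchor.

## Cross statistics and the synthetic generator

Laboratory homing assays cross a transgenic hemizygote to a wild-type or
eye-mutant mate and score progeny for the fluorescent marker, eye colour
and (for *tra*-targeting constructs) sex. `cross_stats` mirrors that
arithmetic:

* `transmissionRate()` — marker-positive proportion with a Wilson score
  interval (better behaved near 0/1 at these sample sizes than the Wald
  interval).
* `chisqGof()` — one-degree-of-freedom goodness of fit against a binary
  expectation, no continuity correction.
* `inferCleavageHdr()` — inverts $T = (1+ch)/2$ together with the mutant
  fraction among non-carriers $m = c(1-h)/(1-ch)$ to give
  $c = (2T-1) + m(2-2T)$ and $h = (2T-1)/c$. The inversion assumes every
  end-joining repair disrupts the scored phenotype gene ($r_2 = 1$ at that
  locus); in-frame repairs that preserve pigmentation would bias $c$
  downward. $h$ is reported as indeterminate when $c = 0$.
* `overallFraction()` — law-of-total-probability composition of
  conditional phenotype fractions across the marker split.
* Replicate handling: statistics are reported per replicate, as the mean
  of replicate rates, and on pooled counts, labelled — published tables
  mix both conventions.

`simulateCross()` generates synthetic progeny tables under the full
germline model: the construct's home locus doubles as the scored recessive
visible marker (as with a drive inserted in an eye-pigmentation gene), an
eye-mutant mate contributes disrupted uncleavable alleles, and maternal
deposition applies when the transgenic parent is the mother. Two
idealisations matter for interpreting tests built on it: mosaic eye
phenotypes are never generated (no somatic-expression model — though the
`MOSAIC` category remains readable in real-style tables), and intersex
progeny do not exist. Note that with $k > 0$, deposition in a
transgenic-mother cross converts maternally transmitted wild-type alleles
in the embryo and inflates the apparent mutant fraction beyond the
germline value; fixtures meant to isolate germline repair therefore set
$k = 0$, and the fixture manifest flags which files satisfy the inference
assumptions (`inference_valid`). Passing tests on these synthetic tables
demonstrate internal consistency of the model and estimators, not the
behaviour of real crosses — real data add somatic mosaicism, viability
differences and genotyping error that the generator deliberately omits.

## Numerical anchors and test problem sizes

The exact enumeration `gameteDistribution()` is the package's own oracle
for the stochastic germline: it enumerates all cleavage/repair outcomes
(both resolution orders of a double cut at weight 1/2) and must sum to 1
within 1e-12. The test suite verifies the stochastic sampler against it at
$n = 10^5$ gametes per parameter draw (3 binomial standard errors), checks
the $(1+ch)/2$ transmission law on a parameter grid, and runs the
strategy-level comparisons at $N = 1000$ with 100 replicates; grid-level
plumbing tests use reduced populations ($N = 60$–400) so the whole suite
stays fast while the acceptance-level checks keep the full release
scenario. The algebraic inversion round-trip ($(c,h) \to (T,m) \to (c,h)$)
is exact to 1e-12.

## What the model shows, and its limits

Under its assumptions, the model reproduces the core comparative claim
that motivates the SSC architecture: at half-functional resistance
($r_2 = 0.5$) neither a plain female-fertility drive nor SSC collapses a
population of 1000 within 20 generations, but as $r_2$ rises SSC begins to
extinguish populations at substantially lower $r_2$ than the
female-fertility drive (in the shipped tests SSC reaches high extinction
fractions at $r_2 \approx 0.95$–$0.99$ where the fertility drive still
fails almost always), and an ideal SSC ($c = h = r_2 = 1$) collapses
essentially every replicate in under ten generations. These are
statements about an idealised constant-size, panmictic population with
complete sex conversion; spatial structure, inbreeding avoidance, partial
conversion, fitness costs and density-dependent regulation could each
shift the quantitative picture and are outside the package's scope.
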