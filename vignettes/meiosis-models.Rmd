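---
title: "Models of diploid and tetraploid meiosis in polymeiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of diploid and tetraploid meiosis in polymeiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymeiosis)
set.seed(1)
```

# The problem

Diploid inheritance is served by a mature ecosystem of linkage-mapping and
QTL software, but tetraploid crops (potato, rose, leek, alfalfa, ...)
inherit chromosomes in sets of four, with phenomena that have no diploid
counterpart: quadrivalent pairing, partial preferential pairing between
subgenomes, and double reduction. Developing and testing statistical
methods for such species requires simulated populations whose meiosis
follows an explicit, controllable model. `polymeiosis` is a forward
simulator of meiosis for diploids and tetraploids: founder chromosomes are
labelled with unique founder alleles, meiosis recombines them into mosaic
gametes, pedigrees are gene-dropped, and marker genotypes and allele
dosages are realized on a genetic map. A test mode accumulates gamete
statistics over replicated meioses and compares them with closed-form
expectations.

# The meiosis model

Each chromosome set is processed independently through four steps.

## Step 1 — pairing configuration

In diploids the two homologs always form a bivalent. In tetraploids,
pairing is initiated independently at the two telomeres. With preferential
pairing fraction $p \in [0,1]$, the matching pairing (each chromosome with
its true homolog) has probability $p + (1-p)/3$ and each of the two other
pairings has probability $(1-p)/3$; $p = 0$ is an autotetraploid with fully
random pairing, $p = 1$ an allotetraploid with strict subgenome pairing.
Two bivalents form when both telomeres pair identically, so

$$P_{\text{bivalents}} = \left(p + \tfrac{1-p}{3}\right)^2 +
  2\left(\tfrac{1-p}{3}\right)^2,$$

and the quadrivalent fraction is its complement
(`expected_quadrivalent_fraction()`): $2/3$ at $p = 0$, $0.292$ at
$p = 0.75$, $0$ at $p = 1$. Alternatively the bivalent/quadrivalent ratio
can be forced per chromosome; pairing is then performed within the drawn
configuration (a single telomere-pairing draw for two bivalents; for a
quadrivalent, the bottom pairing is drawn from the preferential
distribution renormalized over the two pairings different from the top).

A quadrivalent is cross-type (four branches, two pairing the chromosome
tops and two the bottoms, meeting at a chromosome exchange point) or, with
configurable probability, parallel-type (all four chromosomes paired along
their whole length). Univalents, trivalents and other configurations that
produce unbalanced gametes are outside the model's scope.

## Step 2 — chiasmata

Chiasma positions along a paired region follow a renewal process read from
one telomere to the other, with mean inter-chiasma distance 0.5 Morgan in
bivalents and cross-type branches (two chiasmata per Morgan per bivalent)
and 0.25 Morgan in parallel quadrivalents (four per Morgan, preserving the
per-chromatid crossover density). Without chiasma interference the gaps
are exponential and the first position is a single exponential draw from
the telomere; the count over a region is then Poisson and the Haldane map
function $r = (1 - e^{-2d})/2$ applies in bivalents. With interference the
gaps follow a gamma distribution with shape 2.63 and rate $2.63/0.5$
(mean 0.5 Morgan); because a gamma renewal process has no memoryless
entry point, the process is burnt in from 10 Morgan before the region
(first virtual chiasma exponential, then gamma gaps), which is about 20
renewal means and stationary to numerical precision. The resulting
bivalent recombination closely follows the Kosambi map function
$r = \tanh(2d)/2$. The exact asymptote of the gamma model, computed from
the stationary renewal equation, is slightly above Kosambi in the
mid-range (at 20 cM, 0.19077 against 0.19000), so test tolerances for
interference runs are never tighter than 0.002.

Chromatid involvement is uniform: each chiasma involves one of the two
chromatids currently copying each of the two paired chromosome templates,
chosen uniformly and independently of all other chiasmata (no chromatid
interference). Bookkeeping follows the physics: template DNA stays on its
chromosome's axis, recombinant molecules are paths across axes, and a
chiasma at $x$ swaps the distal tails of the two chosen molecules and
exchanges their axes from $x$ onward. A molecule is attached to the
centromere of the axis it occupies at the centromere position. This
detail matters: choosing chromatids by centromere attachment instead of
by axis occupancy makes some exchanges invisible (they swap identical
founder material) and visibly deflates recombination below Haldane.
Zero-chiasma bivalents are allowed; no obligate chiasma is enforced.

## The cross-type exchange point

The position where the top and bottom branches of a cross-type
quadrivalent meet varies between meioses. It is realized in two stages:

1. Pairing fronts advance inward from the two chromosome ends as renewal
   walks with the inter-chiasma step distribution (one walk per branch,
   superposed per side). The side whose front is nearer its own telomere
   advances next (the first mover is random), and pairing ends when the
   two sides' pending steps would cross each other. The exchange point is
   the midpoint of the final gap between the fronts. This yields a
   unimodal distribution with its mode at the chromosome centre (mean
   50 cM, SD about 13 cM on a 100 cM chromosome).
2. Each branch then forms chiasmata by the standard renewal process from
   its own telomere, truncated at the exchange point, so every position
   recombines in exactly one side and the chiasma density is uniform.

Single-stage constructions that race the realized chiasmata themselves and
stop at a frontier collision were evaluated and rejected: conditioning the
acceptance of a chiasma on fronts built from the accepted chiasmata biases
the density near the centre (up to twofold with accepted-front races,
half with candidate-crossing stops), pushing recombination outside the
bivalent-parallel bracket. No experimental evidence distinguishes uniform
from unimodal exchange-point distributions; reference tables derived from
a specific exchange-point model are therefore treated as indicative, not
as exact targets.

## Steps 3 and 4 — the meiotic divisions

In the first division, a bivalent sends one centromere to each pole and
two bivalents split independently. In a quadrivalent the four centromeres
are partitioned into two pairs uniformly over the three possible
partitions. For cross-type quadrivalents an alternative model
(`paired_centromeres`) forces the two chromosomes paired on the centromere
side of the exchange point to opposite poles, with the two compatible
partitions equally likely. In the second division every centromere splits
and its two chromatids go to the two daughter gametes with independent
random orientation. Each tetraploid gamete therefore carries two
chromatids whose centromeres come from different parental chromosomes.

## Double reduction

Double reduction (DR) — a gamete receiving two copies of part of the same
parental homolog — arises only through quadrivalents. At the centromere it
is structurally zero (the two gamete chromatids always carry different
centromere material). Far from the centromere, in a parallel quadrivalent
a chromatid's allele is effectively a uniform draw over the eight
chromatids, of which only one is its sister, so DR approaches $1/7$
independently of chromosome length. For cross-type quadrivalents the same
argument does not apply, because beyond the exchange point a molecule can
only wander within its bottom-pairing pair. Conditioning on the uniform
pole partition gives the exact cross-type limit

$$\mathrm{DR}_\infty = \tfrac13\left(\tfrac13\cdot\tfrac13 +
  \tfrac12\cdot\tfrac13 + \tfrac12\cdot\tfrac13\right)\cdot 3
  = \tfrac{4}{27} \approx 0.148,$$

(top-pairing pole partner: probability $1/3$ of sharing the axis at the
exchange point, then $1/3$ of sharing an axis far away; either other
partner: probability $1/2$ of landing in the same bottom pair, then
$1/3$). The difference from $1/7 \approx 0.143$ is half a percentage
point, indistinguishable in published simulation figures; the test suite
asserts $1/7$ for parallel quadrivalents and $4/27$ for cross-type.

# Populations and genotypes

Founders receive unique founder alleles per homolog (founder $i$ of ploidy
$P$ carries $iP, \dots, iP+P-1$), so every chromosome in the population is
a mosaic of founder segments — a `haplostruct`, an ordered list of
(start, founder allele) segments under the half-open convention
$[\text{start}, \text{next})$: a locus exactly at a crossover position
takes the distal (recombined) allele, a measure-zero tie resolved by a
fixed rule for determinism. Offspring are produced by sampling one of the
four gametes from one meiosis per parent; the maternal chromatids fill
homolog slots $1..P/2$ in order, the paternal the rest. Selfing runs two
independent meioses.

Subgenome identity for preferential pairing in later generations is
positional: slots 1-2 are treated as one subgenome and slots 3-4 as the
other, regardless of recombination history. After quadrivalent
recombination a chromatid can be a subgenome mosaic and no published model
specifies how preferential pairing should then behave; the positional
convention is a documented choice, not a biological claim, and matters
only when simulating multi-generation pedigrees with $p > 0$.

Observable genotypes are realized by assigning an observable allele
(nucleotide, fragment length, dominant/recessive symbol, ...) to every
founder allele at every mapped locus; the dosage of a per-locus reference
allele (by convention the observed allele of founder allele 0) is counted
per individual. Genotypes are complete and error-free; scoring errors and
missing data are deliberately left to downstream post-processing, and
phenotype models are out of scope.

# The test mode

`run_test_meioses()` replays `n` meioses of a single founder, samples one
gamete per meiosis, and records the founder allele of each gamete
chromatid at a set of test loci, together with the realized pairing
configuration and exchange point. From these,
`estimate_recombination()` scores a chromatid as recombinant when its
founder alleles differ between two loci (a double crossover that restores
the allele scores non-recombinant, matching the observational definition
underlying map functions), and `estimate_double_reduction()` scores a
gamete as DR when its two chromatids agree at the locus.
`summarize_gamete_stats()` tabulates estimates, binomial standard errors,
closed-form references (map functions for bivalent-only runs, the pairing
formula for configuration frequencies) and z-scores.

The default problem sizes are 10^5 meioses for the validation runs in the
acceptance suite and 10^3-10^4 for unit-level property checks; standard
errors scale as $\sqrt{r(1-r)/n}$ and all tolerances are 3 SE unless a
documented model bias requires a floor (interference runs, above). All
randomness flows through R's global generator, seeded once per run, so a
logged seed reproduces outputs byte-identically.

# What the simulator does and does not emulate

The generator reproduces: tetrasomic and disomic inheritance and the
continuum between them, bivalent/quadrivalent ratios driven by
preferential pairing or forced, chiasma interference, recombination above
50% in quadrivalents, double reduction rising from zero at the centromere
to its asymptote, and multi-founder mosaic chromatids (three founders in
cross-type, four in parallel quadrivalents).

It does not emulate: univalents/trivalents or unbalanced gametes,
chromatid interference, position-dependent recombination rates along a
chromosome, obligate chiasmata, sequence-level or physical (bp)
coordinates, genotyping error or missingness, viability selection, or
phenotypes. Ploidies other than 2 and 4 are rejected. Passing tests
therefore validate the model's internal consistency and its agreement with
closed-form theory — not the fidelity of any particular organism's
meiosis, where empirical deviations from these idealized assumptions are
expected.

# Known limitations

* The exchange-point mechanism is one concrete realization of a process
  that is not experimentally characterized; statistics that depend on it
  (cross-type recombination at long intervals, the exact cross-type DR
  limit) are model-dependent.
* The gamma-interference model reproduces Kosambi only approximately; its
  exact asymptote deviates by up to about $10^{-3}$ in the mid-range.
* Preferential pairing of subgenome-mosaic chromatids uses the positional
  slot convention described above.
* Very dense maps are supported (chiasma positions are continuous and
  exact), but runtime grows linearly in meioses, chromosomes and
  chiasmata.
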