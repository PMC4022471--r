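---
title: "The genetic model behind tetradrive: spore killers in ordered asci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The genetic model behind tetradrive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradrive)
```

# The biological problem

Spore killers are the fungal form of meiotic drive: in a cross between a
killer-carrying and a sensitive strain, ascospores that do not inherit the
killer element die inside the ascus, so the killer is transmitted to far more
than the Mendelian half of the surviving progeny. In *Podospora anserina* the
Spok genes behave as single-locus toxin–antitoxin elements: one allele
carries both a *distorter* (killing) activity directed at all spores of the
ascus and a *responder* (protective) activity that rescues the spores
carrying it. `tetradrive` implements this genetics as a simulator and an
exact calculator, together with the estimators used to locate and quantify
such elements from ascus counts and progeny genotypes.

# Meiosis in ordered asci

One meiosis produces four products arranged as two first-division (MI) poles
of two products each; a post-meiotic mitosis duplicates every product, giving
eight nuclei. For a heterozygous locus the configuration of parental origins
across the four products is fully described by one of six *origin vectors*:

* **FDS** (first-division segregation, probability $1-s$): both products of a
  pole carry the same parental allele. No crossover occurred between the
  locus and its centromere.
* **SDS** (second-division segregation, probability $s$): each pole carries
  one allele of each parent, the chromatid-within-pole assignment being
  uniform at random. $s$ grows with locus–centromere distance up to the
  asymptote $2/3$.

Packaging then decides what a spore is:

* `binucleate_tetrad` (*P. anserina*): four spores, each holding copies of
  the two distinct products of one MI pole. An FDS locus therefore yields
  homokaryotic spores and an SDS locus four heterokaryotic spores — the
  geometric fact that makes killed-ascus counts read out $s$ directly.
* `uninucleate_octad` (*Sordaria macrospora*): eight single-nucleus spores;
  heterokaryotic rescue is impossible, so a heterozygous killer always kills
  exactly four of eight spores, whatever $s$ is.

## Two linkage modes

The default, *phenomenological* mode takes each locus's SDS probability
`sds_prob` as given — this is the natural parameterisation when the data are
ascus counts. Each locus draws its FDS/SDS pattern independently with its own
$s$; correlation of parental origins between same-chromosome loci is imposed
by a Markov chain over the six origin vectors: given the previous locus's
vector, the new vector is drawn within its (already decided) FDS/SDS class
with weight $r^m (1-r)^{4-m}$, where $m$ counts per-chromatid origin
mismatches and $r$ is the recombination fraction between the adjacent loci.
This construction keeps every marginal $s$ exact, reduces to full
independence at $r = 0.5$, and couples origins maximally at $r = 0$ (ties at
$r = 0$ resolve uniformly among minimal-mismatch vectors). The joint pattern
of two loci that are both SDS is not constrained by ascus phenotypes; the
chain above is our documented, reproducible choice.

The *mechanistic* mode instead places crossovers on an interval map: a
Poisson number with mean $2\Delta$ per interval of $\Delta$ Morgans, each
crossover exchanging the distal segments of one chromatid of each pole
(chosen uniformly, no chromatid or crossover interference). SDS frequency
then emerges and follows the closed form
$s(x) = \tfrac{2}{3}\bigl(1 - e^{-3x}\bigr)$ at map length $x$, which the
test suite verifies at $x \in \{0.05, 0.5, 2\}$. Adjacent-locus
recombination follows Haldane's function. The two modes agree exactly when
`sds_prob` is set to $s(x)$ (also a tested invariant).

# The killing rule

The zygote's allele content defines the *active distorters* and switches
trans-activated responders on or off. A spore survives iff every active
distorter is in the union of the effective responder coverages of the
alleles it carries (over both nuclei and all loci); one resistant nucleus
rescues the whole binucleate spore. Killing is spore-autonomous — the toxin
is assumed to reach every spore of the ascus — and all-or-none by default.
An optional per-distorter `killing_efficiency` below 1 lets an unprotected
spore escape independently with the complementary probability; this is the
only mechanism that can produce 3- or 1-spored asci, classes the reference
system never shows but which the class tables represent anyway.

Three structural consequences follow from the rule and are asserted as
properties in the tests: homozygous distorters are silent (every spore
carries them); every survivor's coverage is a superset of the active
distorters; and a heterozygous distorter covered by the complementary
haplotype's killer is *masked* — it changes no class frequency.

## Resistance epistasis of the reference alleles

The reference library encodes the observed asymmetric resistance as two
coverage families: Spok1-type responders cover both families, Spok2-type
responders cover only the Spok2 family (which includes the tagged,
kinase-site-mutant and heterologous killers). Trans-activated responders
(N-terminally tagged Spok2, the kinase-site double mutant, and the
heterologous killer) protect only when a wild-type Spok2 copy is present
anywhere in the zygote — crossed to a deletion strain they empty every
ascus; crossed to a wild-type-Spok2 carrier every spore survives. We model
*any* declared activator allele as sufficient, since only the wild-type gene
was ever tested as activator.

# Exact enumeration as the simulator's oracle

`enumerate_cross()` sums over all origin-vector assignments of the
heterozygous loci (at most $6^3$ configurations; the limit of three
segregating loci is enforced), weighting each by the same chain law the
simulator samples from, with transition matrices composed through
intervening homozygous loci. Killing and pigmentation are applied
deterministically per configuration (integrating the binomial survival law
when an efficiency is fractional). Because simulator and enumerator share
one joint law, agreement of simulated class frequencies with the exact
probabilities within binomial noise is a sharp correctness check, run over
the whole cross registry in the test suite.

# Estimators

* **SDS frequency.** In a cross where exactly one unmasked killer
  segregates, killed (2-spored) asci are the FDS asci and intact 4-spored
  asci the SDS ones, so $\hat s$ is the 4-spored fraction. Confidence
  intervals are Clopper–Pearson: tetrad experiments often count tens of
  asci, where Wald intervals misbehave. `estimate_sds()` refuses crosses
  where the requested locus is homozygous or masked, rather than returning a
  number that reads as a segregation frequency but measures nothing. The
  conversion $d = s/2 \times 100$ cM is standard tetrad mapping, reported as
  a convenience.
* **Transmission scan.** Per marker, a two-sided exact binomial test of the
  survivor transmission fraction against 0.5, Benjamini–Hochberg adjustment
  across markers at level 0.05, and the longest run of consecutive
  significant markers flagged as the biased region. The original analysis
  was visual; the adjustment is our addition for a defensible automatic
  call.
* **Goodness of fit.** Chi-square with pooling of classes below expected
  count 5, or an exact multinomial tail for small totals; calibration and
  power are checked in the tests by simulation.

# The synthetic-data generator

The generator modules double as the study-condition fixtures: strain
haplotypes over the three reference loci (killer locus at $s = 0.10$ near
its centromere; second killer at $s = 0.60$, unlinked for practical purposes
at $r = 0.5$; pigment locus at $s = 0.01$), the full cross registry with its
documented outcomes, and progeny marker matrices. `generate_marker_dataset()`
samples per ascus one surviving spore homokaryotic at the driver (the
progeny a killed ascus yields), resolving loci at which that spore is
heterokaryotic to one nucleus uniformly — a spore homokaryotic at *every*
marker would be vanishingly rare once ten markers segregate, and genotyping
follows one nuclear haplotype. The synthetic scan map places ten markers
along one chromosome with SDS values from the mapping function and
adjacent-pair recombination from Haldane's function, the driver collocated
with the second, centromere-proximal marker; 50 progeny mirror the original
genotyping panel.

What the generator does *not* emulate: rare 5- or 3-spored asci of real
rosettes, ascus-to-ascus killing-efficiency variation, fertility differences
between crosses, segmental variation beyond the declared loci, and the
uncharacterised third killer (strain Y; its registry entries are stubs).
Passing tests therefore validate the rule system and the estimators under
idealised Mendelian noise, not the full messiness of rosette scoring.

# Numerical and design choices

* Percentages use **all asci, including empty ones**, as denominator; raw
  counts are always retained so any convention can be recomputed.
* Ascus spore order carries no information (rosettes are scored, not ordered
  octads), so classes are unordered counts.
* The backcross simulator implements selection literally: meioses are
  redrawn until the driver segregates at the first division, then one
  chromatid of the driver-carrying pole continues the lineage; SDS
  (heterokaryotic) survivors are excluded as in the original selection for
  killed asci. Unselected chromosomes use a random chromatid, and unlisted
  genome is summarised by the closed form $(1/2)^{g+1}$. Segment lengths are
  reported in map units; a kb conversion needs a user-supplied scale, and a
  single observed 70-kb end segment is one realisation, not a target.
* One selected survivor per generation is assumed (the screening depth per
  generation was not recorded).
* The *Sordaria* transgene insertion site has unknown centromere linkage;
  its SDS is set to 0.5, which the octad phenotype cannot feel (uninucleate
  spores cannot be rescued).
* The C-terminally tagged responder-only constructs are encoded in the
  backgrounds that make their documented crosses reproducible (see
  limitations).
* Simulation sizes in tests: 10,000 asci for the headline percentages
  (binomial SE ≤ 0.5 points), 2,500–3,000 for oracle-equivalence sweeps, 200
  replicates for coverage and scan-localisation properties — large enough
  for 3-SE checks to be sharp, small enough to keep the suite fast.

# Known limitations

* The claim that the C-tagged Spok1-GFP construct yields 100% 4-spored asci
  against *every* tester strain cannot be reproduced by any spore-autonomous
  rule: against a Spok1 carrier, spores carrying neither the transgene nor
  Spok1 would die. The registry therefore encodes the reproducible crosses
  (against the recurrent parent and deletion strains); the discrepancy most
  likely reflects reduced protein levels rather than rule-like genetics.
* The Spok-free strains crossed to a Spok2 carrier are expected at 40%
  killed asci by the model (SDS 0.60); the published table prints a round
  50% from small samples. The registry stores the model expectation.
* Killer–killer interactions beyond coverage (the "complex interaction" of
  the uncharacterised third killer) are not modelled.
* No fitness or population dynamics: the package stops at the ascus.

# Reproducing the reference numbers

Every quantitative claim above is recomputed by `tests/testthat/` and by
`scripts/acceptance.R` (see the README); the vignette intentionally states
no number that those do not compute.
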