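---
title: "Simulating pedigrees, genomes and kinship with pedforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pedigrees, genomes and kinship with pedforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedforge)
```

## The pedigree model

A pedigree is a directed acyclic graph: nodes are individuals, a
directed edge runs from parent to child and represents one genetic
transmission (one meiosis). Acyclicity encodes the biological fact
that nobody is their own ancestor; every individual has at most two
parents, and co-parents of known sex must be complementary (one XX,
one XY — sex here is gametic role only, sex chromosomes are not
simulated). Three file formats are supported: a two-column parent/child
edge list (`.nx`), the six-column PLINK `.ped`/`.fam` layout
(`FID IID P1 P2 Sex Phenotype`, missing parent `0`, sex `1` = XY,
`2` = XX, `0` = unknown), and a generation-ordered four-column layout
(`Gen IID P1 P2`) consumed by forward genetic simulators that need
founders and descendants listed in creation order.

Two founder classes matter for genome simulation. *Explicit founders*
have no recorded parents. An individual with exactly one recorded
parent implies a missing co-parent, synthesized as an *implicit
founder* (reserved id prefix `IF_`): implicit founders receive genomes
so that transmission is well defined, but they are withheld from VCF
output, mirroring the situation in real incomplete pedigrees where the
unrecorded parent was never genotyped.

### Generation ticks

Generation ticks are inferred from structure alone. Ticks are first
propagated in topological order as `tick(child) = 1 +
max(tick(parents))`; founders with children are then placed one tick
below their earliest child (a spouse marrying into generation three
belongs at generation two, not at the root), and each connected
component is shifted so its minimum tick is 1. The max-over-parents
rule is a deliberate choice: a shortest-path assignment and the
requirement that a child's generation follow *every* parent's cannot
both hold on consanguineous loops, and we take the latter as binding
because transmission order — parents before children — is what the
gene-drop engine needs. On loop-free pedigrees the two rules coincide.
Re-running the assignment on its own output changes nothing.

## Sibship-size model

The structure simulator grows a family forward from one or more
founder couples. For a couple reproducing under schedule row $g$ the
number of children is

$$ n \sim \max(0,\ \mathrm{round}(\mathcal{N}(\mu_g, \sigma_g^2))) $$

Rounding to the nearest integer and truncating below zero is our
discretization choice for turning a continuous sibship-size
distribution into child counts; it preserves the mean to within about
1.5% for the parameter ranges of the packaged census schedule and
slightly shrinks the standard deviation, and
`discretized_sibship_moments()` computes the exact transformed moments
by numerical integration so simulations can be checked against their
true target rather than against the raw normal parameters. Zero-child
draws are retained in the recorded sibship sizes (a childless couple
is still a couple), which is why summaries count them even though a
childless spouse never enters the graph.

Every child of a non-final generation is paired with a newly created,
unrelated founder spouse of complementary sex and reproduces exactly
once under the next schedule row; the sex of each child and of the
first member of each couple is a fair Bernoulli draw, with the partner
assigned the complement. Monogamy plus universal reproduction makes
the expected number of generation-$k{+}1$ sibships equal the expected
number of generation-$k$ children, the bookkeeping that the census
replication checks. The model deliberately omits assortative mating,
remarriage, mortality and age structure; half-relationships enter only
through the misattributed-paternity simulator.

The packaged schedule (census years 1850, 1880, 1910, 1940, 1970)
carries means 3.31, 3.02, 2.72, 2.35, 2.30 and standard deviations
2.13, 1.95, 1.85, 1.70, 1.43 children per couple. Census years are
labels; row order alone defines generation order.

## Misattributed paternity

Given a pedigree and profiles, each eligible child (two recorded
parents, one XY) independently triggers a MAP event with probability
`p_map`. With probability `p_within` the replacement father is drawn
uniformly from the existing fathers at the replaced father's
generation tick — excluding the replaced father and any candidate
whose adoption would create a cycle — and otherwise, or when no
candidate exists, a new XY individual is created at that tick. Mother
edges are never touched, only one event per child per run is possible,
and every rewiring is followed by a full validity check. The cycle
exclusion is our addition: it is not part of the published description
of the procedure, but acyclicity is an invariant of the data
structure, so candidates that are descendants of the child are
excluded.

## Relationship metrics

For a pair $(a, b)$ with at least one common ancestor:

* **MD (meiotic distance)** — for direct (ancestor–descendant) pairs,
  the shortest directed path length; otherwise the minimum over common
  ancestors of the two distances summed.
* **GDD (generation depth difference)** — for direct pairs the same
  path length; otherwise the absolute difference of the two depths at
  the minimizing ancestor.
* **GRT (type)** — `direct`, else `full` when two distinct most recent
  common ancestors (a couple) achieve the minimal distance, `half`
  when one does, `NA` when the pair shares no ancestor (spouses,
  in-laws: label "unrelated").

Counting *minimal-distance common ancestors* rather than raw shortest
paths is deliberate: path counting would double-count through every
monogamous couple. On inbred pedigrees additional ancestors at the
minimal distance are surfaced in an `n_mrca` diagnostic column but do
not change the label. Labels follow standard kinship nomenclature:
writing $d_1 \le d_2$ for the two depths at the minimizing ancestor
(so $MD = d_1 + d_2$, $GDD = d_2 - d_1$), $d_1 = 1$ gives siblings
($GDD = 0$) or (grand-)avuncular pairs, and $d_1 \ge 2$ gives cousins
of degree $d_1 - 1$, $GDD$ times removed, with a `half-` prefix for
single-ancestor variants.

Expected kinship uses Wright's path counting with non-inbred common
ancestors: $(1/2)^{MD+1}$ for direct and half relationships,
$(1/2)^{MD}$ for full ones, zero for unrelated pairs. No $(1+F)$
correction is applied for inbred ancestors — a documented limitation,
with the `n_mrca` column as the flag for affected pairs.

## Gene-drop engine

Genomes live on a single abstract contig of length $L$ with 0-based
internal coordinates (1-based in VCF). A haplotype is the sparse
sorted set of positions carrying a derived allele; under the
infinite-sites approximation used throughout (collisions redrawn), a
position identifies a mutation event, so no separate allele id is
needed. One meiosis draws $\mathrm{Poisson}(rL)$ crossovers at
uniform positions, starts on a fair-coin haplotype and returns the
alternating mosaic; $\mathrm{Poisson}(\mu L)$ new mutations are added
at uniform unoccupied positions. There is no crossover interference
and both maps are uniform — the model exposes scalar rates only.
Defaults are $\mu = 10^{-8}$ and $r = 10^{-7}$ per bp per generation.

Transmission proceeds in ascending generation-tick order, each
non-founder receiving one gamete per parent, so parents are always
realized before their children; with $\mu = 0$ this makes every child
allele traceable to a parent, a property the test suite checks
exactly. VCF output is phased VCF 4.2 with synthetic `A`/`T`
REF/ALT states, restricted to sites segregating among the written
samples, and excludes implicit founders.

Founder genomes come from three sources: a user VCF with random
assignment (uniform, without replacement), a user VCF with an explicit
founder-to-sample mapping file, or the built-in neutral Wright–Fisher
burn-in — a randomly mating diploid population of size $N_e$ run for
$10 N_e$ generations (long enough to approach mutation–drift
equilibrium from a monomorphic start) at the configured rates, from
which $n \le N_e$ individuals are sampled. Implicit founders default
to fresh draws from the founder pool with replacement; how the
original pipeline seeds unrecorded parents is not documented, and
drawing from the same pool keeps their allele frequencies matched to
the explicit founders.

## Kinship estimation and validation

From dosages $x \in \{0,1,2\}$ over $S$ segregating sites, the
allele-matching proportion of a pair is
$M_{ij} = \frac{1}{S} \sum_s [x_{is} x_{js} + (2-x_{is})(2-x_{js})]/4$
and the beta estimator rescales it as
$\hat\beta_{ij} = (M_{ij} - \bar M)/(1 - \bar M)$ with $\bar M$ the
mean matching over all distinct pairs of a reference set. Because all
sites enter with the same weight, averaging $M$ over loci and the
ratio-of-sums form coincide here. The reference set is a documented
parameter: `founders` (the default in the validation loop) anchors the
zero point to the explicit-founder pairs — the generation on which
path-counting expectations are defined, so parent–child pairs from
unrelated founders are expected at 0.25 — while `all` uses every
released individual, which compresses estimates downward by the mean
relatedness of the whole family. The validation report groups pairs by
relationship label, compares mean observed to expected kinship, and
fits an ordinary least-squares regression of observed on expected over
related pairs (unrelated pairs optional, off by default).

## What the synthetic data does and does not show

The built-in burn-in emulates neutral, equilibrium, panmictic founder
genomes on one short chromosome. Real founder panels differ in ways
that matter for kinship work: they carry genome-scale marker sets
across ~35 Morgans of map length, population structure, and background
relatedness. Two consequences follow for the package's own validation
runs, both visible in the test suite and the acceptance script:

* Class *means* for close relationships (parent–child, sibling,
  grandparent, avuncular) recover their expectations well, and the
  regression of observed on expected kinship has slope near 1 and
  intercept near 0 — the estimator and the transmission engine are
  unbiased.
* Per-pair *scatter* is large. On a 1 Mb sequence at $r = 10^{-7}$ the
  genome is 0.1 Morgan, so a gamete is essentially one whole parental
  haplotype: realized IBD for collateral relatives is nearly
  all-or-nothing around its expectation, and with
  $\theta = 4 N_e \mu L = 20$ only on the order of 140 markers
  segregate. The $r^2$ of the per-pair regression is therefore small
  at this scale (a few percent), and the means of distant classes
  drift by run-level offsets of ~0.01–0.02 through the realization
  variance of the founder reference. Genome-scale runs — many
  chromosomes or higher $rL$ and $\mu L$ — are what tighten per-pair
  estimates; the desk-scale defaults are chosen for runtime, not
  realism of per-pair precision.

Passing structure-level tests (sibship moments, relationship metrics,
Mendelian transmission, Poisson crossovers) therefore validates the
simulator's mechanics; they do not imply that single-short-locus
kinship estimates discriminate relationship classes pair by pair.

## Numerical and design choices

* Sibship draws: `round()` then truncate at zero; with `sd = 0` the
  draw is deterministic. R's round-half-to-even applies on exact .5
  means, a measure-zero concern for real schedules.
* `n_generations` counts reproducing generations (schedule rows
  consumed); individuals span ticks 1 to `n_generations + 1`.
* Ties in the within-family MAP candidate draw are uniform; the
  replaced father is always excluded, and the within/new decision is
  drawn before the candidate search, with fallback to creation on an
  empty pool.
* The burn-in prunes fixed and lost sites every 25 generations;
  positions are integers, breakpoints continuous.
* Degenerate inputs fail loudly: empty pedigrees for generation
  assignment, monomorphic dosage matrices for the estimator (the
  sharing scale $1 - \bar M$ is undefined), unphased genotypes in
  founder VCFs, cycles anywhere.
* Default problem sizes in the validation runs: 10,000 replicate
  families for the sibship table; one census family of ~500–2,500
  individuals from three founder couples ($N_e = 500$ burn-in pool,
  the family redrawn if its founder count exceeds the pool) for the
  kinship loop. These sizes were chosen to make the Monte-Carlo
  standard errors small relative to the quantities being checked.

## Known limitations

Single contig per run; no selection, demography, sex chromosomes,
crossover interference or genetic maps beyond scalar rates; no
inbreeding correction in expected kinship; no alternative estimators
(KING, PC-Relate); misattributed maternity, adoption and gamete
donation are out of scope, as is drawing pedigrees.
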