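---
title: "Replicator analysis: autocatalysis, selection, heredity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicator analysis: autocatalysis, selection, heredity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replikit)
library(tibble)
```

replikit treats "being a replicator" as a set of exactly decidable,
quantitative properties rather than a verbal definition. It answers four
families of questions:

1. **Multiplication** — is a species multiplied by a reaction cycle, with
   what order and what exact per-turn replication ratio, and from which
   minimal seeds can the cycle be ignited?
2. **Selection** — which entities are equivalent under a given selective
   sorting, i.e. how does a phenotype function partition an entity set?
3. **Heredity** — how much of an entity is variable, how much of that is
   heritable, and what parent–offspring similarity does that predict?
4. **Evolution** — when is a population a unit of selection, and when a
   unit of evolution with a genotype coupled to the phenotype?

## Stoichiometric networks and the token game

A `reaction_network` is a list of integer-stoichiometry reactions over
species with three roles: *internal*, *food* (externally supplied,
treated as an unlimited reservoir) and *waste* (a sink that may never be
consumed). Catalysts are a first-class field of a reaction — required to
be present, returned unchanged — rather than matched reactant/product
pairs, so "is this species needed only catalytically?" is a syntactic
query. Reversible steps are modelled as two irreversible reactions.

Ignition is decided by a bounded *token game*. The state is a multiset
of internal species; a reaction may fire when its non-food reactants and
catalysts are available; firing consumes reactants, returns catalysts,
adds non-waste products. A seed **ignites** when some firing sequence
reaches a state that holds at least the seed counts of every seed
species with a strict surplus in at least one — one turn has produced
more offspring than parents. A seed **sustains** when the reachable set
is exhausted without surplus but some sequence returns exactly to the
seed (sequential replacement), and **dies** when neither happens. The
search is a breadth-first reachability exploration with explicit bounds
(`max_steps`, default 50 firings; `max_states`, default 50000 distinct
states); when a bound is hit the outcome is reported as `undecided`
rather than being claimed as a death. Witness firing sequences are
deterministic because reactions are explored in id order and seeds are
enumerated size-ascending, then lexicographically.

```{r}
bn <- fixture("bird_nest")
bn
can_ignite(bn, c(A1 = 1))
minimal_seeds(bn)
```

The *replication ratio* of a species is computed from the smallest pure
seed `{species: k}` that ignites: the count after the shortest igniting
turn divided by `k`, kept as an exact rational because ratios such as
4/3 are exact claims, not floating-point estimates:

```{r}
replication_ratio(fixture("formose"), "glycolaldehyde")
replication_ratio(fixture("calvin"), "PGA")
```

Role labels separate obligate from facultative autocatalysts. A species
with an igniting pure seed is an *autonomous* (obligate) autocatalyst; a
species multiplied by the cycle that appears in minimal seeds but has no
pure seed is *dependent*; a species that participates only catalytically
yet is multiplied per turn is *autoinductive* (facultative) — the nest of
the bird–nest cycle, whose per-turn ratio is 2 even though no number of
nests alone can start anything:

```{r}
tidy(analyze_network(bn))
```

### Fixture encodings

The eight built-in networks encode the worked examples at the coarsest
granularity that preserves their seed structure, and are content-hash
pinned so the test suite detects any accidental edit.

* **formose** — only the autocatalytic core: glycolaldehyde →
  glyceraldehyde → dihydroxyacetone → tetrose → 2 glycolaldehyde, with
  formaldehyde as food. One turn nets +1 glycolaldehyde for 2
  formaldehyde.
* **calvin** — the sugar-phosphate network at metabolite granularity
  (triose-phosphate isomerase as two directions; CO2, ATP, NADPH as
  food; ADP, NADP, Pi as waste). Enzymes are represented by a single
  always-available catalyst pool, `Ecalvin`, carried as a food-role
  species on every enzymatic step: the analysis is conditional on all
  obligate enzymes being present, which is exactly how the cycle's seed
  claims are stated. Under this encoding one PGA dies, two PGA die, and
  three PGA ignite to four — ratio 4/3 — while the smallest mixed seeds
  have two molecules (e.g. {Se7P, DHAP}).
* **reductive_tca** — the asymmetric reductive cycle at coarse
  granularity: citrate cleavage regenerates one oxaloacetate directly
  while the acetyl branch rebuilds the second through pyruvate, so the
  two oxaloacetate copies per turn arise differently. The thioanalogue
  variant of this cycle is not reconstructible at this granularity and
  is not encoded.
* **bird_nest** / **bird_catalyst** — the nesting-bird formalisation
  (nest produced in phase 1, required catalytically in phase 2) versus
  the naive version in which birds simply catalyse nests; in the latter
  the nest is a heterocatalytic product and correctly classifies as
  non-autocatalytic.
* **rna_only**, **rna_protein_facultative**, **rna_protein_obligate** —
  template replication alone; with a facultative peptide catalyst
  (the catalysed route duplicated alongside the uncatalysed one); and
  with fully obligate gene–enzyme coupling, where enzyme production
  itself requires both partners, so only {DNA, E} ignites.

The `undecided` outcome matters in practice: a few size-3 Calvin seed
candidates exceed the default search bounds (their reachable state
spaces grow through repeated carbon fixation), so seed enumerations at
that depth carry an `incomplete` flag instead of a completeness claim.
All reported seeds are genuine (each has an explicit witness); the flag
concerns candidates that could not be rejected within bounds. For the
Calvin analyses we use `max_seed_size = 3`, which already contains every
minimal seed of the network.

## Selection as equivalence partitioning

Selection is modelled as sorting by a *phenotype function*: two entities
are equivalent exactly when the phenotype cannot distinguish them. The
partition induced on an entity set is the entire content of a single
selective event — anything finer (structure, sequence) is invisible to
that selection.

```{r}
codons <- codon_entities(rna = TRUE)
glance(partition_by_phenotype(codons, "amino_acid"))
are_equivalent(codons, "UCA", "AGU", "amino_acid")
```

The standard genetic code ships as a frozen in-package table (64 codons,
20 sense classes plus stop); a test cross-checks it against the
Biostrings reference table. Phenotypes are compared by exact equality;
for real-valued phenotypes the caller supplies a quantising function, a
deliberate choice since no tolerance is universally right.

A population is a *unit of selection* when its phenotype partition has
at least two blocks — no death, heredity or even copying fidelity is
required, which is why a diverse population of exact replicators is
selectable. A *unit of evolution* additionally needs a positive
heritable fraction and a genotype–phenotype map that is not decoupled:
`gp_map(g_idx, p_idx)` records which feature indices determine each, and
if the two sets are disjoint, selection on phenotypes cannot be
channelled toward genotypes. Acquired changes classify into four
quadrants (heritable × phenotype-affecting); whether a heritable neutral
change is trivially or non-trivially neutral is accepted as
caller-supplied metadata because no operational criterion exists at the
level of index sets.

## The S/N and V/H heredity models

Hereditary potential is context-dependent: with `S` possible stable
states and `N` individuals, a population larger than its state space
(`N > S`) can only have limited heredity, while `N <= S` permits
unlimited heredity and open-ended evolution. The boundary `N = S` is
assigned to the unlimited domain. State counts of sequences are computed
exactly — `sequence_state_count(30, 4)` exceeds what a double represents
exactly, so large counts are kept as exact decimal integers and compared
exactly against `N`. (The letter S is used in the literature both for
this state count and for the similarity below; the two quantities live
in different types here and never mix.)

The V/H model describes one entity's information as `I` modules of which
a fraction `V` is variable and a sub-fraction `H <= V` heritable (the
genotype). With per-module lifetime-change probability `upsilon` (over
one inter-replication interval — a probability, not a rate to be
integrated) and per-module copy error `mu`, the expected number of
features an offspring shares with its parent is

$$S = I(1-V) \;+\; I(V-H)(1-\upsilon) \;+\; I H (1-\upsilon)(1-\mu)
\;+\; I H \upsilon \mu \varepsilon,$$

where `epsilon` is the probability that a miscopied module lands back on
its original state: `1/(A-1)` under uniform miscopy over an inventory of
`A` symbols, hence certainty for a binary inventory and negligible for
large ones (`default_epsilon()`).

```{r}
expected_similarity(vh_params(100, V = 0.5, H = 0.2,
                              upsilon = 0.1, mu = 0.01))
```

**Reference convention.** The four terms do not all compare the
offspring against the same parent snapshot: the non-heritable variable
term counts matches against the *current* parent, while the heritable
terms count matches against the parent *at its own birth* (a heritable
module that changed during the parent's lifetime and was then copied
faithfully matches the current parent but is not counted). The closed
form is implemented exactly as stated, and the simulator's similarity
measurement exposes the same choice as `convention = "as_printed"`,
under which the Monte-Carlo mean reproduces the formula with no free
parameter. A pure current-parent reference (`"current_parent"`) is also
available for comparison; it would add a term $I H \upsilon (1-\mu)$
(plus a smaller $\varepsilon$-correction) to the expectation. Which
reference is "right" is a modelling choice we do not adjudicate; the
package makes the choice explicit and testable.

Classification follows from the parameters: `V = 0` is an exact
(holistic, non-informational) replicator; `V > 0, H = 0` a variable
replicator that cannot pass changes on; `H > 0` an informational
replicator, refined into limited/unlimited by the S/N context; `V = H =
1` is flagged as the hypothetical ideal replicator. The hierarchy
classifier chains these with multiplication and kinetics — regeneration,
order at least 2 with `g > d`, then V, H, and finally development —
each label presupposing all shallower capabilities. `has_development` is
a declared input: development is defined conceptually (interpretation of
previously copied information) and has no operational test from the
parameters alone.

## The population simulator

`run_simulation()` uses discrete non-overlapping bookkeeping: per
generation each entity undergoes lifetime change, replicates with
probability `g`, dies with probability `d`; an optional carrying
capacity is enforced by uniform random culling, which is neutral with
respect to phenotype so that selection arises only from `g` differences.
Offspring heritable modules are copied from the parent's current state
(with error `mu`); offspring non-heritable variable modules are rebuilt
to the parent's birth values. That reset is the simplest "development"
operator consistent with the requirement that the non-heritable part is
not produced by copying; richer development operators that increase
similarity further are out of scope.

Two design points matter for reproducibility and scale. Trajectories are
bit-reproducible given `(config, seed)`. And when `V = 0`, entities
carry no mutable state, so the dynamics depend only on per-type counts;
the simulator then switches to exact count-based binomial updates, which
is what makes 40 generations of unlimited growth (populations of order
$10^9$) feasible:

```{r}
dil <- dilution_experiment(0.5, 0.25, generations = 10, reps = 30,
                           n0 = 200, seed = 1)
tail(dil, 3)
```

The slow type's expected frequency,
$n_0(1+g_s)^t / (n_0(1+g_s)^t + n_0(1+g_f)^t)$, declines monotonically
— selection and extreme dilution without any death. The simulated mean
tracks this closed form within sampling error at every generation.

## What the synthetic tests do and do not show

The verification strategy is dual-route throughout: every closed form
or search result is checked against an independent computation that
shares no code with it.

* The closed-form similarity is checked against the Monte-Carlo simulator on a
  66-point grid spanning $V \in \{0, .3, .7, 1\}$, $H \in \{0, V/2, V\}$
  and $\upsilon, \mu \in \{0, .05, .2\}$ at $10^4$ replications per
  point, within 4 standard errors.
* `minimal_seeds()` is checked against a brute-force oracle that
  enumerates every firing sequence recursively, on 200 random networks
  of up to 6 species and 6 reactions (bounds 3 seed molecules, 5
  firings — small enough for the oracle's exponential enumeration).
* The dilution simulation is checked against the two-type growth
  expectation at every generation (200 replicates, initial count 200
  per type; the initial count is large enough that the frequency's
  Jensen bias is far below the Monte-Carlo standard error).

These checks validate the *implementations against each other* under
the stated model. They do not show that real chemistries satisfy the
token-game idealisation (unlimited food, discrete firings, no rates),
that real phenotypes are exactly comparable, or that real lifetime
change is homogeneous across modules — those are modelling assumptions
the user must judge per application.

## Numerical and degenerate-input conventions

* Stoichiometries and seeds are integers; replication ratios exact
  rationals; state counts exact integers of arbitrary size. No float
  comparison decides a structural claim.
* Canonical orderings (species, reactions, seeds, partition blocks) use
  byte-order sorting, so written files, content hashes and JSON reports
  are identical across locales and platforms.
* Empty networks, unknown species, waste used as input, a species that
  is reactant and catalyst of the same reaction, `H > V`, and
  non-probability rates are all rejected with specific errors; a food
  species that is also produced is recorded as a warning, since food is
  treated as externally supplied either way.
* Search problem sizes used by the shipped analyses: `max_steps = 50`
  and `max_seed_size = 6` by default (generous for the fixture
  networks; the Calvin seed enumeration uses `max_seed_size = 3`, which
  contains all of its minimal seeds).
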