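---
title: "Detecting four-node hybridization cycles with concordance-factor invariants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting four-node hybridization cycles with concordance-factor invariants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetinv)
```

## The model

A level-1 semi-directed phylogenetic network with one reticulation whose
cycle has four nodes — `h` (the hybrid node), its two parents `v1` and
`v2`, and the node `v3` opposite the hybrid — partitions the taxa into
four clades: the hybrid clade `n0` below `h`, the parent-side clades `n1`
(at `v1`) and `n2` (at `v2`), and the opposite clade `n3` (at `v3`).  The
model parameters are the internal branch lengths in coalescent units —
the clade stems `t0..t3`, the hybrid edges `t01` (`h–v1`) and `t02`
(`h–v2`), and the cycle edges `t13`, `t23` — and the inheritance
probability `gamma`, the probability that a lineage entering `h` follows
`h–v1`.  Pendant branch lengths never enter quartet concordance factors,
so only these nine quantities matter; they appear through
`z_e = exp(-t_e)`.

Under the multispecies coalescent, the expected frequency of each
unrooted quartet split among gene trees (the concordance factor, CF) is a
polynomial in the `z_e` and `gamma`.  `quartetinv` constructs these
polynomials exactly, by what amounts to a first-coalescence argument: for
four sampled lineages, the quartet split is decided by the first pair to
coalesce, so propagating the probability that no pair has yet coalesced
edge-by-edge toward the root — splitting off decision mass
`(1 - z^C)/C` per pair on every edge carrying `m >= 2` lineages, with
`C = m(m-1)/2`, and enumerating the `gamma`-weighted hybrid-edge choices
of clade-0 lineages — yields each CF as an exact rational polynomial.
Quartet subsets drawing at most two taxa per clade are *informative*
about the cycle; there are 19 informative classes on the reference
network with two taxa per clade, hence 57 CF polynomials in 9 parameter
variables.  Smaller networks use the subset of classes their clade sizes
allow (12 polynomials for a five-taxon network with clade sizes 1,1,1,2).

Two independent checks guard this engine: a numeric implementation of the
same propagation on arbitrary networks (any clade sizes, used to fill
complete CF tables for nine- and ten-taxon networks), and a Monte-Carlo
coalescent simulator (`mc_quartet_cfs()`) that merges lineages with
exponential waiting times and is compared to the polynomials within
binomial standard errors in the tests.

## Invariants by degree-truncated elimination

A phylogenetic invariant is a polynomial in the CF values alone that
vanishes whenever the CFs come from the model, whatever the branch
lengths and `gamma`.  Each class contributes two *trivial* invariants —
its three CFs sum to one, and its two minor CFs are equal whenever the
class draws a pair from some clade (they are exchangeable) — and the
remaining structure comes from eliminating the nine parameters from the
CF system.

The elimination is performed on reduced coordinates: after substituting
the trivial relations, each class keeps its major CF as one free
coordinate, except the class drawing one taxon from every clade, which
keeps two (its minors differ because they straddle the hybrid
asymmetry).  On these coordinates the package computes all polynomial
relations up to a truncation degree:

1. evaluate the reduced CF polynomials at random points of a prime field
   `F_p` (`p` just below 2^20, so all products stay exactly representable
   in doubles), for two independent primes;
2. build the monomial-evaluation matrix up to the truncation degree and
   take its reduced row echelon form (a small C++ kernel) with columns in
   graded order — each non-pivot monomial yields one canonical relation
   expressing it in earlier pivot monomials, mirroring a truncated
   Groebner basis under a graded order;
3. keep minimal generators (leading monomial not divisible by an earlier
   one), reconstruct each rational coefficient from the two primes by
   Chinese remaindering and continued fractions, and
4. *verify every candidate symbolically*: the substituted polynomial in
   the nine parameters is fully expanded, with coefficient arithmetic in
   two further prime fields, and must be identically zero.  Candidates
   that fail are dropped with a warning (none do in practice).

The derivation is deterministic (fixed internal seeds for the field
points), takes seconds for signatures up to seven taxa and ~20 s for the
eight-taxon system, and is memoized per session;
`store_invariants()`/`load_invariants()` persist sets as JSON with a
checksum and an on-load re-validation against freshly generated model
CFs.

**Choice of truncation degree.**  Degree 3 suffices for most signatures
(the five-taxon generators come out with degree ≤ 2, matching the
published basis for that network, whose ten printed polynomials all
vanish on our model CFs under the index correspondence resolved by
`resolve_printed_1112_indices()`).  But completeness at a fixed degree is
not guaranteed, so the default derivation escalates the degree (3, 4, …,
capped at 6) until the set *separates clade-role reassignments*: model
CFs read through any wrong same-signature assignment of the clades to the
four cycle roles must score strictly positive (beyond double-precision
zero).  This is the minimal identifiability the method exists to provide,
and it is decided on a fixed internal seed before any data are seen.
Six-taxon signatures with a two-taxon hybrid clade and two singleton
clades (2211, 2121, 2112 in the `n0 n1 n2 n3` size notation) need degree
5: exchanging the parent-side and opposite singleton clades lands
remarkably close to the model variety, and the separating invariants are
high-degree and give small margins (about 1e-5 at the simulation-study
parameters).  For the five-taxon signatures 2111, 1211 and 1121 no
separating invariants exist up to degree 6 — with so few taxa around the
hybrid node those role reassignments are (at least nearly)
unidentifiable from CFs; the derivation warns, and their candidates can
score at numerical zero on data they did not generate.  In practice this
confines reliable top-1 inference to six or more taxa: a five-taxon
ranking still contains the truth at an on-variety score, but zero-score
candidates from the unidentifiable signatures crowd the head of the
list, so it should be read as a shortlist.  This mirrors the method's
known weakness when the hybrid clade is sparsely sampled; the validation
study accordingly starts at six taxa.

## Scoring and ranking

The invariant score of a candidate partition is the L2 norm of all its
evaluated invariants (trivial plus derived), after mapping the observed
CF table onto the candidate's a-vector: every four-taxon subset realizes
exactly one class; its three CFs are assigned to slots (slot 1 is the
class-predicted split; minor slots follow the canonical column order of
the sorted quadruple) and averaged per slot across the realizations of
the class.  Averaging is the natural unbiased estimator of the common
true CF.  The conceivable alternative — evaluating invariants once per
realization and pooling the scores — is not offered: the nontrivial
invariants couple CFs across several classes, so a per-realization
evaluation has no well-defined meaning beyond the trivial invariants,
and averaging first is the coherent choice.  Raw (unnormalized) L2 norms are compared
across signatures with different invariant counts, as the inference
procedure prescribes; `normalized = TRUE` divides by the square root of
the invariant count for users who want comparable per-invariant
magnitudes.

Candidates are all ordered partitions of the taxa into four clades of
size 1 or 2 (2520 for eight taxa, 1080 for six).  Partitions whose clades
exceed two taxa are not candidates: two taxa per clade already carry all
information about the cycle, and larger taxon sets go through the subset
algorithm below.  Both members of each n1/n2-symmetric pair are
enumerated; their scores agree to machine precision *by construction* —
derived generator sets are closed under (or mirrored through) the induced
relabeling, and the slot conventions are label-based — so symmetric pairs
appear adjacently in the ranking and ties are broken by the canonical
partition text.

For more than eight taxa, every eight-taxon subset is ranked, all
candidates are pooled into one global ranking, and the best candidate
N8* is extended: each missing taxon takes its clade from the
highest-ranked candidate that contains it and agrees with N8* on every
shared taxon.  The agreement rule is our concrete reading of "placement
in the next-best network"; each placement is logged (`placements` in the
result) so it can be audited, and a taxon with no agreeing candidate is
reported as unplaced rather than guessed.

## The synthetic-data generators

The generators reproduce the validation conditions: every internal branch
1.0 coalescent unit and `gamma = 0.3` by default, Gaussian noise with
`sigma` in {5e-4, 5e-5, 5e-6}, and gene-tree counts in {100, 1000,
10000}.

* `true_cf_table()` — exact model CFs, one row per four-taxon subset,
  complete even for clades of three or more taxa (within-clade ladders
  with 1.0-unit internal branches; pendant lengths are irrelevant to the
  CFs and chosen to keep clades ultrametric for tree output).
* `perturb_gaussian()` — i.i.d. Gaussian noise on every entry, clipped to
  [0, 1]; triples are *not* renormalized by default (at the tiny sigmas of
  the design the triples stay essentially on the simplex), a
  `renormalize` flag exists.
* `sample_gene_tree_quartets()` — per-quartet multinomial counts at the
  true CFs; cheap, but quartets are independent across one "gene", unlike
  real data.
* `simulate_gene_trees()` — full coalescent gene trees on the network
  (per-gene hybrid choices, exponential coalescence within edges),
  preserving within-gene quartet dependence; its output re-counted by
  `cfs_from_gene_trees()` matches the CF polynomials within sampling
  error in the tests.

What passing tests on these generators do *not* show: robustness to
gene-tree estimation error from finite sequences (emulated only crudely
by Gaussian noise), to missing data patterns correlated with the
phylogeny, or to model violations such as gene flow outside the single
four-node cycle.

## Numerical choices and degenerate inputs

All polynomial algebra is exact (integer numerators/denominators in
doubles, far below 2^53, with an overflow guard).  Model-vanishing is
asserted at 1e-10 in tests; "zero score" for on-variety candidates is in
practice below 1e-12.  CF tables are canonicalized to sorted taxon order
with the split columns permuted accordingly, so row order and label
permutations cannot change results; duplicate quadruples and non-unit
triples (beyond 1e-6, unless disabled for perturbed tables) are rejected
with row numbers.  Gene trees may be non-binary: unresolved quartets are
skipped entirely (they enter no numerator and no denominator), quartets
with no informative tree are omitted with a warning and later surface as
an explicit missing-quadruple error if a ranking needs them.  Multiple
individuals per species are handled by label mapping; each choice of one
representative per species counts as a fractional observation.

The problem sizes used by the test suite — 30 replicates per noise
setting, 10^4 sampled genes, Monte-Carlo checks at 10^4–10^5 draws, and
one nine- and one ten-taxon subset-algorithm run — are reduced-scope
versions of the full simulation study, chosen so the whole suite runs in
minutes while still exercising every claim at its stated threshold.

## Known limitations

Only four-node cycles on level-1 networks are detectable (three-node
cycles admit no CF invariants; larger cycles are out of scope).  Topology
within clades is never resolved, and neither `gamma` nor branch lengths
are estimated — the n1/n2 symmetry is therefore unresolvable by design.
Signatures with a single taxon below or beside the hybrid node are only
weakly identifiable (see the degree discussion above); with noisy data,
treat the top-5 list, not the top-1, as the result there.  Scores carry
no calibrated goodness-of-fit scale: they rank candidates but do not test
whether *any* four-node cycle fits.
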