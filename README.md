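# quartetinv

Optimization-free detection of four-node hybridization cycles in level-1
phylogenetic networks from quartet concordance factors.

## The problem

Hybridization, introgression and horizontal transfer make parts of the
Tree of Life a *network*: a reticulation node `h` with two parent edges,
carrying an inheritance probability γ (the fraction of the genome that
followed the minor parent).  Likelihood-based network inference has to
search network space and optimize branch lengths — expensive and often
intractable beyond a few dozen taxa.

`quartetinv` takes a different route.  Under the multispecies coalescent
on a level-1 network whose reticulation sits in a four-node cycle
`h–v1–v3–v2–h`, the cycle partitions the taxa into four clades
(the hybrid clade *n0* below `h`, the parent-side clades *n1*, *n2*, and
the opposite clade *n3*).  For every four-taxon subset, the expected
frequencies of the three quartet splits among gene trees — the
*concordance factors* (CFs) — are polynomials in the branch-length
exponentials `z_e = exp(-t_e)` (coalescent units) and γ.  For example,
for two taxa `k1,k2` from clade *n2* and two `l1,l2` from clade *n3*,

    CF(k1k2|l1l2) = 1 − (2/3) z2 z23 z3,
    CF(k1l1|k2l2) = CF(k1l2|k2l1) = (1/3) z2 z23 z3.

Eliminating the nine parameters from this polynomial system leaves
*phylogenetic invariants*: polynomials in the CFs alone that vanish
whenever the CFs come from the model, for **any** branch lengths and γ.
A candidate placement of the cycle is scored by the **invariant score**,
the Euclidean (L2) norm of its evaluated invariants; the candidate
closest to zero best explains the data.  Because scoring is just
polynomial evaluation, ranking every candidate partition of up to eight
taxa (2520 candidates for eight) takes about a second, and larger taxon
sets are handled by scanning all eight-taxon subsets and re-attaching the
remaining taxa.

The package derives the invariant sets itself, by exact degree-truncated
elimination over prime fields with symbolic verification of every
generator, and validates its CF polynomials against an independent
Monte-Carlo coalescent simulator.  A synthetic-data suite (exact CF
tables, Gaussian-perturbed tables, multinomial quartet sampling, and full
coalescent gene-tree simulation on networks) reproduces the simulation
conditions the method is validated under.

## Who it is for

Phylogeneticists with a multilocus dataset (gene trees, or a quartet CF
table from e.g. a BUCKy/PhyloNetworks workflow) who want to locate a
single hybridization event quickly, or to shrink the candidate-network
space before a likelihood analysis.  The method identifies the *placement
of the cycle* — which taxa are below the hybrid node, which flank it,
which sit opposite — not the topology within clades, and not γ or branch
lengths.

## A worked example

```r
library(quartetinv)

# the reference eight-taxon network: two taxa per clade, every internal
# branch 1.0 coalescent units, gamma = 0.3
truth <- clade_partition(c("A","B"), c("C","D"), c("E","F"), c("G","H"))
tbl   <- true_cf_table(truth, network_params())   # 70 exact CF rows

ranking <- rank_partitions(tbl, m = 5)
top_networks(ranking, 3)
#> # A tibble: 3 × 5
#>    rank    score partition                   signature symmetric_rank
#>   <int>    <dbl> <chr>                       <chr>              <int>
#> 1     1 2.01e-15 n0=A,B;n1=C,D;n2=E,F;n3=G,H 2222                   2
#> 2     2 2.07e-15 n0=A,B;n1=E,F;n2=C,D;n3=G,H 2222                   1
#> 3     3 1.84e- 2 n0=A,B;n1=G,H;n2=E,F;n3=C,D 2222                   4
```

Rank 1 is the true partition with a score at machine zero; rank 2 is its
n1/n2-symmetric twin (the method provably cannot distinguish the two
parent-side clades without estimating γ — their scores agree to 1e-15);
rank 3, the best genuinely wrong candidate, is six orders of magnitude
worse.  `as_enewick(parse_partition(ranking$partition[1]))` serializes
the winner as extended Newick:

```
(((C,D),(A,B)#H1),((E,F),#H1),(G,H));
```

From gene trees instead:

```r
trees   <- simulate_gene_trees(truth, network_params(), k = 1000, seed = 1)
cfs     <- cfs_from_gene_trees(trees)
ranking <- rank_partitions(cfs, m = 5)
```

`tidy()`, `glance()` and `autoplot()` work on rankings; a thin command
line wrapper lives in `inst/cli/quartetinv`
(`quartetinv infer --cf-table cfs.csv --m 5 --out results/`).

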