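---
title: "TMRCA versus divergence time: model, oracles and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TMRCA versus divergence time: model, oracles and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalsplit)
```

## The model

`coalsplit` simulates gene genealogies under the simplest isolation
model that exhibits the TMRCA/divergence-date distinction: two
populations of equal, constant size N₀, no migration, and a single
population split. Looking backward in time, lineages sampled from each
population coalesce only within their own population until the join time
`t_join`, when the source population's surviving lineages move into the
destination population and coalescence proceeds panmictically.

Time is measured in units of 4N₀ generations (the ms convention): while
a population holds *k* lineages, the waiting time to its next coalescence
is exponential with rate *k(k−1)*, so a pair coalesces after mean 0.5
units. The canonical design throughout is 10 samples from an ingroup
taxon X plus a single outgroup representative Y — the sampling layout of
most dating studies, where within-taxon sampling is dense and a lone
outgroup polarizes the tree.

Two named scenarios bind the model to concrete commands:

* **deep** — `ms 11 1 -t 2.0 -I 2 1 10 -ej 10 1 2 -T`: divergence at
  10 × 4N₀ = 40 N₀ generations;
* **recent** — the `-ej 0.01` variant: divergence at 0.04 N₀ generations.

Under the deep scenario the ingroup's TMRCA is governed entirely by its
own coalescent (mean `1 − 1/n = 0.9` for n = 10) while the root height —
the MRCA of X and Y, the only divergence-related random quantity per
replicate — always exceeds `t_join`. Under the recent scenario ancestral
polymorphism has not sorted: the ingroup is rarely monophyletic and the
TMRCA and root-height distributions coincide.

### Why the root height is the divergence-date proxy

Per replicate we report three ages and a status:

* `tmrca(tree, X)` — the age at which the ingroup samples coalesce;
* `root_height(tree)` — the global TMRCA, i.e. the MRCA of X ∪ Y. This
  is what an outgroup-containing dating analysis estimates, and it is
  the per-replicate divergence-date proxy (the true parameter `t_join`
  is carried alongside for reference, but it is a constant, not a
  distribution);
* `basal_node_age(tree)` — the oldest internal node *other than* the
  root. Empirical studies sometimes report this "age of the most basal
  node" as if it were the TMRCA. We formalize it as the oldest non-root
  internal node because that is the largest value any such reading could
  take, and it is still strictly younger than the root height on every
  binary tree — `compare_node_age_vs_tmrca()` makes that ordering
  executable and returns 1.0 on any valid input;
* `classify_sorting(tree, X)` — monophyletic iff the MRCA of X has no
  non-X descendants. A singleton ingroup is vacuously monophyletic (a
  documented convention, not a theorem).

## Exact oracles

The simulator is validated against closed forms that share no code with
it.

**Lineage-count distribution.** The number of ancestral lineages of a
sample of *n* is a pure-death chain stepping from *j* to *j − 1* at rate
*j(j−1)*. The classical alternating-series solution is numerically
unstable at moderate *n*, so `lineage_count_distribution()` exponentiates
the generator matrix instead (scaling-and-squaring via `Matrix::expm`);
probabilities are clipped at 0 and renormalized, with total deviation
from 1 far below 1e−12 in the regimes used here.

**Monophyly probability.** Conditional on *j* ingroup lineages surviving
to the join, the ingroup is monophyletic iff all *j* coalesce before any
joins the lone outgroup lineage. Among *k* ingroup + 1 outgroup
exchangeable lineages the next merge is ingroup-internal with probability
C(k,2)/C(k+1,2), and the product over *k = j..2* telescopes to
*q(j) = 2/(j(j+1))*. `monophyly_probability(n_in, t)` convolves *q* with
the lineage-count distribution at *t*. The recursion is itself verified
in the tests against exhaustive enumeration of all uniformly chosen
pair-merge histories for *j* ≤ 4. The oracle is restricted to a single
outgroup lineage — the study design above — because a general
multi-lineage outgroup requires a two-dimensional state recursion that
nothing in the package needs.

**Watterson expectations.** `expected_tmrca(n) = 1 − 1/n`,
`expected_total_length(n) = H(n−1)` and
`expected_segsites(n, θ) = θ·H(n−1)` close the loop on the mutation
overlay: for n = 2 the mean pairwise difference is θ.

As an additional, fully independent route, the test suite compares
root-height samples against msprime run under the identical demography
(two-sample Kolmogorov–Smirnov at α = 0.01).

## Mutation overlay

Mutations follow the infinite-sites model: a single Poisson draw with
mean θ × total branch length, each mutation assigned to a branch with
probability proportional to its length (equivalent to independent
per-branch Poisson processes, but one draw and exact), a fresh
uniform(0,1) position mark, and the derived allele set equal to the
branch's descendant leaves. Ancestral state is 0; there is no
back-mutation, recombination or finite-sites correction. Position marks
are decorative (printed at 4 decimals in the ms dialect); the haplotype
matrix is the observable. The mutation stream is seeded separately from
the genealogy stream, so changing θ never changes the trees.

## Reproducibility and numerical choices

* **Substreams.** One master seed; replicate *i*, stream *s* uses
  `mix_seed(seed, i, s)` — an exact double-precision modular LCG (all
  intermediates < 2⁵³, modulus the largest prime below 2³¹) feeding
  `set.seed()`. Replicate *i* is therefore invariant to `n_reps`, and an
  ms `-seeds a b c` triple is folded into one master seed by the same
  absorption. The calling session's RNG state is saved and restored
  around every simulation.
* **Pair selection.** The coalescing pair is an indexed uniform draw over
  the k(k−1)/2 pairs in label-sorted order, making runs byte-reproducible
  across platforms given R's RNG. Ties in continuous event times have
  probability zero; no tie-breaking logic exists beyond that ordering.
* **Newick IO.** Writing goes through ape. Parsing accepts rooted binary
  trees with branch lengths; node ages are recovered from root-to-tip
  distances and inputs must be ultrametric within 1e−6 (relative to tree
  height), else an error — silent repair would corrupt age-based
  metrics. Round trips preserve ages to 6 decimals.
* **Unit discipline.** Every internal time is in 4N₀ generations; the
  sweep grid is specified in Ne generations (the units in which the
  "sorting completes after 4–7 Ne" rule of thumb is stated) and converted
  by t/4 at the boundary, with Ne ≡ N₀ since both populations share one
  constant size. `convert_time()` is the only conversion point.
* **Histograms.** Scenario summaries bin by Freedman–Diaconis and record
  the bin edges, so summaries are exactly reproducible from the JSON.
* **Problem sizes.** Documented checks use 5,000 replicates per sweep
  point (binomial SE < 0.008) and 10,000 replicates for closed-form
  recovery; each such batch takes seconds on one CPU. Monte-Carlo
  assertions use 3-standard-error bands.

## The masking/SNP-culling step

`mask_and_cull()` reproduces the cleanup applied to whole-genome
alignments before molecular dating: (1) every column intersecting a
recombinant interval (`Node`/`Beg`/`End`, 1-based inclusive — the
ClonalFrameML importation dialect) is removed entirely; (2) columns
containing any character outside A/C/G/T (ambiguity codes, N, gaps —
strict whitelist, case-insensitive) are removed; (3) the remainder is
culled to columns with ≥ 2 distinct valid states, in original order, with
a 1-based map back to source coordinates.

Design choices where the convention is genuinely open:

* **Column-wise masking is the default** — an interval on any taxon
  removes the whole column, matching the "remove positions from the
  alignment" phrasing such pipelines use; `per_taxon = TRUE` instead
  blanks only the named taxon's characters (they then fall to the
  incomplete-site rule). Both are exposed because detectors disagree on
  which is meant.
* **Intervals naming unknown taxa** (detectors emit internal-node labels)
  warn by default and fall back to whole-column masking — the
  conservative reading; `unknown_taxon = "error"` tightens this. Mapping
  node-labelled intervals to descendant taxa would require the detector's
  tree, which the package deliberately does not consume.
* **Accounting is exact**: kept + masked-only + incomplete-only +
  invariant-only + multiply-flagged equals the input length, and the
  report carries the fraction of positions attributed to recombination.

## The synthetic generator

`generate_alignment()` emulates the structure such pipelines consume: a
reference row, independent per-column background substitutions, planted
tracts of elevated divergence on named taxa (returned as ground-truth
intervals), and sprinkled N characters. Columns are independent — there
is no linkage, no phylogenetically correlated substitution, and no
realistic recombination process. That is sufficient to exercise masking,
culling, accounting and recall of planted tracts, and is exactly why
passing those tests says nothing about detecting recombination in real
data: detection is out of scope, only the post-detection bookkeeping is
implemented.

## Limitations

* At most two populations, one join event, no migration, growth or
  serial sampling; the ms parser rejects everything outside
  `{-t, -I, -ej, -T, -seeds}` loudly rather than approximating it.
* The monophyly oracle covers a single outgroup lineage only.
* The sorting sweep reports the smallest *grid* time meeting the
  threshold; the threshold itself (default 0.90) is a parameter, since
  "complete" sorting has no canonical probability cutoff.
* The infinite-sites overlay is not a sequence simulator: no nucleotides,
  no rate heterogeneity, no clock misspecification — so the package can
  demonstrate the sampling-design problem, not the additional biases a
  relaxed-clock dating analysis may add on top.
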