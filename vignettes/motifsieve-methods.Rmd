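---
title: "Monte Carlo subset sampling for motif discovery: models and methods"
author: "motifsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo subset sampling for motif discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sets of DNA sequences assembled for motif discovery — windows around
ChIP-seq or ChIP-chip peaks, promoters of putatively co-regulated genes —
are routinely corrupted: a substantial fraction of the entries contain no
instance of the motif at all, because binding was indirect, the peak was
an artifact, or the site is too degenerate to count.  Probabilistic
finders address this softly: under the ZOOPS model (zero or one
occurrence per sequence) each entry carries a prior probability of
containing a site, and entries with low posterior effectively drop out.
When the corruption is heavy, though, the mixture likelihood surface is
dominated by the background and a single finder run fails.

`motifsieve` takes the harder line of excluding sequences outright: it
runs the finder on many small random subsets of the input, refines each
subset into a "related subset" — the set of entries that actually support
the subset's motif — and then asks which motifs keep being rediscovered
from unrelated starting subsets.  Convergence to the same motif from many
random starting states is treated as the signal of a meaningful motif,
and the surviving motifs are organised into a tree, cut into families,
and condensed into one familial profile (FP) per family, which is finally
mapped back onto every input entry (the MotifMap).

## The finder: ZOOPS expectation–maximization

Each entry $Y_j$ of length $L_j$ either contains no site (probability
$1-\gamma$) or exactly one site of width $w$ at a uniformly chosen
position and strand.  A site at position $i$ is emitted by the motif
frequency matrix $f$ (4 × $w$, pseudocount-smoothed); all other positions
are emitted by the order-0 background marginal $q$.  The E-step gives
each entry a posterior over $\{\text{no site}\} \cup \{\text{every start}
\times \text{strand}\}$; the M-step re-estimates $f$ from the
posterior-weighted site counts (with a background-proportional Dirichlet
of total mass `pseudo_total`, default 1 per column) and $\gamma$ from the
mean site-presence posterior.  The objective we track — the observed-data
log-likelihood ratio against an all-background model, plus the Dirichlet
smoothing penalty — is non-decreasing across iterations, and the package
asserts this in its tests.

Three points deserve emphasis:

* **Starting points.**  EM on a ZOOPS mixture is extremely multimodal.
  Following standard finder practice, a sample of `n_init_candidates`
  (default 100) subsequence windows is scored cheaply — each candidate
  word becomes a 0.7/0.1 frequency matrix and is scored by the sum over
  entries of its best-window log-odds — and the top `n_starts` (default
  2) candidates are refined with full EM; among converged starts the one
  with the largest total site log-odds wins, which also de-selects
  phase-blurred solutions of periodic motifs when a sharp one is
  available.  Uniform-random starts without this pre-scoring essentially
  never find a planted site at realistic corruption levels.
* **Phase-shift refinement.**  EM frequently converges to an
  *off-register* version of a motif: every site shifted by the same one
  to three columns.  After EM, all sites are slid together by up to
  `max_shift` (default 3) columns; the shift with the largest total site
  log-likelihood ratio wins, repeatedly until stable.  Since the
  in-register alignment concentrates the informative columns, this both
  sharpens motifs and — just as importantly — makes independent seeds
  agree on one register, so that downstream clustering sees them as the
  same motif.
* **Background model.**  The window likelihood ratio uses the order-0
  marginal $q$.  A $k$-th order model (default $k=3$, counts pooled over
  both strands, Laplace pseudocount) is estimated, serialized and used by
  the synthetic generator, but exact scan p-values by dynamic programming
  require positional independence, and using one $q$ throughout keeps the
  finder and the scanner on the same likelihood-ratio scale.  This biases
  the scanner slightly liberal on sequence with strong local composition;
  with fixed-width peak windows the effect is modest.

A collapsed Gibbs sampler (`zoops_gibbs`) is provided as an alternative
finder: per sweep each entry's assignment (absent, or start × strand) is
resampled from its full conditional under the hard counts of the other
entries; after burn-in (default 200 sweeps) the assignment with the best
site statistic over the sampling phase (default 300 sweeps) is reported.

## Motif significance: the shuffle-null E-value

The framework needs an E-value to filter related subsets (default cutoff
0.001, following the stricter of the two conventions in circulation; the
laxer 0.01 is sometimes quoted).  The statistic is
$T = \sum_{\text{sites}} \log_2 \frac{P(\text{site}\mid f)}{P(\text{site}\mid q)}$,
the total log-odds of the motif's provenance sites.  Its null
distribution comes from refitting a same-width motif — one EM start,
chosen by the same candidate pre-scoring, same iteration cap — on
dinucleotide-preserving (Altschul–Erikson) shuffles of the same entry
set, `null_reps` (default 2499) times.  The E-value is
$n_\text{cand} \cdot (r+1)/(n+1)$ where $r$ counts null statistics at or
above $T$ and $n_\text{cand}$ is the number of candidates the search
considered (widths × starts), so it can never be zero and doubles exactly
when the candidate count doubles.  With the defaults the smallest
attainable E-value is $2/2500 = 8\times10^{-4}$, below the 0.001 filter.
Mind the interaction: a search over $k$ widths and $m$ starts has floor
$km/(\texttt{null\_reps}+1)$, so multi-width searches need `null_reps`
raised in proportion if their motifs are to survive the default filter.

Mirroring the observed fit's protocol in the null is what keeps it
approximately calibrated: on pure background data the fitted motif's
E-value exceeds 0.05 in most data sets (about four of five at the sizes
used in the tests; the multi-start Bonferroni factor is conservative,
the selection of the best start is not fully reproduced).  One
deliberate approximation remains,
and users should know it: for subsets produced by the *iterative* scheme,
the observed motif benefited from repeated selection over the whole input
set, which the null (a single fit on the same subset, shuffled) does not
reproduce.  Spurious fixed points can therefore reach small E-values.
The family stage is the intended guard — spurious motifs scatter into
singleton families while genuine ones accumulate — and the OOPS-refit
familial profile gets its own E-value, which catches weak profiles.

Null samples are expensive, so they are memoised: within a run (or across
runs that share a `null_cache` environment) motifs of the same width,
model (ZOOPS/OOPS) and entry-set size bucket (sets of up to 10 more
entries share a bucket, rounded up, which is conservative) reuse one
sample.  Under shuffling, sets of near-identical size drawn from one
background have near-identical null statistics; sharing the sample makes
a Monte Carlo run pay for each null distribution once.

## The scanner

A motif is scanned as a log2-odds matrix against $q$; the per-window
score distribution under the background is computed *exactly* by
integerizing scores at resolution 1/`scale` (default 1/1000) and
convolving column distributions, so each best hit gets an exact position
p-value.  The sequence-level p-value is
$1-(1-p)^{n_\text{pos}}$ with $n_\text{pos}$ the number of scanned
windows on both strands, and the sequence E-value is that times the
number of scanned entries.  An entry counts as containing a match when
its sequence E-value is at most `sig_evalue` (default 10, inclusive,
the conventional display threshold) **and** its best hit reaches the
instance-level gate `hit_pvalue_max` (default $10^{-4}$, the
conventional hit-display threshold).  The second condition matters
precisely because our p-values are exact: a calibrated sequence E-value
of 10 admits an *expected ten random entries per scan whatever the
motif*, and without the hit gate the related subsets of the Monte Carlo
schemes absorb cross-talk entries, drift into chimeric motifs, and
bridge families that should stay separate.  For short or weak motifs
whose best attainable p-value exceeds the gate (a 6-mer cannot beat
$4^{-6} \approx 2.4\times10^{-4}$), the gate relaxes to "perfect match
required" rather than making the motif unscannable.  Ties go to the
leftmost position, forward strand first; entries shorter than the motif
are skipped, never errors.

## The three related-subset schemes

1. **Subset-only** (`zoops_mc`): run the finder on the seed subset; the
   related subset is the entries whose subsequences built the motif.
   Members never leave the seed.  Convention: many cheap seeds (default
   500).
2. **Single scan** (`single_mast`): fit on the seed, scan the whole set
   once, take every significant entry.  The reported motif is rebuilt
   from the best hits inside the members so provenance is consistent.
   Default 200 seeds.
3. **Iterative** (`iterative`): alternate fitting on the current set and
   scanning the whole set, until the scan returns exactly the current set
   — a fixed point: the motif has significant instances in, and only in,
   its own subset.  Stops unconverged if the set shrinks below two
   entries, revisits a previous state (a cycle; the visited state with
   the best E-value is reported), or hits `max_rounds` (default 20; the
   cap and the cycle policy are engineering guards, since convergence is
   typical but not guaranteed).  Default 50 seeds.  This is the
   recommended scheme.

Seed subsets are drawn uniformly without replacement; the default seed
size is `max(8, ceiling(0.10 N))` (ten percent of the input, floored at
the conventional 8 entries).  Each seed runs under an RNG substream
derived from the master seed, so runs are reproducible end to end and a
rerun with the same configuration writes byte-identical artifacts.

## Tree, families, profiles, MotifMap

Retained subsets (motif E-value ≤ `evalue_max`; at most `top_k` = 200
best) are compared pairwise with the average log-likelihood ratio (ALLR)
column similarity under the best ungapped alignment over all offsets and
both orientations, requiring an overlap of at least half the narrower
width.  The alignment similarity $s_{12}$ is converted to a distance via
the motifs' self-similarity baseline:
$d = \max(0,\ (s_{11}+s_{22})/2 - s_{12})$.
The baseline matters: a realistic, entropy-bearing motif has mean
self-ALLR far below the theoretical maximum of $\max_b \log_2(1/q_b)$,
so subtracting a fixed offset would leave even identical motifs at an
apparently large distance and no relative clustering threshold could
separate families.  With the baseline, identical motifs are at distance
zero whatever their entropy; the quantity is symmetric, nonnegative, and
zero on delta motifs and their reverse complements (no triangle
inequality is claimed).

The distance matrix feeds a hand-rolled UPGMA (deterministic smallest-
leaf-index tie-breaks; heights are half the merge distance; cross-checked
against average-linkage `hclust` in the tests), exported as Newick via
`ape`.  Families are cut at `cluster_frac` (default 0.05) of the maximum
observed dissimilarity — merges at height up to that threshold stay
together; a zero threshold means no merging at all.

Each family's entries are ranked by **re-occurrence frequency** (the
fraction of the family's subsets containing the entry).  Entries at or
above `fp_threshold` (default 1.0, the conservative choice; `"auto"`
selects the grid value in $\{0, 0.1, \dots, 1\}$ with the smallest
profile E-value, ties to the larger threshold) are refit under OOPS —
the same EM with the site prior pinned at 1 and the no-site branch
removed — to produce the familial profile.  The OOPS refit is
warm-started from the family's own best motif in addition to the usual
candidate starts, so the profile condenses the family rather than
rediscovering from scratch.  Finally every valid profile is scanned over
the whole input; best-hit spans (1-based, inclusive) of significant
entries populate the MotifMap (one instance per cell by default;
`all_hits = TRUE` records ties).

## The synthetic generator and what the tests mean

`generate_planted(N, L, consensi, fraction, mut_rate, bg_order, ...)`
draws `N` length-`L` sequences from the background, then gives
`round(fraction * N)` entries per consensus exactly one instance at a
uniform offset and strand, each position independently mutated to a
uniform other base with probability `mut_rate`.  Ground truth (which
entries, where, which strand) is recorded, and the generator is
bit-reproducible from its seed.  The standard study conditions used
throughout the tests are: 60 entries of 300 nt, one 12-mer consensus,
10% per-position mutation, planted fractions 0.4 and 0.25, 30 seeds of
8 entries; and for family segregation, 40 entries of 100 nt with two
18-mer repeat motifs planted disjointly in 42% and 30% of entries (28%
motif-free), mirroring the group proportions of the published two-family
analysis this scenario emulates.  These sizes were chosen as the smallest
at which the corruption phenomenon is clearly expressed.

What passing these tests shows: that the pipeline separates a planted
signal from iid (or low-order Markov) background at realistic corruption
and mutation levels, that the iterative scheme's fixed points are genuine,
and that two distinct planted signals end in distinct families with
non-overlapping profile maps.  What it does not show: behaviour on real
genomic background (repeats, composition gradients, CpG structure),
motifs with strong positional dependencies, multi-instance entries
(planting is zero-or-one by construction, matching the ZOOPS assumption),
or widths far from those tested.

Entry-level recovery is scored with sensitivity $tp/(tp+fn)$,
specificity $tn/(tn+fp)$, and — following the convention of the framework
this package operationalizes — an **F-measure defined as the harmonic
mean of sensitivity and specificity**, *not* of precision and recall.
A reported motif covering fewer than 5% of the input entries can
optionally be scored as half a discovery (`half_discovery = TRUE`).

## Numerical and degenerate-input policy

* E-step posteriors are computed with a max-shift in log2 space; no
  underflow at any realistic width.
* N characters: excluded from background counting; windows overlapping an
  N score $-\infty$ and sites spanning an N contribute no counts.
* Entries shorter than the current width are excluded from fitting and
  scanning, silently at the entry level.
* Consensus ties break by the fixed order A < C < G < T.
* Empty results are contracts, not errors: a run on pure background
  returns an empty fit (with a warning) whose artifacts still serialize.
* All user-facing coordinates are 1-based inclusive; internal 0-based
  half-open.

## Known limitations

* The E-value is operational (shuffle-null), not MEME's analytic one;
  absolute values are not comparable across tools, only across motifs
  measured by this package, and the iterative-scheme liberality noted
  above applies.
* Order-0 nulls in the scanner; higher-order backgrounds affect only the
  finder through $q$ and the generator.
* ALLR is the only column metric and UPGMA the only linkage; the
  interfaces (`motif_distance`, `upgma_tree`) are pluggable by design.
* Single-motif ZOOPS fits on data carrying two dense motifs can converge
  to the union pattern — the degenerate motif with an instance in the
  entries of *both* groups — because that union genuinely maximizes the
  mixture likelihood.  Union fixed points form their own (statistically
  significant) family next to the two sharp ones, so two-motif inputs
  may yield three families rather than two; the sharp families still
  dominate and their profiles do not cross-map.  Suppressing union
  solutions would require a multi-motif model, which is out of scope.
* The MATLAB-era batch options (palindrome forcing, multiple motifs per
  finder run) are out of scope; multiplicity comes from many seeds.
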