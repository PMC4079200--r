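---
title: "Models and methods behind retroclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retroclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

retroclock analyses full-length LTR retrotransposon families: it finds
structurally intact copies, dates insertions and lineage divergences with
two molecular clocks, builds distance phylogenies, types recombinant
mosaics, and screens for horizontal transfer (HT). This vignette explains
the models, the parameters that matter, and the numerical and design
choices, in the package's own terms.

## The two clocks

**Insertion clock.** Retroviral-type integration copies the LTR so that a
new insertion has *identical* 5′ and 3′ LTRs and a duplicated 5-bp target
site (TSD). Both LTRs then evolve independently and neutrally, so their
Kimura 2-parameter (K2P) distance $k$ grows as $2 r_i t$, giving
$t = k / (2 r_i)$. The default intergenic rate is
$r_i = 3.3 \times 10^{-8}$ substitutions/site/year (maize *tb1* intergenic
region), appropriate for noncoding DNA in grasses. Assumptions: no gene
conversion between the LTRs, no selection on LTR sequence, and a host
lineage whose intergenic rate matches the calibration.

**Divergence clock.** Between element lineages the package uses the
synonymous distance $k_s$ of the polyprotein ORF, estimated by the
Nei–Gojobori method with Jukes–Cantor correction, and
$T = k_s / (2 r_s)$ with $r_s = 6.5\times10^{-9}$ substitutions per
synonymous site per year (grass *adh1/2* calibration, which assumes a
maize–rice split of 50 Ma). Synonymous sites are used because they are
nearly neutral even in a protein under purifying selection. The two
default rates differ about 5-fold (`rate_fold_difference()` reports
5.08), which is why insertion ages computed with the intergenic rate are
~5-fold lower than those computed with a synonymous rate.

Both conversions carry the factor 2: after a split (or an insertion),
*both* descendant sequences accumulate substitutions. The `age_estimate`
invariant `t_ma == k / (2 * rate * 1e6)` is enforced to 1e-9 and the
published $(k, t)$ pairs the tests assert (e.g. $k = 0.116 \to 1.757$ Ma)
validate the convention.

## Distance models

* `count_substitutions()` applies pairwise deletion: any site with a gap
  or `N` in either sequence is dropped. Transitions are A↔G and C↔T.
  IUPAC ambiguity codes other than `N` are mapped to `N` at read time so
  that "missing" has exactly one meaning downstream.
* K2P: $k = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$. Saturation
  ($1-2P-Q \le 0$ or $1-2Q \le 0$) is a hard error that names the failing
  log argument; `age_table()` downgrades it to a per-element `NA` with a
  warning, since genuinely ancient insertions are expected to saturate.
* Tamura 3-parameter adds a G+C correction via $h = 2\theta(1-\theta)$;
  $\theta$ is computed from the two compared sequences over compared
  sites only, in the same pairwise-deletion spirit. At $\theta = 0.5$ it
  reduces to K2P; the test suite checks this identity on 10,000 random
  $(P,Q)$ draws at 1e-12.
* Nei–Gojobori: per codon position, the synonymous-site fraction is the
  fraction of synonymous changes among *sense* single-nucleotide changes
  (changes creating a stop are excluded from numerator and denominator).
  This keeps $S + N = 3 \times$ codons exactly, which the tests enforce
  at 1e-9. Codons differing at 2–3 positions are resolved by averaging
  the $d!$ single-step pathways that avoid stop-codon intermediates; if
  every pathway crosses a stop, the unweighted average over all pathways
  is used as a documented fallback. Codon pairs containing gaps, `N`s or
  stop codons are excluded pairwise. The implementation is verified
  exhaustively against an independent pathway-enumeration oracle on all
  3,721 sense-codon pairs.
* Standard errors are bootstrap everywhere (columns for nucleotide
  distances, codons for $dS$/$dN$), 500 replicates by default, seeded and
  bit-reproducible. The choice of bootstrap rather than analytic
  variance follows the convention of distance software in this field.

## Neighbor joining and support

`nj_tree()` is the Saitou–Nei agglomeration with the standard
Q-criterion, written in-package so its tie-break is defined: among equal
Q minima the lexicographically lowest index pair is joined (this matters
only for degenerate matrices such as star phylogenies). Negative branch
lengths are clamped to zero and counted in the `clamped` attribute. The
tree is returned unrooted (basal trifurcation), so on an additive matrix
the leaf-path distances reproduce the input exactly; tests require
recovery of 100 random 4–12-taxon additive matrices with branch lengths
to 1e-9, and cross-check topologies against `ape::nj()` on perturbed
matrices.

`bootstrap_support()` resamples alignment columns (default 1,000
replicates), rebuilds the tree per replicate, and annotates each internal
edge of the *full-data* topology with the percentage of successful
replicates containing the same bipartition (the convention used when
supports are drawn on a single inference tree, rather than a majority-rule
consensus). Replicates with a saturated pair are dropped and counted.
Rows are canonically sorted by id first so supports are invariant to
input order at a fixed seed.

`assign_subfamily()` expects the query in reference-alignment
coordinates (the simulator emits true alignments; for real data, align
first with an external MSA tool). The winning group must beat the
runner-up by a margin (default 0.01 substitutions/site) or the query is
`unclassified`; queries covering under half the region are rejected.

## Recombination typing

`similarity_profile()` reproduces the classic SimPlot reading: percent
identity of a query against each candidate parent over sliding windows of
200 alignment columns, step 20. Only positions ungapped and unambiguous
in both sequences count, and a window is reported only when at least half
its columns are comparable — a fixed, documented gap rule. Window
coordinates live in alignment-column space with a back-translation map to
ungapped query coordinates.

`call_breakpoints()` assigns each window to its nearest parent; windows
with a winning margin under 2 percentage points are ambiguous. A
breakpoint requires the new assignment to persist for at least `min_run`
(default 3) informative windows, so isolated noise cannot create
breakpoints; the breakpoint is placed midway between the flanking
confirmed windows. Both thresholds are configurable — they codify what a
reader of a similarity plot does by eye.

`subdomain_typing()` is the coarser, domain-wise variant: the alignment
is cut into caller-supplied segments (the classical layout uses 13
LTR/polyprotein subalignments; the exact boundaries are data-dependent
and therefore an input, with the LTR/UTR/gag/PR/RT/RH/INT template
available from the element's `domain_map`). Each query segment is labeled
A or B by smaller mean p-distance to the parent groups; ties and segments
with fewer than 20 comparable columns are `ambiguous`.

`pairwise_identity()` uses a deterministic global alignment (match 1,
mismatch −1, gap open −4, extend −1) rather than local BLAST statistics —
adequate and reproducible at desk scale; identities are matches over
aligned columns.

## Horizontal-transfer screen

`ht_scan()` consumes per-pair element divergence times plus a host
divergence table and applies two complementary triggers:

1. **Fence rule** — Tukey box-plot outliers of the element-divergence
   distribution, quartiles by linear interpolation (R's default type 7);
   mild below $Q_1 - 1.5\,\mathrm{IQR}$, extreme below
   $Q_1 - 3\,\mathrm{IQR}$. The 3× coefficient is the conventional
   reading of "extreme outlier"; it is configurable.
2. **Ratio rule** — element divergence under half the host divergence
   (configurable), which still works when too few pairs exist for
   meaningful fences (fewer than 5 pairs skips the fence rule with a
   warning).

Both triggers are recorded separately per pair. Transfer *direction* is
deliberately not automated — it rests on qualitative similarity patterns
— and is left as an annotation field. `selection_check()` classifies
$dN/dS < 1$ as purifying; $dS = 0$ leaves the ratio undefined.

## Element finder

`scan_genome()` replaces a BLAST search with a deterministic seed-and-
chain: exact 13-mer anchors on both strands, chained by diagonal
consistency (±30 band, 1.5-kb maximum anchor gap), reported when the
chain spans at least half the query. Span coverage (not base-level
coverage) is the criterion because exact 13-mer survival at 80% identity
is only ~5% per window, while anchors still tile the whole element.
Candidate intervals are extrapolated to full query extent from the chain
diagonal.

`detect_ltrs()` locally aligns the candidate's head against its tail and
accepts a terminal-repeat pair at ≥100 nt and ≥70% identity. Because LTRs
terminate the element by definition and local alignment trims terminal
mismatches, repeat ends within 20 nt of the candidate termini are snapped
to them. `validate_tsd()` then compares the exact 5-bp flanks (zero
slack): at most one mismatch passes, the structural rule for an intact
in-situ insertion; `N`s count as mismatches. `call_full_length()`
composes the three steps and returns only candidates passing both checks,
with forward-strand genome coordinates and strand.

The finder is validated on synthetic 1-Mb genomes with planted copies at
80–95% identity to the query (lineage divergence applied first, then the
LTR reset of a fresh insertion plus up to 1 Ma of post-insertion
divergence — the structure a real recent insertion has): the tests demand
100% recall of intact copies, coordinates within ±5 nt, and zero
acceptances of 2-mismatch TSDs across 20 genomes.

## The simulator: what it emulates and what it does not

`simulate_cr()` is a master-copy forward simulation along an ultrametric
host tree (branch lengths in Myr). Per subfamily one active master
lineage exists per host branch; retrotransposition (Poisson, default 0.2
insertions/lineage/Myr) copies the master, resets the LTRs and stamps the
true insertion time; copies keep mutating until the present but do not
transpose. Speciation duplicates all lineages into both daughter
branches. A scheduled HT event captures the donor master mid-branch,
resets its LTRs (the transferred element reinserts) and replaces the
recipient's master, so the cross-host pair divergence truth equals the
event time.

The substitution process is K2P-like with transition:transversion 2:1 and
uniform base frequencies. Noncoding positions are sampled *exactly* from
the Kimura transition probabilities at $r_i$ — no event loop, no
approximation — so LTR dating is estimator-consistent by construction
(the tests regress estimated $k$ on true age over 100 elements and
require a slope within 10% of $2 r_i$). Coding positions evolve by
proposal–rejection at the synonymous rate $r_s$: synonymous proposals are
always accepted, nonsynonymous ones with probability $\omega$ (default
0.2), stop-creating ones never. This calibrates the synonymous clock to
$r_s$ and produces a realistic purifying-selection signal with measured
$dN/dS$ monotone in $\omega$, without the cost of a full codon rate
matrix.

Deliberate simplifications, hence what passing tests do *not* show about
real data: uniform base composition (no GC gradients — T3P and K2P
coincide in expectation here); no indels, so simulated alignments are
exact and column-filtering/alignment error is never exercised; no nested
insertions or element decay (an old element is purged by saturation of
its clocks, not by structural erosion); copies inherited through a later
speciation are evolved independently per descendant tip (their cross-host
divergence is not used as truth); founders of different subfamilies are
unrelated random sequences, so between-subfamily distances are
saturated noise. Generator defaults (element ~7.7 kb with ~1.2 kb LTRs,
ORF ~4.1 kb; hosts splitting 50 Ma; HT at 4 Ma; 11 subfamilies for the
HT experiments) mirror the scale of the grass CR system; the
transposition rate and $\omega$ defaults are chosen for testability, not
as biological estimates.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally, 1-based inclusive in all
  human-readable output.
* Every stochastic operation takes an explicit seed; the simulator's
  randomness flows from one root seed (pipeline stages derive child seeds
  by stage-name hashing), and same-seed runs are byte-identical.
* Saturation is an error wherever a distance is a primary result
  (`distance_matrix()` names the offending pair) and a skip-with-warning
  wherever a summary spans many pairs (`group_mean_ks()`,
  `age_table()`); bootstrap replicates that saturate are dropped and
  counted.
* Empty alignments, empty groups, missing host pairs, sub-50-nt LTR
  overlap and queries covering under half the reference region are
  defined errors, not silent results.
* At deep divergence ($k_s \gtrsim 0.65$, i.e. host splits ~50 Ma at the
  default rate) the Jukes–Cantor correction under a K2P-generating
  process is upward-biased; the HT screen is unaffected (it compares a
  young outlier against old peers) but absolute deep divergence times
  should be read with that bias in mind. The cross-host validation test
  therefore uses a wide acceptance band around the 50-Ma truth.

## Problem sizes used by the validation suite

The test and acceptance runs use: all 3,721 sense-codon pairs for the
Nei–Gojobori oracle; 100 additive matrices of 4–12 taxa for NJ; 50
elements with 1,200-nt LTRs and ages U(0, 2) Ma for insertion dating
(median absolute relative error ≤ 15%); 100 HT and 100 no-HT two-host
simulations with 11 subfamilies for detection power (≥ 95% power,
≤ 5% false-extreme rate); 100 mosaics of ~7-kb parents ≥ 5% diverged for
breakpoint recovery (≥ 90% within ±40 columns); and 20 synthetic 1-Mb
genomes with six planted insertions each for the finder. These sizes make
the whole suite run in minutes on one CPU while keeping each estimate's
sampling error well inside the asserted margins.
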