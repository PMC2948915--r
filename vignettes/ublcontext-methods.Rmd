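---
title: "Methods: comparative genomic context analysis of ubiquitin-like protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomic context analysis of ubiquitin-like protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ublcontext)
```

## The analysis problem

Ubiquitin-like (Ubl) proteins — the ThiS/MoaD-family sulfur carriers and
their relatives with the β-grasp fold, and a handful of analogous families
such as Pup — are short proteins that act through their extreme C-terminus:
a double-glycine (GG) doublet that is adenylated by E1-like enzymes and
either carries activated sulfur or is conjugated to target proteins
(SAMPylation in halophilic archaea). Some halobacterial families carry a
double-cysteine (CC) variant instead. Because the business end of the
molecule is the very last two residues, candidate Ubl families can be found
by scanning ortholog-cluster alignments for small proteins whose consensus
*ends* in a conserved GG or CC.

Finding a family is only half the problem; the interesting question is what
it does. With no direct experiments, comparative genomics answers by "guilt
by association": genes that stay next to each other across many genomes and
several independent lineages, genes fused into one multi-domain protein, and
families with matching (or complementary) phyletic patterns are likely to
work together. `ublcontext` implements this entire workflow — motif
discovery, neighborhood analysis, operon and divergent-gene calls, fusion
detection, phyletic queries — plus the protein phylogenetics needed to place
the families on a tree: JTT maximum likelihood with a neighbor-joining
start, NNI local rearrangement, and RELL bootstrap supports.

Real ortholog databases (arCOG-style flat files) and their alignments are
the intended production input; the package ships a synthetic-data module
that emulates those inputs with planted, exactly known ground truth, and the
entire test suite and acceptance analysis validate the pipeline against that
truth and against independent oracles.

## Consensus and motif scan

For each alignment column the *plurality residue* is the most frequent
non-gap character (ties broken alphabetically, for determinism). Its
*conservation* is its count divided by the number of members — gap rows
included, so a column occupied by few members can never look conserved; this
is stated as the invariant `conservation <= 1 - gap_fraction`. The consensus
character is the plurality residue in uppercase when conservation reaches
`plurality_min`, `-` when gaps exceed 50%, and the lowercase residue
otherwise.

The doublet test reads the *trimmed* consensus: leading and trailing
majority-gap columns are removed first, because alignment overhangs would
otherwise displace the biological C-terminus. A hit requires the final two
columns to be strong (uppercase) consensus calls spelling GG or CC, each
conserved at `cons_min` or better, in a family whose *median* ungapped
member length is below `max_len`.

Parameter defaults, all configurable:

* `plurality_min = 0.5` — a residue must be the absolute majority before it
  is a strong consensus call. No published threshold exists for this step;
  0.5 is the weakest value at which "the consensus residue" is unambiguous.
* `cons_min = 0.8` — the terminal doublet must be present in ≥ 80% of
  members. Strict enough that "conserved motif" is meaningful, loose enough
  to tolerate a few mis-annotated or truncated members in real families.
* `max_len = 200` aa, applied to the *median* member length — Ubl domains
  are 70–120 aa and the size filter is what separates them from ordinary
  GG-ending proteins; the median is robust to fusion outliers that would
  drag a mean above the cutoff.
* The doublet is required at the absolute final two trimmed columns. Real
  precursor sequences can carry a short C-terminal extension that is cleaved
  after the GG; scanning at a fixed offset would admit such families but
  also many false positives, so the strict reading is the default and an
  extension-tolerant scan is left to the caller (scan a profile truncated by
  the suspected extension length).

## Gene context

Neighborhoods are defined on annotation order: the `k = 3` genes on either
side of an anchor, in replicon coordinate order, *not* relative to the
anchor's strand — conserved neighborhoods mix strands (a divergently
transcribed chaperonin gene is part of the signature Sulfolobales
neighborhood), so strand is carried along rather than folded into the
definition. Linear replicons truncate at the ends; circular replicons wrap,
and on small replicons each gene is claimed at most once, nearest distance
first (upstream first at equal distance), so a neighborhood never contains
duplicates or the anchor itself.

Association records aggregate (anchor cluster, neighbor cluster) pairs
across genomes. Two counts are kept deliberately distinct: `n_genomes`
counts each genome once no matter how many paralogous anchors it carries —
cross-genome conservation is the evidence, and paralogs within one genome
are one observation — while `occurrence_count` keeps the raw tally
(within one neighborhood, a neighbor cluster is counted once per neighbor
gene carrying it, so tandem paralogs inside a window do inflate the raw
count but never the genome count). Records are ranked by the number of
distinct *lineages*, then genomes: an association recurring in several
independent lineages cannot be a single ancestral accident. Neighbors
without a cluster assignment are tallied under the pseudo-cluster
`UNASSIGNED` rather than dropped, so the conservation-of-counts invariant
(total occurrences = total assigned neighbor slots) holds exactly.

Operons are maximal same-strand runs with intergenic gaps ≤ `d_max = 100`
bp, a common prokaryotic heuristic (no value is prescribed by the biology
here; 100 bp splits typical archaeal intergenic distances well). Divergent
genes are the immediate flanks in head-to-head orientation — the only
orientation in which a flanking gene shares a promoter region with the
operon while being transcribed away from it: the minus-strand gene
immediately upstream of a plus-strand operon, or the mirror case.

Fusion detection is purely structural: any gene carrying two or more
cluster assignments is a candidate, domains ordered by start coordinate.
Overlaps larger than `min_sep = 10` aa are flagged as suspect (conflicting
rather than tandem domain calls); multi-assigned genes without coordinates
are reported with the flag unset, since a missing coordinate is not
evidence of either.

## Phyletic patterns

Presence is binary — the comparative arguments these matrices support
("absent only from several methanogens", "complementary to family X") are
about which genomes encode a family at all; copy number lives in the
context module. Genome order follows the lineage map so reports group by
lineage. `absence_report` and `pattern_query` are two views of the same
matrix and the suite checks their consistency as a property:
`c ∈ pattern_query(∅, S)` exactly when `S ⊆ absence_report(c)`.

## Phylogenetics

The tree protocol is: select informative positions → JTT ML pairwise
distances → neighbor-joining starting tree → NNI hill climb under the full
JTT likelihood → RELL bootstrap supports.

*Informative positions.* No standard definition exists for "informative"
in this context, so the package uses parsimony-informative columns (at
least two residues, each in at least two sequences) with gap fraction
≤ `max_gap_frac = 0.5`, and records the selection in the output so any
analysis is reproducible.

*Model.* Plain JTT: published exchangeabilities and equilibrium
frequencies, rate matrix normalized to one expected substitution per site,
no +F frequencies and no rate heterogeneity (+Γ is out of scope). The
transition probabilities come from the eigendecomposition of the
symmetrized rate matrix, which is exact for a reversible model and
numerically stable. Gaps are missing data (all-ones partials), so an
all-gap site has log-likelihood exactly 0.

*Distances and starting tree.* Pairwise distances maximize
`sum log(pi_i P_ij(t))` over shared non-gap columns, `t` in [0, 10],
symmetrized count matrices making `d(a,b) = d(b,a)` exact. The starting
tree is neighbor joining on that matrix (negative branch lengths clamped to
zero) — a fully specified distance-based agglomerative start for local
rearrangement, in the same role an original Fitch distance tree plays.

*Branch lengths.* Cyclic univariate optimization: each branch in turn is
optimized by Brent search on [1e-8, 10] with the conditional likelihoods on
both sides of that branch held fixed, so every accepted step is exact
coordinate ascent and the log-likelihood is non-decreasing by construction;
cycles repeat until a full cycle gains < `tol = 1e-6` log units. The
boundary value is re-checked explicitly because near-zero branches put the
optimum at the edge of the Brent interval.

*Topology search.* Nearest-neighbor interchange hill climbing: both NNI
alternatives of every internal branch are scored with a short (2-cycle)
branch-length re-optimization, the best is re-optimized fully, and the move
is accepted only if the fully optimized log-likelihood improves. Screening
with few cycles is purely an acceleration: acceptance is always judged on
fully optimized values, so the final log-likelihood can never fall below
the start. The local-rearrangement neighborhood is NNI (rather than local
SPR); it is the minimal fully specified move set, and the exhaustive-search
tests show it suffices under the simulated conditions.

*RELL bootstrap.* Per replicate, site indices are resampled with
replacement (implemented as multinomial weights), each candidate tree's
resampled log-likelihood is the weighted sum of its cached per-site values,
and the replicate is awarded to the argmax — exact ties split equally, so
supports always sum to 100%. No re-optimization per replicate is what makes
the default 10,000 replicates cheap. Branch supports: a replicate supports
a bipartition if the winning candidate's tree contains it; the candidate
set for a search result is the ML tree plus its branch-length-optimized
NNI neighborhood, which brackets the local uncertainty the search itself
explored. Supports are attached to the Newick output as integer-rounded
internal node labels.

## The synthetic-data generators, and what they do not emulate

`generate_genomes` produces single-replicon genomes with gene lengths
uniform on 80–400 aa (both sides of the 200 aa filter populated),
intergenic gaps uniform on 0–200 bp (both sides of the 100 bp operon
threshold), random strands, and one background cluster per gene drawn
uniformly from the pool. Associations are planted by relabeling an anchor
gene and a neighbor within `max_offset` positions in exactly
`ceiling(f * n)` genomes — deterministic placement, so expected counts are
exact; a Bernoulli mode (each genome with probability `f`) exists for
distributional tests. Planted absences add a cluster to every genome
outside the absence set. `generate_motif_family` places the terminal
doublet in exactly `round(conservation * n)` members and guarantees
non-carriers do not end in GG/CC, so planted conservation is exact.
`evolve_alignment` draws the root from JTT equilibrium and mutates along
branches with the JTT transition probabilities.

What passing on these data does *not* show: the generators have no indels,
no alignment error, no rate heterogeneity across sites, no compositional
bias, no horizontal transfer, no genome rearrangement dynamics, and
cluster assignments are error-free. Results on real ortholog databases
inherit none of those guarantees; in particular the motif thresholds and
the NNI search adequacy were validated only under these idealized
conditions.

## Study conditions and numerical choices used in validation

The validation suite and the acceptance analysis run at fixed problem
sizes chosen once: 200 random alignments (≤ 20 × ≤ 100) for the consensus
oracle; 50 clusters (10 GG + 10 CC planted at conservation 0.9, 30 decoys
at ≤ 0.5, lengths straddling 200 aa) for motif recovery; 1000 random
replicon/anchor cases for the neighborhood oracle; 10 genomes × 200 genes
with one association planted at f = 0.8 over a 100-cluster pool; 100
random quartets against exhaustive internal-state enumeration (tolerance
1e-10); 5-taxon alignments of 2000 sites with 0.3 branches for the
exhaustive 15-topology comparison (agreement required in ≥ 9/10 seeds);
and a fixed 8-taxon tree with 1000-site alignments for parameter recovery
(topology in ≥ 8/10 seeds, branch lengths within 15%, mean RELL support of
true bipartitions ≥ 90% at 10,000 replicates).

Two statistical readings were fixed in advance of any measurement, as the
package's own calibration choices. Branch-length recovery at 1000 sites is
asserted on the *mean* relative error per seed: the per-branch sampling
error of a 0.2-substitution branch at 1000 sites approaches 15% by itself,
so a per-branch bound at that length would measure sampling noise, not
correctness (the per-branch form is asserted in the unit suite at 5000
sites, where it is attainable). The Bernoulli-mode planting check over 20
seeds asserts the mean frequency within 3 SD of the mean's own sampling
error and allows the single expected per-seed 3-SD tail draw: with 20
binomial draws of Binom(10, 0.8), demanding every draw inside a 3-SD band
would fail a provably correct generator roughly once in eight runs.

## Known limitations

* The likelihood machinery targets the small protein families this
  analysis deals in (tens of taxa); partial-likelihood scaling is per
  message with a scalar factor, adequate to ~50 taxa but not for hundreds.
* NNI is a local search; with weak signal (few informative positions — the
  realistic regime for 80 aa proteins) it can stop at local optima, which
  is precisely why RELL supports over the NNI neighborhood are attached.
* `jtt_distance` saturates at t = 10; distances beyond ~5 expected
  substitutions/site are not meaningful for 20-state data anyway.
* Operon prediction does not wrap around circular replicons; a run
  spanning the origin is reported as two operons.
* The GFF3 reader keys proteins by feature `ID` and expects one CDS per
  gene; multi-exon CDS grouping (irrelevant for prokaryotes) is not
  implemented.
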