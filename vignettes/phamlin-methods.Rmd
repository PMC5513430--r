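---
title: "Comparative phage genomics with phamlin: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative phage genomics with phamlin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phamlin)
```

# The analysis

phamlin implements the comparative workflow used to characterize newly
isolated phage collections: all predicted proteins are grouped into
phamilies ("phams") by amino-acid similarity; genomes are compared by
exact-word dotplots and fragment-based average nucleotide identity (ANI);
genomes are then assigned to clusters and singletons; and the pham
presence/absence structure yields gene-content distances, split-network
exports, and per-cluster diversity statistics (cluster-identifier phams,
orphams, inter-cluster and cross-host sharing).

Phage genomes are pervasively mosaic: genes move between otherwise
unrelated genomes, so no single gene tree describes the population. The
workflow therefore works at two levels that deliberately do not have to
agree: nucleotide-level comparison (dotplots, ANI) defines clusters of
recently related genomes, while protein-level comparison (phams) captures
the longer reach of horizontal exchange. The interesting biology — and the
statistics in the diversity report — live in the gap between the two.

# Pham construction

Two proteins are linked when a local (Smith–Waterman) alignment under
BLOSUM62 (gap open 11, extend 1) reaches **percent identity ≥ 32.5** over
aligned columns (gap columns count) **and coverage ≥ 0.5** of the shorter
protein. Phams are the connected components of this graph — single linkage,
so a chain A–B–C forms one pham even when A and C are not directly linked.
This follows the conventions of the Phamerator lineage of tools; both
thresholds are exposed (`pham_params()`) because published analyses have
used slightly different settings over the years.

Local rather than global alignment is deliberate: mosaic proteins share
domains, and a global aligner would score multi-domain relatives poorly.
The coverage guard is what keeps a single promiscuous domain from chaining
the whole proteome into one pham.

*Percent identity* is identical residue pairs over aligned columns
including gaps (`PID1`); *coverage* is the aligned span on the shorter
protein divided by its length, so a clean containment scores 1.

An all-vs-all alignment over thousands of proteins is dominated by pairs
that share nothing. A shared-4-mer prefilter (inverted index, floor of one
shared distinct 4-mer) can skip those pairs. It is opt-in
(`pham_params(prefilter = TRUE)`) rather than the default, because an
exact k-mer filter can in principle miss a borderline pair — two proteins
at ~33% identity need not share any exact 4-mer — and the package
guarantees by default that pham components are exactly the transitive
closure of the thresholded all-vs-all matrix. The test suite verifies that
on simulated collections the filtered and unfiltered runs produce
identical pham tables; on a corpus of your own, verify the same before
relying on it.

Pham identifiers are content-derived — components ordered by decreasing
size, ties by smallest member id — so identical inputs always produce
identical tables.

An external reference set (proteins of phages infecting other host genera,
FASTA with `[genus=...]` header tags) can be attached afterwards: each
external protein joins the pham of its best edge above the same thresholds,
or is ignored. The internal partition never changes. A pham is an **orpham**
when it holds a single gene from a single phage and has no external member;
without an attached reference the definition degrades to "internal
singleton pham" and the report says so.

# Nucleotide comparison

**Dotplots** report every shared exact `w`-mer in both orientations
(default `w` = 10), the content of a Gepard-style plot without the
rendering; `plot()` draws it.

**Fragment ANI** follows the JSpecies-lineage scheme: the query is cut into
consecutive 1,020-bp fragments (last kept if ≥ half size; a genome shorter
than one fragment is compared whole); each fragment is matched to its best
location in the subject on either strand; fragments are retained when the
alignment covers ≥ 70% of the fragment at ≥ 30% identity. ANI is the mean
identity of retained fragments on the 0–1 scale, reported with the
companion `aligned_fraction` (retained/total). Directions are computed
separately and symmetrized by averaging, so ANI(a,b) = ANI(b,a) exactly,
and self-ANI is exactly 1.

The implementation seeds each fragment with exact 13-mers (sampled every 6
positions) and votes on the diagonal offset. A fragment whose seeds sit on
one dominant diagonal is scored by direct ungapped comparison at that
offset — for a clean match (≥ 90% identity) that comparison *is* the
answer; below it, the best ungapped local run (match +1 / mismatch −1)
decides retention. Only fragments whose seeds spread over several diagonals
(indels) or that hit the subject edge go through gapped local alignment in
a padded window. Gap costs there are deliberately expensive (open 5,
extend 2): a fragment overlapping a gene-content difference should align
only its homologous part and let the coverage rule judge it, not pass at
gap-diluted identity. Two consequences worth knowing:

* fragments spanning an insertion/deletion junction are usually unretained —
  that lowers `aligned_fraction`, not ANI, which is the intended division
  of labor between the two statistics;
* seeding sets a detection floor: pairs below roughly 70–75% nucleotide
  identity report ANI ≈ 0 rather than a small number. Cluster membership
  decisions happen far above this floor, and relationships below it are
  exactly what the dotplot and pham levels are for.

**Similarity segments** (for genome-map shading) are ungapped diagonal
runs: exact 12-mer matches on a common diagonal merged across gaps ≤ 100 bp,
kept when ≥ 200 bp and ≥ 60% identity, selected greedily by score with
overlap suppression on the first genome only (so duplications in the
second genome remain visible). An indel splits a segment in two, which is
the correct granularity for map coloring.

# Cluster assignment

Genomes are joined by an edge when symmetrized **ANI ≥ 0.60 and aligned
fraction ≥ 0.50**; clusters are connected components with ≥ 2 members,
everything else is a singleton. Single linkage mirrors the clustering
conventions of the actinobacteriophage literature. Shared-gene-content can
be enabled as a corroborating edge (`t_gene`), but is off by default: the
known behavior of related-but-separate clusters — substantial gene sharing
(~25–30%) with ANI below 0.6 — must *not* merge them, and ANI-primary
defaults guarantee that. Labels (AK, AL, ... by default, continuing the
lettering already in community use) are cosmetic; equivalence to any
published partition is judged by structure, not names.

`intra_cluster_ani_summary()` reports min/mean/max intra-cluster ANI and
raises a report-only flag when the minimum drops below 0.70 — a hint that a
cluster might warrant subdivision, never an automatic split.

# Gene content and diversity

The presence/absence matrix has one row per genome and one column per pham.
The default distance is the Jaccard distance on pham sets (computed via
`stats::dist(method = "binary")`), which is a proper metric; a
"shared-fraction" alternative (1 − mean directional shared fraction) is
available. Since split-network software applies its own transform to
binary characters, the NEXUS export ships the raw binary CHARACTERS block
as well as a DISTANCES block; neighbor-joining trees (via `ape::nj`, with
negative branches clamped to 0) are exported as newick.

Diversity statistics use the **cluster pham universe** (distinct phams
across members) as denominator throughout:

* *cluster-identifier phams*: present in every member, absent from all
  other study genomes (not computed for singletons);
* *orpham percent*: orphams among the universe;
* *inter-cluster shared percent*: universe phams present in ≥ 1 phage of
  another cluster/singleton of the study set;
* *cross-host shared percent*: universe phams with ≥ 1 external member.

Identifier and inter-cluster-shared sets are disjoint by construction, and
all statistics are invariant to genome order and pham relabeling — both
property-tested.

# The synthetic pangenome generator

Downloading deposited genomes cannot be a prerequisite for testing an
analysis pipeline, so the generator plants the statistical structure the
analysis assumes and emits a truth table for every planted feature.

Each cluster (and singleton) is a *unit* with: a GC target, a core pham
set carried by every member, an accessory pool, member-private orphams,
and an ancestral gene order. Defaults: 4 clusters of 3–6 genomes plus 2
singletons; 12–14 genes per genome of lognormal length (median ~220 aa);
core fraction 0.9; orpham rate 0.08; inter-unit pham sharing 0.02; GC
targets spread evenly over 0.45–0.68 — the span observed across real phage
collections, whose GC tracks phage lineage rather than host.

Design choices that matter to interpretation:

* **Proteins first.** Random proteins (residues tilted toward GC-rich or
  GC-poor codon families, plus a mild dipeptide smoother) are
  reverse-translated with codon choice tilted to the unit's GC target; the
  tilt is solved numerically against the pooled residue composition of the
  unit. Realized genome GC lands within ±2 points of target for ≥15-kb
  genomes (property-tested). A purely uniform residue composition caps
  coding GC at ~63%, which is why the composition itself must shift for
  high-GC units — as it does in real high-GC organisms.
* **Cassette inheritance.** A gene travels with its downstream intergenic
  spacer, and strand is an ancestral property. Members of a cluster are
  therefore collinear and homologous wherever they share genes, which is
  what real cluster members look like.
* **Divergence.** The configured intra-cluster rate is the target
  *pairwise* divergence; each member lineage mutates at half that rate from
  the ancestor, so two members diverge by the configured rate (realized
  identity is recorded in the truth table). Substitutions draw replacements
  from the target-GC base composition and never create internal stop
  codons, so translations stay valid and GC stays put.
* **Accessory carriage is nested** (prevalence-ordered): members carry a
  prefix of the accessory pool, so content differences between members are
  few — matching the observation that real cluster members differ by a
  handful of insertions, not by wholesale reshuffling.
* **Orphams and realized truth.** Orpham truth is computed from the
  realized collection: any pham ending up with one gene in one genome and
  no external homologue. External reference proteins are generated over
  realized phams (mutated copies tagged with a host genus).

One caveat on planted truth: at extreme GC targets the composition tilt
concentrates the residue alphabet, and two planted-unrelated proteins can
then occasionally reach the pham edge thresholds by chance. Planted pham
and orpham structure is therefore recovered up to rare chance linkages,
and truth-comparison checks that span arbitrary seeds report agreement
fractions rather than demanding exact equality.

What the generator does *not* emulate: real virion-gene synteny,
recombination breakpoints, repeats and tRNA arrays, sequencing error, and
indel-level divergence within shared genes (substitutions only). Tests
passing on synthetic data therefore demonstrate the statistical machinery —
recovery of planted partitions, calibration of ANI against known
divergence, exactness of the set-arithmetic statistics — not robustness to
every artifact of real assemblies.

# Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally; GenBank I/O converts
  to/from 1-based inclusive at the file boundary. Compound
  (`join(...)`) CDS locations are collapsed to their envelope with a flag —
  the genomes this pipeline targets are unspliced, so the envelope is a
  safe fallback.
* `%GC` excludes `N` and IUPAC ambiguity codes from numerator and
  denominator, and is undefined (an error) on an all-ambiguous sequence;
  the metrics table rounds to one decimal.
* Translations: a curated `/translation` qualifier is trusted verbatim;
  otherwise the span is translated with the bacterial code (table 11),
  trailing stop trimmed, internal stops mapped to `X`.
* Ties everywhere break lexicographically (pham ids, cluster labels, NJ
  joins via `ape`), making every stage deterministic; the pipeline writes a
  manifest (inputs with MD5 checksums, full parameter echo, seed) and
  re-running a manifest reproduces byte-identical tables.
* All randomness in the generator flows from one seed through R's global
  generator.

# Problem sizes used in the test suite

The suite exercises the full pipeline at desk scale: collections of ~20
genomes of ~10 kb (≈ 260 proteins) for end-to-end recovery, 30-protein
corpora against a brute-force transitive-closure oracle, 10-seed ANI
calibration runs, and constructed universes of ≤ 200 phams for exhaustive
diversity checks. These sizes were chosen so each property runs in seconds
to a few minutes on one CPU while still containing every structural
feature (clusters, singletons, shared phams, orphams, external homologues)
the statistics must handle.

# Known limitations

* ANI below the seeding floor (~0.7) is reported as 0/unaligned; the
  cluster threshold (0.6) sits near that floor, so genuinely borderline
  pairs should be inspected with `similarity_segments()` or a dotplot.
* The pham prefilter can, for adversarial borderline pairs, differ from an
  unfiltered run (documented above; disable with
  `pham_params(prefilter = FALSE)` to be certain).
* `attach_external()` credits an external protein to its single
  best-scoring pham even if it passes thresholds to several — external
  counts are per-pham attributions, not a full homology map.
* Compound CDS locations lose their intron/exon structure (envelope
  collapse); fine for phage genomes, wrong for spliced genes.
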