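---
title: "Methods: genetic-code-aware taxonomy of megaphage genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic-code-aware taxonomy of megaphage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phagetax classifies uncultured phage genomes — in particular the very large
("mega") phages recovered from gut metagenomes — into nested taxonomic ranks
using only their sequences. This vignette is the package's account of the
method: the models behind each stage, the parameters that matter, what the
synthetic validation data do and do not establish, and the design decisions
taken where the problem was genuinely open.

## The problem

Megaphage clades pose two practical obstacles to standard genomic taxonomy.
First, many members repurpose the TAG stop codon to encode glutamine
(translation table 15), so gene callers and pangenome tools that assume the
standard bacterial code (table 11) fragment their genes; worse, a single
analysis may mix recoded and standard-code genomes. Second, their genome
size defeats several virus-specific similarity tools. phagetax therefore
(i) detects the genetic code per genome before any protein-level analysis,
and (ii) computes intergenomic similarity by a fragment-based method whose
cost is linear in genome length.

The pipeline (`run_taxonomy_pipeline()`) runs: code assignment → ORF
prediction under the assigned code → protein clustering (pangenome) →
family assignment → per-family core-protein phylogeny → fragment-based
similarity → rank demarcation.

## Genetic-code detection via coding-capacity differentials

Coding capacity is the summed length of predicted, non-redundantly selected
ORFs as a percentage of genome length. A genome that reads TAG as glutamine
has its genes interrupted by spurious in-frame "stops" under table 11, so
its capacity rises sharply when re-predicted under table 15; a
standard-code genome shows essentially no differential. The detector
computes `delta = cc15 − cc11` with identical ORF-calling parameters and
assigns table 15 when `delta ≥ 10` percentage points (`delta_threshold`).
On recoded and standard genomes the two regimes sit around +15 to +25 and
−1 to +2 points respectively, so the 10-point default sits between them
with a wide margin on both sides.

The ORF caller is deliberately rule-based rather than statistical, because
the capacity statistic needs determinism, symmetry between the two codes,
and nothing else. In each of the six frames, every stop-delimited interval
contributes at most one ORF, from the first in-frame start codon to the
codon before the stop (contigs are linear; an interval may end at the
contig edge). Two conventions matter:

* **Start codons.** The default start set is `{ATG}` alone. With a
  first-start rule, admitting GTG/TTG (as trained gene finders do) lets
  translation "restart" within a handful of codons after every spurious
  table-11 stop — valine and leucine codons are frequent — which refills
  most of the capacity lost to gene fragmentation and compresses the
  recoded-genome differential from ~20 points to ~11, uncomfortably close
  to the threshold. Scoring gene finders avoid this by penalising the
  resulting fragments; a rule-based caller cannot, so it restricts the
  start set instead. The set remains a parameter (`start_codons`).
* **Interval convention.** Reported ORF coordinates and `length_nt`
  exclude the stop codon; the minimum-length filter (`min_orf_len`,
  default 90 nt) applies to the start-to-stop span *including* the stop.
  Codons containing ambiguous bases translate to X and never act as starts
  or stops.

Because six-frame calling over-predicts, capacity uses a greedy
longest-first selection (`select_orfs`): an ORF is kept iff it overlaps
every already-kept ORF by at most `max_overlap` (default 30 nt,
approximating the limited gene overlap seen in real annotations); ties on
length break by smaller start, then by plus strand. This guarantees summed
lengths cannot exceed genome length and makes capacity strand-symmetric.

## Code-aware pangenome

Predicted proteomes (each genome translated under *its own* assigned
table — the capability that existing pangenome tools lack for mixed-code
inputs) are clustered at an amino-acid identity threshold with
connected-component semantics: an edge joins two proteins when global
identity ≥ `identity_threshold` (default 70 %) and the aligned span covers
≥ `coverage_threshold` (default 0.8) of *both* sequences; clusters are the
components, so chains of near-threshold pairs merge transitively.

Identity is defined over a global alignment with free terminal gaps
(BLOSUM62, gap open 11, extend 1): `100 × matches / aligned columns`, gap
columns included; coverage of each sequence is its aligned span divided by
its length. Free end gaps make coverage informative — a strict end-to-end
alignment would force coverage to 1 and void the threshold.

Two exact optimisations keep all-vs-all clustering at desk scale without
changing results (asserted against a brute-force union-find oracle and
against prefilter-off runs in the test suite): identical sequences are
aligned once and their edges expanded afterwards, and only pairs sharing at
least one amino-acid 6-mer are aligned. At 70 % identity a true edge pair
shares dozens of 6-mers, while unrelated proteins almost never share one;
the word size is a parameter (`k`) for use at lower thresholds.

Core clusters of a genome set are those with ≥ 1 member in every genome.
Cluster functions are majority votes over member annotations (ties broken
lexicographically and flagged); the presence/absence structure can be
summarised as an average-linkage dendrogram over Jaccard distances between
genome profiles.

## Family assignment and the outlier diagnostic

Families are connected components of the genome graph whose edges are
"shares ≥ 1 protein cluster at the working identity threshold". A genome
sharing nothing with anyone becomes its own family — the signature of a
proteome-level outlier. For such genomes `outlier_link_threshold()` scans a
descending identity grid (5-point steps) and reports the highest level at
which the outlier's proteome gains a qualifying edge to any other genome,
distinguishing a deeply divergent relative (connects at low identity) from
an unrelated contaminant (never connects).

## Core-protein phylogeny and subfamilies

For each multi-genome family, every core cluster contributes one
representative per genome (the longest member, collapsing paralogs); the
representatives are aligned with MAFFT (progressive FFT-NS-2, deterministic
for fixed input) and the alignments concatenated, with all-gap blocks where
a genome lacks a representative and partition boundaries recorded.
Distances are Poisson-corrected p-distances (`d = −ln(1 − p)`) with
pairwise deletion of gap/ambiguous columns — complete deletion would
discard most columns of a concatenation containing all-gap blocks.
p ≥ 0.95 is clamped (with a warning) to keep the correction finite.

The tree is canonical neighbor joining — exact on additive matrices, which
the test suite verifies up to eight taxa — with negative branch lengths
zeroed and their excess moved to the sibling edge. Distance-based NJ
replaces model-fitted maximum likelihood here as a deliberate method
substitution: the load-bearing output at this stage is the topology of deep
splits, determinism matters for reproducible rank assignment, and NJ is
orders of magnitude cheaper. Support comes from a column-resampling
bootstrap over the full distance+NJ pipeline (default 100 replicates,
configurable; seeded, so identical seeds give identical supports), and the
tree is midpoint-rooted, which preserves all leaf-to-leaf path lengths.

Subfamilies are the two child clades of the family root, accepted only when
the root bipartition's support reaches `min_subfamily_support` (default 95,
matching the convention of reporting only strongly supported splits);
otherwise — or when the family is too small to carry an internal edge — the
family remains one subfamily with a warning. There is no numeric
demarcation criterion between subfamily and genus rank in common use; the
root-bipartition rule is this package's stated interpretation, and the
`evidence` column of every assignment records that it fired.

## Fragment-based intergenomic similarity

Each query genome is cut into consecutive non-overlapping fragments
(default 3 000 nt; a terminal remainder shorter than half a window is
dropped). Each fragment is matched against each reference genome by exact
13-mer seeding on both strands: seeds vote for diagonals, the top
diagonals are scored by column identity over their seed-supported span,
and near-disjoint spans on different diagonals are chained into one gapped
match, as a gapped local aligner would produce across an insertion. A
fragment is matched iff the best (possibly chained) span covers at least
half the fragment at ≥ `min_fragment_identity` (default 80 %).

For a directed pair, ANI is the mean identity of matched fragments, the
aligned fraction AF is matched/total fragments, and the intergenomic
similarity is `S = ANI × AF` (percent; ANI 99 with AF 0.99 gives
S = 98.01). `similarity_matrix()` averages the two directions, fixes the
diagonal at 100 and floors values below 0.01 to 0. By construction
`S ≤ min(ANI, 100·AF)` and the matrix is exactly symmetric.

The seed-and-chain matcher assumes collinear homology within a fragment;
it does not model large rearrangements inside a window, and its identity is
computed columnwise along diagonals rather than from a full
Smith–Waterman — adequate because fragments either match well above the
80 % floor or not at all, and verified to recover planted divergences of
1–10 % within ±1 point on 100 kb genomes.

## Rank demarcation

Species and genus are single-linkage partitions of the similarity matrix at
`S ≥ 95` and `S ≥ 70` (the ICTV convention for phage species and genera;
both inclusive). Single linkage is deliberate: a borderline strain that
falls marginally below 95 % against distant members of its species still
joins via intermediates, which matches how such cases are resolved in
practice. `build_taxonomy()` assembles species ⊆ genus ⊆ subfamily ⊆
family ⊆ order, enforces nesting (a violation is a hard error naming the
offending genomes — it indicates inconsistent upstream evidence, not
something to patch silently), assigns deterministic placeholder labels
(components ordered by size, then smallest member), and accepts an optional
name map; nomenclature itself is editorial, not computable. Order
membership is an input: all genomes in one run are assumed to belong to one
order, since order-level demarcation requires comparison against the full
classified tailed-phage diversity, which is out of scope here.

## The synthetic clade generator

`simulate_clade()` produces genome sets with fully known truth — taxonomy,
genetic code, gene-family content, pairwise divergence — so every pipeline
stage can be validated without downloads. The model:

* **Genes and genomes.** Codon-structured genes (ATG start, single TAA
  stop, 150–450 codons) separated by short spacers at ~89 % coding
  density; amino-acid composition follows an AT-rich-proteome profile
  (Lys/Ile/Asn-enriched) with glutamine at 6 %, and codon choice is
  GC-weighted with the weight solved analytically (`uniroot`) so realised
  genomic GC hits a requested target — controllable within ±1 point across
  the 26–31 % window typical of these phages.
* **Deep edges (family/subfamily/genus)** apply amino-acid substitutions
  at an edge rate, then redraw every codon synonymously and re-randomise
  spacers. Protein identity therefore decays slowly while nucleotide
  identity between genera collapses to background — the silent-site
  saturation that makes fragment-ANI blind beyond the genus, exactly as in
  real data. Default edge rates (subfamily 0.045, genus 0.05) place
  cross-subfamily core-protein identity near 82 %, safely above the 70 %
  clustering threshold, so planted core families stay single clusters
  across the whole family — the regime implied by a real family-wide core
  proteome at 70 % identity.
* **Shallow edges (species/strain)** apply exact-count single-nucleotide
  substitutions: synonymous-only inside genes (third-position changes
  preserving the amino acid under the genome's code), free in spacers.
  Site selection is proportional to each site's total substitution weight
  and replacements are drawn from the composition weights, making the
  process reversible with the genome's base composition as stationary
  law — a naïve "pick a site, force a change" scheme ratchets GC upward by
  several points.
* **Gene content.** Accessory families "home" at a rank (family,
  subfamily, genus, species) and are lost on deeper edges with small
  probabilities; species-level accessory genes and per-strain gains are
  short (100–150 codons) and the species-level ones sit in one contiguous
  accessory island. This mirrors how young accessory content clusters in
  phage genomes, and it matters quantitatively at reduced genome scale:
  scattering full-length content differences across a 50 kb genome would
  let a handful of gene gains dominate the aligned fraction and push
  within-genus similarities a rank downward. Novel genes are screened
  against all existing families by shared amino-acid 9-mers so gains never
  collide with planted families at clustering thresholds.
* **Recoding.** Recoded families have 15 % of glutamine codons written as
  TAG (inherited within a genus, so relatives agree on TAG positions);
  their genomes are table-15 by construction.

`simulate_benchmark_clade()` fixes a 23-genome design used throughout the
tests: one family of 22 genomes with two subfamilies (genera of 11, 9 and
2 genomes; species of sizes 4,1,1,1,2,2 / 9 / 2) plus a single-genome
outlier family whose proteins are diverged to ~50 % identity (connecting
only far below the 70 % working threshold), with uniform table-15 recoding.
At the default `scale = 0.1` genomes are ~45–50 kb — about a tenth of real
megaphage size — so the full pipeline runs in about a minute per replicate;
`scale = 1` approximates full size for profiling.

**What passing on this generator does and does not show.** It shows the
statistics behave as designed under i.i.d. substitution (no rate
heterogeneity or codon-usage realism), content evolution by whole-gene gain
and loss (no recombination, HGT tracts, or structural variation), and clean
rank separation in similarity space. Real data add assembly artifacts,
mosaicism, and intermediate divergences that can straddle thresholds; the
demarcation thresholds themselves are field conventions, not quantities the
simulator can validate.

## Problem sizes used in validation

The shipped test suite and the acceptance script use: the 23-genome
benchmark clade at `scale = 0.1` (5 seeds in the tests, 3 in the
acceptance script; 50 bootstrap replicates), 20 seeded genomes per class of
≥ 50 genes for code detection, 100 kb pairs at 1/2/5/10 % divergence for
ANI recovery, ≤ 50 random proteins for the clustering oracle, and additive
matrices of up to 8 taxa for the NJ oracle. These sizes were chosen so the
whole battery runs on a laptop in minutes while leaving every comparison
statistically decisive.

## Known limitations

* The rule-based ORF caller is built for the capacity statistic, not for
  annotation-grade gene models; its capacity values differ from trained
  gene finders by a few points (systematically, for both codes alike).
* Exact parity with external clustering tools' cluster counts is not
  claimed; connected-component semantics at 70 % identity with 0.8
  bidirectional coverage is the closest defensible reading of that family
  of methods, but unstated sensitivity settings differ.
* The fragment matcher's ANI is columnwise along chained diagonals; highly
  indel-dense homology would be under-scored.
* NJ replaces maximum likelihood; branch lengths are Poisson-corrected
  distances and should not be interpreted as substitution-model estimates.
* Subfamily rank uses the root-bipartition rule described above; other
  operational definitions are possible and the output flags the rule used.
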