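---
title: "Discovering and characterizing huge phage genomes: methods"
author: "hugephage package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and characterizing huge phage genomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hugephage)
```

# Scope and model

Bacteriophages with genomes above 200 kb ("huge" or jumbo phages, above
500 kb megaphages) are systematically missed by isolation-based methods and
fragment easily in metagenomic assemblies. This package implements the
computational core of a discovery workflow for such genomes among long
assembled contigs: assembly quality control, minimal gene calling with
inference of alternative genetic codes, element-type classification,
CRISPR array and spacer-target analysis, host-phylum prediction, and
two-step protein-family clustering. A synthetic-community generator plants
every one of these genomic features with known coordinates, so each
detector is validated by recovery of ground truth rather than by visual
inspection.

The package deliberately consumes *annotation hit tables* (per-gene best
database match: lineage, functional keyword, bitscore) and *similarity edge
tables* (all-vs-all and profile-profile scores) as inputs. Running the
underlying homology searches is out of scope; any search stack that can
emit these tables can drive the pipeline.

# Assembly quality control

**Circularization.** A complete genome assembled from a circular template
shows an exact terminal direct repeat: the first L bases equal the last L.
`detectCircularity()` finds the longest such overlap between 50 bp and
20 kb (both configurable; no specific bounds are canonical in the
literature, these defaults bracket the overlaps real assemblers produce).
The search is anchored on a 31-mer and verified by full string comparison,
so it is exactly equivalent to trying every length — a property the test
suite asserts against a brute-force oracle.

**Concatemer artifacts.** Assemblers sometimes emit a genome as two or
more tandem copies. `detectLongDirectRepeats()` reports all maximal exact
direct repeats of at least 5 kb (anchored search, again oracle-exact), and
`flagConcatemer()` calls a contig an artifact when a self-overlap at lag u
covers essentially the whole sequence; the corrected length is the unit
length u. Contigs with long repeats that are not tandem covers are flagged
for manual review instead of being auto-corrected. After correction a
sequence is retained for analysis when its corrected length is at least
200 kb; the threshold is a configurable parameter of the classification
stage.

**Short repeats.** All maximal exact repeats longer than 25 bp, direct and
inverted, are tabulated by shared-k-mer diagonals (k = 26). These feed
repeat-region reporting only; no filtering decision depends on them.

**GC skew.** Leading and lagging replication strands accumulate opposite
G/C biases, so the cumulative per-window G−C excess of a bidirectionally
replicating genome is piecewise linear with slope changes at the
replication origin and terminus. `gcSkew()` profiles (G−C)/(G+C) in 1 kb
windows stepped by 500 bp; `classifyReplicationMode()` places breakpoints
at the extrema of the cumulative curve — the least-squares changepoints of
a sign-alternating piecewise-constant skew — and accepts the bidirectional
model only when the corresponding piecewise-linear fit has R² ≥ 0.85,
every segment slope is at least 0.01 G−C counts per bp in magnitude, and
the fit clearly beats a single line. A single line with sufficient slope
and R² is classified unidirectional; anything else, including profiles of
fewer than 10 windows, is "none". The slope floor is what separates real
skew from the random-walk wander of an unskewed genome, whose cumulative
curve can fit a line deceptively well while staying nearly flat.

With the generator's default skew amplitude (0.05, a typical magnitude for
clearly skewed bacterial genomes) the breakpoint estimate is usually
within one window of the planted origin; occasional excursions of a few
kilobases are intrinsic to the noise level, which is why recovery is
asserted at ±5 kb.

**Reorientation.** For circularizable contigs with a bidirectional
profile, `reorientToOrigin()` trims the terminal overlap and rotates the
sequence so that it starts in the intergenic gap nearest the inferred
origin (the breakpoint where the cumulative slope turns from negative to
positive). Rotation is a bijection and preserves length and gene
complement.

# Gene calling and alternative genetic codes

`callOrfs()` is a deliberately minimal six-frame caller: maximal ORFs
start at the first in-frame ATG/GTG/TTG after a stop (or the sequence
start), end at a stop codon of the active genetic code, and must reach 60
codons (configurable; no canonical value exists, 60 excludes most random
ORFs at these GC contents). Overlapping calls are resolved greedily by
length, ties by leftmost position then forward strand. It stands in for a
production gene caller so that coding density is a well-defined, exactly
testable quantity; it makes no attempt at translation-initiation
refinement.

Coding density is the fraction of positions covered by at least one call.
Genomes that have reassigned a stop codon to a sense codon look
pathological under the standard bacterial code 11: every in-frame
reassigned codon truncates an ORF, and density collapses.
`inferGeneticCode()` flags a contig when its code-11 density falls below
0.78 — anchoring the flag at the density regime observed in recoded huge
phage genomes — then re-calls genes under TAG-recoded and TGA-recoded
tables and accepts an alternative only when it gains more than 0.10 of
density over code 11. The margin prevents spurious reassignment on
genuinely low-density (e.g. fragmented) sequences; both values are
arguments. Candidate codes that retain a single stop codon (such as a
code-6-like table with TAA and TAG both read through) are additionally
screened for implausible gene fusions: such a code is ruled out when its
95th-percentile gene length exceeds three times that of the code-11 calls,
or when more than 20% of its genes each span three or more code-11 genes.
These two cutoffs quantify a rule-out that is otherwise qualitative;
two-stop candidate codes do not face the fusion screen because genuine
recoding makes candidate genes span many truncated code-11 fragments by
construction.

# Element-type classification

Each gene votes with its best hit's lineage at every rank from domain to
genus; a rank has a winner only above a strict 50% majority of the
non-abstaining genes. Ranks are evaluated independently and all are
reported (the alternative — stopping at the first winnerless rank — would
hide information and complicate no downstream rule).

Classification applies four ordered rules: (1) a detected prophage
transition makes the contig prophage-containing; (2) plasmid
partitioning/conjugation keywords with no phage markers make it
plasmid-like; (3) phage marker genes (capsid, tail, terminase, spike,
holin, portal, baseplate — shipped as an editable lexicon in
`inst/extdata/phage_markers.tsv`), or the combination of no domain-level
winner with a hypothetical-protein fraction of at least 0.6, make it a
phage; (4) otherwise unknown. The 0.6 quantifies "a high number of
hypothetical protein annotations"; it is configurable. Phylogenetic
placement of markerless candidates is out of scope and replaced by an
explicit `phageOverride` flag. Contigs under 200 kb are rejected unless
they carry a CRISPR array, mirroring the practice of retaining
CRISPR-bearing phages just under the size cutoff.

Prophage transitions are located by a Bernoulli changepoint along the gene
order on the indicator "confident bacterial functional prediction"
(non-hypothetical keyword, not a marker, bitscore ≥ 60). A first pass with
symmetric weights locates the split; a second pass reweights by the
estimated log-likelihood ratio of the two regimes, which markedly sharpens
the boundary when the flank (confident fraction ≈ 0.9) and the phage
interior (≈ 0.2) are asymmetric. A boundary is accepted only when the
flank spans at least 20 kb at ≥ 70% confidence and the remainder shows at
most half the flank's confident fraction — the latter contrast test is
what keeps uniformly bacterial contigs (e.g. plasmids) from producing
phantom boundaries.

# CRISPR arrays, spacer matching and the interaction network

`detectArrays()` follows the CRT family of detectors: exact 8-mer seeds
recurring at a period between 36 and 120 bp (repeat 19–48 bp plus spacer
17–72 bp, the customary bounds) nominate a repeat pair; the array is
walked outward, allowing up to one mismatch per additional copy.
Boundaries are then re-derived across *all* copies as the maximal run of
(near-)unanimous columns overlapping the seed — using the full array
rather than one copy pair removes the chance single-pair extensions that
otherwise shift boundaries by a base or two. The consensus is the
per-column majority. Arrays need at least three repeat copies; orientation
is reported as detected, with no repeat-degeneracy orientation call.

Spacer matching is an ungapped full-length Hamming scan of both strands of
every target — short spacers make gapless matching exact and
oracle-checkable, whereas a local aligner would blur the mismatch-count
semantics. The strict tier keeps matches longer than 24 bp with at most
one mismatch. For every (array, target) pair with a strict match, the same
target — and only that target — is rescanned for the array's other spacers
at up to three mismatches (the expanded tier), accommodating spacer decay
and escape mutations. Matches falling inside a detected array on the
target (the spacers themselves) are excluded. `buildNetwork()` collapses
matches into directed owner-to-target edges; edges with strict support are
drawn solid, expanded-only edges dashed, and self-targeting is reported
separately.

# Host prediction

The phylum-level best-hit counts over a phage's genes vote for its host;
the top phylum is assigned only when it has at least three times the
count of the runner-up. The boundary is taken inclusively (exactly 3×
qualifies), multi-hit genes contribute one vote (their best hit), and
abstaining genes are excluded from the denominator. Independently,
bacterial contigs whose arrays strictly target the phage nominate their
phylum. `reconcileHost()` reports agreement, conflict (no final call), or
single-evidence assignments, symmetrically in the two evidence lines.

# Protein families

The two-step procedure first builds subfamilies by greedy set cover on the
all-vs-all similarity graph filtered at E ≤ 1e-3 and coverage ≥ 0.5: the
node covering the most uncovered nodes becomes a representative, ties
break by node id, making the result independent of input order. Profile
edges between subfamilies, filtered at probability ≥ 95% and coverage ≥
0.5 and weighted by probability × coverage, are then clustered by Markov
clustering with inflation 2.0. The MCL loop adds self-loops at the maximum
incident weight, column-normalizes, and alternates expansion with
inflation, pruning entries below 1e-5, until the matrix changes by less
than 1e-6 or 100 iterations elapse (pruning threshold, tolerance and cap
are conventional choices; only the inflation value is canonical).
Attractor rows define clusters; a node supported by several attractors
goes to the one holding more mass, ties to the lower id. All subfamilies —
including singletons — enter the profile network as nodes, so unclustered
subfamilies surface as families of their own and the final families
partition the protein set exactly, which every run asserts.

# The synthetic-community generator

`communitySpec()` lays out the study conditions; `generateCommunity()`
draws everything from one seeded RNG stream in fixed order, so identical
specs give byte-identical FASTA/TSV/JSON outputs. Defaults: 10 phage
genomes spread over 200–700 kb, 5 host contigs (280–420 kb), one
plasmid-like contig; GC 0.5; replication skew cycling
bidirectional/unidirectional/none with amplitude 0.05 and breakpoints at
25% and 75% of length; every fifth phage from the second TAG-recoded with
a planted sense-TAG usage of 2.5% of body codons (enough to drive code-11
density below the 0.78 flag while the true-code density stays above it);
odd-indexed phages circularized with a 120 bp terminal repeat; the last
phage emitted as a tandem dimer of a 250 kb unit; CRISPR arrays (32 bp
repeats, 34 bp spacers; six copies on phages, matching the compact arrays
reported in phage genomes, eight on hosts) on two phages and three hosts;
seven spacer-protospacer links at 0–3 mismatches wiring hosts to their
phages and phages to rival phages; one host carrying an integrated 250 kb
prophage with 40 kb bacterial flanks.

Genomes are dense tilings of random-codon genes (log-normal length, median
300 codons, sd 0.45 on the log scale; intergenic gaps 20–150 bp) over an
iid base background, with per-region base probabilities implementing the
skew; genes on the minus strand sample with inverted G/C bias so the
emitted strand shows the intended excess. Annotation tables sample each
gene's category (hypothetical / viral hit / phylum hit / functional) from
per-role profiles: phage genes vote their true host phylum at an expected
4.5:1 ratio over the runner-up, hosts vote their own phylum near-uniformly,
five phage genes carry marker keywords, five plasmid genes carry
partitioning/conjugation keywords. Protein-similarity tables plant a known
subfamily/family structure with strong within-subfamily all-vs-all edges,
sub-threshold noise edges, within-family profile edges at 96–99.9%
probability and between-family edges at 30–70%.

What the generator does *not* emulate: sequencing error and read-level
artifacts, real protein evolution (bodies are random codons), genuine
codon-usage bias, mosaic phage genomes, degenerate repeat copies inside
arrays, and database annotation noise beyond the sampled category
fractions. Passing recovery tests therefore demonstrates the correctness
of the detectors' logic and thresholds under controlled signal and
realistic base-composition noise — not robustness to every failure mode of
real metagenomes.

# Numerical and convention choices

Coordinates are 1-based inclusive everywhere, the native convention of the
R/Bioconductor containers the package is built on; GFF3 output is 1-based
inclusive as the format requires. Windows with G+C = 0 have skew 0 by
convention. The trailing partial window of a skew profile is not profiled,
so the cumulative total telescopes exactly when step equals window.
Degenerate inputs follow the documented contracts: contigs shorter than
twice the minimum overlap warn and return no overlap; zero genes make the
hypothetical fraction an error rather than a silent 0/0; constant tRNA
tables report an undefined correlation explicitly. Permutation p-values
(10,000 seeded permutations) are used for the size/tRNA rank correlation
because the comparison sets of interest are small.

Problem sizes in the tests are chosen to keep the full suite in a few
minutes: oracle-equivalence checks run on 1.2–8 kb sequences where the
quadratic brute force is instant, module recovery tests on a 5-phage
community with 200–300 kb genomes, and the acceptance checks on the
full-scale default community (10 phages, 200–700 kb).

# Known limitations

Element classification depends entirely on the quality of the annotation
table; it has no sequence-intrinsic phage model. The ORF caller does not
refine start sites, so density is a slight underestimate near gene starts.
Array orientation is not called, and Cas-gene identification is consumed,
not computed. Host prediction stops at phylum. The concatemer corrector
handles exact tandem copies; diverged copies fall to manual review by
design.
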