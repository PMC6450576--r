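---
title: "Probe-based 16S profiling and its validation framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-based 16S profiling and its validation framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probetax)
```

## The two classification models

`probetax` implements two ways of turning 16S rRNA gene amplicon reads into
taxon counts, plus the machinery needed to compare them on equal footing.

**The two-tier probe classifier** is the core of the package. Its knowledge
base is a set of short (17–40 nt) oligonucleotide probe sequences, each
diagnostic either for a single species or for a group of congeneric species
that cannot be separated at the species level. Classification of a read is a
pure exact-substring question, asked in two tiers:

1. If the read contains any *species-level* probe sequence (forward or
   reverse complement), it is a **species-tier** read and is never tested
   against genus probes. This precedence rule limits double counting between
   tiers, because genus probes can legitimately occur inside species-probed
   sequences.
2. Otherwise, if it contains any *genus-level* probe sequence it is a
   **genus-tier** read.
3. Otherwise it is **unassigned**. Unassigned fractions of 15–25% are
   typical for probe panels against real oral communities, which is why the
   simulator can designate probe-free taxa.

Within a tier, the default counting policy (`all_matches`) credits every
probe the read contains — probe panels accept the over-representation this
can cause — while `policy = "unique"` credits a probe only when the read
matches exactly one probe in its tier, reporting multi-probe reads as
ambiguous. Both policies conserve reads: species-tier + genus-tier +
unassigned = total, always.

Matching is *exact*: no mismatches, no positional constraint, both strands
by default. Probes are short and highly specific, and exact matching keeps
the classifier deterministic and fast. A mismatch-tolerant mode is a
deliberate non-goal.

**The closed-reference identity classifier** is the comparison arm. Each
read is aligned against candidate reference sequences with an end-gap-free
(semi-global) alignment, scored with match = 1, mismatch = 0, so the
alignment score *is* the number of matched columns and a short perfect
subregion can never outscore a near-full-length alignment. Identity is
matches divided by aligned columns, internal gaps counting as mismatch
columns. A read is assigned to its highest-identity reference if that
identity reaches `min_identity` (default 0.99); otherwise it is excluded
from all downstream analyses, the defining behaviour of closed-reference
OTU picking. Ties go to the earliest reference in file order and are
counted. Candidates are shortlisted by shared 12-mers; `exhaustive = TRUE`
disables the shortcut, and the two paths are required to agree in the test
suite. Note the k-mer prefilter's known blind spot: a read whose
substitutions are spaced closer than k apart shares no k-mer with its
source and is excluded; at realistic error rates this is negligible, and
the exhaustive flag exists for exactness.

## Read processing

Paired-end joining slides the reverse-complemented mate along the forward
read and accepts the overlap (≥ 6 nt) with the lowest mismatch fraction
(≤ 8%, ties to the longest overlap) — the conventions of the fastq-join
family of tools. In the overlap, the consensus base comes from the mate
with the higher Phred score and the joined quality is the per-position
maximum, so disagreements resolve toward the stronger base call.

Quality filtering rejects whole reads; it never truncates. A read is
rejected if it contains any ambiguous base (e.g. N), or a run of more than
`max_consecutive_low` (default 3) consecutive calls below `min_phred`
(default 25). A single isolated low-quality base is *not* grounds for
rejection — under a per-base reading of the threshold the run rule would be
unreachable, so bases below the threshold are interpreted as "low-quality
calls" that feed the run rule. Filtering is idempotent and every read lands
in exactly one bucket. Only offset-33 Phred encoding is accepted; input
that implies offset 64 raises an error rather than being silently rescaled.

## Count-table rules

- **Low-abundance filter**: within each sample, counts strictly below
  0.01% (`fraction = 1e-4`) of that sample's total are zeroed; a count
  exactly at the threshold survives. The denominator is the per-sample
  matched total, and because filtering only shrinks it, the filter is
  idempotent at a fixed fraction.
- **Singleton removal**: features with a table-wide total ≤ 1 are dropped.
  The rule is deliberately *only* total ≤ 1 — a feature with one read in
  each of two samples stays.
- **Genus aggregation**: species-tier counts are summed per genus, then
  genus-tier counts are added; per-sample totals are conserved exactly.
- **Rarefaction**: sampling without replacement to exact depth; samples
  below depth are dropped and reported, not errors. Seeded, reproducible.
- **Serialization**: TSV (features × samples with tier/genus/taxon columns)
  and BIOM v1 JSON via the biomformat package. BIOM v2/HDF5 is out of scope
  to keep the core free of binary formats.

## Diversity and congruence

Shannon diversity uses log base 2 (the upstream pipeline's convention; a
`base` argument gives nats). Chao1 uses the bias-corrected form
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$, defined even with no doubletons.
Rarefaction schedules are arithmetic progressions capped at the maximum
depth, with the maximum appended when the progression does not land on it —
printed endpoint pairs such as 100→20,640 by 2,064 are unreachable
otherwise.

UniFrac is computed over a rooted tree with branch lengths by a single
post-order accumulation of per-branch descendant masses. Unweighted UniFrac
is unique branch length over union branch length; weighted UniFrac weights
each branch by $|A_i - B_i|$ (the difference in community fraction
descending through it) and defaults to the normalized variant (divided by
$\sum b_i (A_i + B_i)$) so both metrics live in [0, 1]. The implementation
is held equal, within 1e-10, to a brute-force per-branch enumeration on
hundreds of random trees, and to phyloseq's implementation on fixtures.

PCoA is classical metric scaling (`stats::cmdscale`): eigendecomposition of
the double-centered squared-distance matrix; negative eigenvalues are
reported but carry no coordinates, and proportions explained are relative
to the positive spectrum.

Procrustes congruence scales both configurations to unit Frobenius norm
after centering and minimizes the residual over rotations *and* reflections
(full orthogonal group) with optimal uniform scaling, giving
$m^2 = 1 - (\sum_i \sigma_i)^2 \in [0, 1]$. Significance is a Monte Carlo
permutation test on the second configuration's sample labels with
$p = (\#\{m^2_{perm} \le m^2_{obs}\} + 1)/(n_{perm} + 1)$; 1,000
permutations by default. The statistic matches vegan's symmetric Procrustes
`ss` and the permutation p-value is verified to be approximately uniform
under independence.

Method congruence at the composition level uses relative abundances over
assigned reads only (unassigned reads are excluded from the denominator, as
proportional bar charts do), compared per sample by Bray–Curtis
dissimilarity and total variation over the shared label space. Paired
profiles are built over the top-k genera of a chosen reference sample and
report raw (not renormalized) proportions with per-sample coverage, since
coverage gaps are themselves informative. When the two arms live in
different label spaces, species-level features can be collapsed through the
probe coverage map (species probe first, else first covering genus probe,
else uncovered and dropped with a log).

## What the simulator emulates — and what it does not

`generate_reference_set()` builds amplicon-length (441 nt) templates for
`n_taxa` taxa in `n_genera` genera, mirroring mixtures of PCR products from
a clone collection: 250 + 250 nt mates with a 59 nt designed overlap join
back to 441 nt. Probe sites are spliced into fixed regions (species site in
the forward-read region, genus site in the reverse-read region), and every
probe is verified to occur nowhere else in any template, on either strand,
with resampling on collision — chance 20-mer collisions are astronomically
unlikely but are checked, not assumed. A configurable fraction of taxa is
probe-free, producing designed unassigned reads; a configurable fraction of
covered taxa carries a dedicated species probe, and *every* covered taxon
carries its genus's shared probe site, reflecting real panels in which
genus probes also match species-probed sequences.

Default probe lengths are 18–22 nt — typical oligonucleotide probe lengths,
inside the 17–40 nt range the validator enforces. Mixtures follow the
validation-mixture conventions: 6–23 components spanning sub-1% to dominant
proportions, with `exact` (largest-remainder, totals preserved) or
`multinomial` allocation. Errors are i.i.d. per-base substitutions applied
independently to each mate (Phred 38 for correct calls, 15 at error sites,
so the QC path sees realistic quality structure); indels are deliberately
excluded because exact-substring matching would conflate indel handling
with probe sensitivity. Proportions, not absolute amounts, are the ground
truth — the physical mixtures the design emulates had undetermined absolute
inputs.

What passing tests therefore show: the classifier arms recover designed
proportions exactly on clean data and within binomial error at 1%
substitution noise, with the designed probe-free mass reappearing as the
unassigned fraction. What they do not show: robustness to chimeras, indels,
amplification bias, quality-by-cycle degradation, or reference databases
with near-identical entries — none of which the simulator generates.

## Numerical and design choices

- Probe alphabet is strict ACGT; degenerate IUPAC codes in probes are
  rejected because no expansion rule is defined for them. Reads may carry
  IUPAC codes up to QC, where the ambiguity rule removes them.
- Demultiplexing assigns a read only when exactly one map barcode lies
  within the mismatch radius; two candidates in range make the read
  unmatched even if one is strictly closer.
- Whether the original probe software counts a multi-probe read once or
  per-probe is not documented; `all_matches` is the default and `unique`
  exists for sensitivity analysis. Under `unique`, ambiguous reads remain
  in tier totals but credit no probe.
- Low-quality runs reject the whole read rather than truncating it; the
  filtering language of the upstream pipeline does not distinguish the two,
  and whole-read rejection keeps read lengths deterministic.
- Identity ties in the reference arm resolve to file order and are counted;
  silent arbitrary tie-breaking would make runs irreproducible across
  re-orderings.
- The weighted-UniFrac variant used upstream is not recorded; the
  normalized variant is the default here so weighted and unweighted values
  share [0, 1].
- Every stochastic step takes an explicit seed; the pipeline driver derives
  per-stage seeds from the global seed and the stage name, so any stage can
  be reproduced in isolation.

## Problem sizes

The shipped validation suites run on a single CPU in minutes: ten recovery
mixtures of 1,000 reads; one hundred noisy replicates of 500 reads at 1%
substitution error; two hundred random trees (4–16 leaves) for the UniFrac
oracle; two hundred Procrustes null trials at 99 permutations each; one
thousand rarefaction seeds for the unbiasedness check. These sizes give the
statistical assertions comfortable margins (3-standard-error bands on
proportions of a few hundred to a few thousand reads) while keeping the
whole suite fast.

## Known limitations

Exact matching means a single substitution inside a probe site silently
demotes a read to the next tier or to unassigned; at the 99% identity
threshold the reference arm excludes reads whose joined error count exceeds
~1%, so the two arms respond differently to noise — which is precisely the
comparison the congruence module quantifies. The closed-reference arm is a
deliberately minimal identity classifier, not a re-implementation of any
particular aligner's seed statistics; it exists so both arms can be run on
identical, fully-specified inputs.
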