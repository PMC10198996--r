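---
title: "Discovering novel start codons: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering novel start codons: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

A single-nucleotide variant in a 5'UTR can convert a non-AUG triplet into an
AUG upstream of, and in frame with, the annotated coding sequence. If no stop
codon intervenes, the new AUG defines an N-terminal extension of the protein
— a *start-gain* variant. The same mutation type can also fix along a
lineage: a start codon present in one species but absent from its relatives
is a candidate species-specific gain of coding sequence. `startscan`
implements both discovery problems, quantifies translation-initiation
activity at the discovered codons from ribosome profiling, and asks whether
the novel coding sequences evolve under selection, using codon substitution
branch models.

This vignette documents the models, the tunable parameters, the
synthetic-data generator used for validation, and the design decisions that
were genuinely open.

# Population-level discovery (start-gain SNVs)

`classify_snv()` evaluates one biallelic SNV against one transcript. A call
requires all of:

1. the SNV lies in the transcript's 5'UTR (exonic, upstream of the annotated
   start in transcript coordinates);
2. substituting the alternate allele into the transcript-oriented sequence
   creates an `ATG` at a triplet covering the variant base, the reference
   triplet not already being `ATG` — the variant may supply the A, the T or
   the G;
3. that triplet is in frame with the downstream CDS;
4. no `TAA`/`TAG`/`TGA` occurs in that frame strictly between the novel AUG
   and the annotated start (both exclusive, matching the definition of the
   novel CDS);
5. the variant's genomic position is not inside any annotated CDS of any
   transcript (the union across isoforms).

Only AUG is considered a start codon, and no Kozak-context or other sequence
feature is required: requiring such features would trade sensitivity for
precision in a way that cannot currently be justified, since the sequence
determinants of initiation are not settled. Calls are made per
(SNV, transcript) pair; population summaries deduplicate to the SNV level.
An individual *carries* a novel start codon if it has at least one alternate
haplotype; heterozygotes and homozygotes count alike, since initiation is
assayed per allele. Missing genotypes are excluded from both the numerator
and denominator of allele frequencies.

For the occupancy analysis, calls are filtered to those with at least
`min_codons = 5` codons between the novel and the annotated start (shorter
extensions cannot be distinguished from start-codon signal bleed), at least
`min_carriers = 3` carrier individuals (fewer carriers give no contrast
group), and autosomal location (sex chromosomes would confound per-individual
read-depth comparisons). The autosome list defaults to `1–22` with or
without a `chr` prefix and is configurable.

Transcripts whose stop codon ends more than 50 nt upstream of the 3'-most
exon–exon junction are flagged as predicted nonsense-mediated-decay targets
(`nmd_classify()`); the rule is strict (`> 50`), and single-exon transcripts
are never flagged.

# Species-level discovery (fixed novel start codons)

Starting from pairwise whole-genome alignment blocks (MAF) of the reference
species against one close outgroup (chimpanzee) and two further outgroups
(gorilla, orangutan):

1. only *one-to-one* blocks are kept — every base of both the target and the
   query interval covered by exactly one block genome-wide — to exclude
   paralogous or ambiguous alignment;
2. divergent sites (different alleles, no gaps, no `N`) between human and
   chimpanzee are collected;
3. a candidate is a divergent site inside the annotated start codon of a
   human transcript whose chimpanzee ortholog lies in the 5'UTR of a
   chimpanzee transcript (any transcript; the chimp transcript id is
   recorded);
4. polarisation: gorilla and orangutan must both carry a non-human allele.
   A missing outgroup alignment drops the candidate, because the ancestral
   state cannot then be established;
5. fixation: the site must be monomorphic across the population VCF — absent
   entirely, or present with every called genotype homozygous reference.
   Sites with some missing genotypes still qualify if all called genotypes
   are reference.

Codons in which human and chimp differ at more than one triplet position are
kept as a single call listing all divergent positions: the unit of discovery
is the codon, not the SNV. Novel AUG codons whose chimpanzee ortholog is
`CTG` are flagged (`flag_cug_origin()`): CUG is a known near-cognate start
codon with residual initiation activity, so occupancy contrasts are run both
with and without these calls. If the chimp triplet is only partially
aligned, the flag is `NA` and the call is retained; if the divergent site
itself falls in an alignment gap, no divergent site exists and the candidate
is never formed. (These are two different situations: the first loses only
the origin label, the second loses the evidence for divergence itself.)

For each call, a four-anchor panel drives the occupancy analysis: the human
novel start codon (hSSC), the human ancestral start (hASC — the human
position orthologous to the chimpanzee start codon), the chimpanzee ortholog
of the hSSC (cOSC), and the chimpanzee start codon (cSC). Calls need at
least five codons between hSSC and hASC to be analyzable, for the same
bleed-over reason as above. Calls whose chimp-derived ancestral start is not
in frame with the human start get `NA` novel-CDS length and are excluded
from analyzability rather than erroring: a frameshifted ortholog has no
well-defined novel CDS.

# Ribosome occupancy

Footprints are filtered to uniquely mapped reads of 26–32 nt that do not
overlap a non-coding-RNA blacklist. Uniqueness is taken from the SAM `NH`
tag (`NH == 1`), with a `MAPQ > 3` fallback when `NH` is absent — aligners
disagree on how "uniquely mapped" is encoded, and these two conventions
cover the common cases. The blacklist is consumed as a BED file; rebuilding
rRNA/tRNA/snRNA databases is out of scope.

The P-site is the 12th nucleotide from the 5' end for 26–29-nt reads and
the 13th for 30–32-nt reads; on the minus strand the 5' end is the rightmost
aligned base. Per-base P-site counts are scaled to reads per million (RPM),
so every sample's track sums to exactly 10^6. Codon occupancy sums the RPM
at the codon's first and second nucleotide and the nucleotide before the
first, tolerating ribonuclease cleavage error; on the minus strand "before"
and "second" follow transcript orientation, because the rule reflects
ribosome geometry, which is transcript-directional. Metagene windows walk
transcript coordinates (splice-aware), since 5'UTR anchors can sit near
junctions; reads whose P-site falls in an intron still contribute to the
genome track but are never visited by transcript-space windows.

Aggregation is mean over anchors within sample, then mean over samples, so
deeply sequenced samples do not dominate; anchors are not weighted by
expression (an open choice — unweighted means are the most transparent
default).

Two-group comparisons use Wilcoxon tests: rank-sum for carrier versus
non-carrier contrasts (independent groups), signed-rank for paired anchor
contrasts such as hSSC versus hASC. The exact signed-rank null is computed
by full enumeration through the generating function over (doubled average)
ranks for up to 25 informative pairs — this handles tied absolute
differences exactly, which the standard exact implementation declines to do
— and a normal approximation with continuity correction beyond. Zero
differences are dropped; an all-zero contrast returns p = 1 with a warning.

# Codon substitution branch models

Novel CDSs (both flanking start codons excluded) are extracted with their
chimpanzee and gorilla orthologs read through the alignment columns; codon
columns containing a gap, `N`, or a stop in any taxon are dropped with a
count — the orthologs need not be coding in the other genomes, so stops are
expected occasionally and are not an error. Alignments from CDSs strictly
longer than 15 nt are concatenated: individual novel CDSs carry too few
substitutions for a stable estimate. The threshold is exposed
(`concat_min_len`) because "longer than" is read strictly here.

The model is a Goldman–Yang style single-matrix codon model on the unrooted
3-taxon star tree (human, chimpanzee, gorilla — orangutan is used only for
polarisation upstream): off-diagonal rates
`q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]` for codon pairs
differing at one position, zero otherwise, scaled to one expected
substitution per codon per unit branch length. Codon frequencies are F3x4
from the concatenated alignment by default (with a 0.5 pseudocount per
nucleotide per position, so no sense codon has probability zero), with a
uniform-frequency option used by the calibration tests to separate estimator
properties from frequency-model mismatch. The genetic code is the standard
table.

Four models are fitted: a single shared omega, and one foreground omega on
the human, chimpanzee, or gorilla branch with the other two sharing the
background value. Each alternative is compared to the shared-omega null by
a likelihood-ratio test with one degree of freedom (one extra omega).

Likelihood evaluation exploits reversibility: the symmetrised rate matrix is
diagonalised once per distinct omega (in compiled code), and branch
transition matrices come from the eigendecomposition. Optimisation is
bounded quasi-Newton (`L-BFGS-B`) over log-transformed parameters
(`kappa`, omegas, three branch lengths) from a deterministic grid of five
starting points — one moment-based start using the mean pairwise codon
difference plus four fixed perturbations spanning low/high omega and
short/long branches. A deterministic grid was chosen over random restarts so
that fits are bit-reproducible without seed plumbing; the grid spans the
same basins random restarts would. All starts are explored at loose
tolerance and the best is polished to an absolute log-likelihood tolerance
of about 1e-6. Negative LRT statistics within 1e-4 (optimiser round-off)
are clamped to zero; larger deficits raise an error.

# The synthetic-data generator

`make_fixture()` emulates every input at toy scale with planted ground
truth. Its defaults are the study conditions under which the pipeline is
validated:

* a population of 40 diploid individuals genotyped at 5 true start-gain SNVs
  and at least 3 distractors of each rejection class (out-of-frame AUG
  creation, stop-interrupted novel CDS, variant inside an overlapping
  isoform's CDS, no AUG created), with planted carrier counts, one
  homozygous carrier, one missing genotype, one multiallelic record and one
  indel. Novel-CDS gaps of 3–30 codons and carrier counts of 2–6 are chosen
  so that the occupancy filter's three rules each remove at least one true
  call (gap < 5 codons, carriers < 3, X chromosome);
* a four-species comparative panel with 26 planted fixed start codons, 16 of
  them with at least 5 codons of novel CDS and 2 of those CUG-origin
  (matching the with/without-CUG analysis design), novel-CDS lengths from
  3 to 186 nt with a 30-nt median, plus two distractors per rejection class
  (polymorphic, outgroup-shared, chimp ortholog not in a 5'UTR, alignment
  gap at the divergent base). One locus is planted inverted in the chimp
  assembly (minus-strand MAF query), one gorilla ortholog carries a planted
  stop codon and one a one-codon deletion, exercising column dropping;
* ribosome footprints per sample (8 human, 5 chimpanzee, 30 000 signal
  reads each — enough for ~20 reads per background codon at this genome
  size, so per-anchor contrasts are well resolved while the suite stays
  fast): P-sites are drawn from a uniform background over each transcript's
  coding grid (novel CDS included, for carriers and non-carriers alike),
  multiplied by a 4-fold peak at active start codons — annotated starts for
  every sample, novel starts for carrier samples only, and a 2-fold residual
  at chimpanzee CUG orthologs. Within a codon, 80% of the mass sits on the
  first nucleotide and 10% on each neighbour, which plants both the 3-nt
  periodicity and the cleavage slop the occupancy rule is designed to
  absorb. Read lengths are uniform over 26–32 and the leftmost coordinate
  is back-computed from the P-site through the inverse offset rule, so both
  strands and all seven lengths exercise the P-site logic. Multimapped,
  out-of-length and blacklist-overlapping distractor reads are appended;
* novel CDSs evolved on the star tree with branch lengths 0.06/0.06/0.08
  expected substitutions per codon, kappa = 2, omega 0.36 on the human
  branch and 2.74 on the others — the purifying-foreground /
  relaxed-background contrast the branch models are meant to detect. These
  branch lengths are one to two orders above real great-ape divergence so
  that a ~400-codon concatenation carries enough substitutions for a stable
  toy-scale estimate.

What the generator does **not** emulate: sequencing error and base-quality
structure, indel evolution beyond single-codon gaps, alignment error,
paralogy (beyond one planted decoy block pair used to exercise the
one-to-one filter), population structure and linkage, translation-efficiency
variation between transcripts, and expression-weighted anchor usage. A green
test suite therefore demonstrates that the implementation applies its rules
exactly and recovers planted signal at realistic magnitudes — not that the
rules are robust to every artefact of real data.

# Numerical and coordinate conventions

Internally every coordinate is 1-based and closed on the forward genome
strand, the Bioconductor convention; GFF (1-based), VCF (1-based), BED
(0-based half-open) and MAF (0-based, strand-relative) are converted at the
I/O boundary only. All frame and length rules are difference-based, so the
convention choice does not touch the science; adopting the convention of
the surrounding ecosystem avoids a translation layer around every
`Biostrings`/`IRanges` call. Minus-strand MAF query intervals are
normalised to forward-strand coordinates on load.

Transcript coordinate mapping uses exon interval arithmetic and is verified
in the tests against an exhaustive per-base walk; the round trip
genome → transcript → genome is the identity on every exonic base of every
fixture transcript.

The test suite validates the likelihood machinery against brute-force
root-state enumeration (tolerance 1e-8), detailed balance and unit rate
scaling for random parameters, omega bias below 10% at omega in
{0.3, 1, 2.5} on 500-codon simulations, sign recovery of the
foreground/background design in at least 95% of 100 replicates, and LRT
type-I error within binomial error of the nominal 5% over 200 replicates.
The Wilcoxon implementation is checked against full sign-assignment
enumeration for every n up to 10. Problem sizes (500-codon alignments,
200-replicate calibrations, 30 000-read samples) were chosen as the
smallest at which these statistical checks have adequate resolution.

# Known limitations

* The chimpanzee 5'UTR requirement accepts any chimp transcript, not
  specifically the orthologous gene's; with real annotations a same-gene
  restriction would be stricter.
* The Fig.-style carrier contrast is a rank-sum test by default; the paired
  signed-rank alternative is available through `compare_anchor_classes()`,
  and the choice matters for small carrier groups.
* The branch model is a single-matrix family: no site models, no
  branch-site models, no synonymous rate variation. A significant LRT on
  concatenated novel CDSs supports selection on the pool, not on any
  individual CDS, and regulatory overlap of the region cannot be excluded
  as the selective agent.
* Genome-scale counts from real resources (thousands of SNVs, dozens of
  fixed codons) are not reproducible from synthetic data; the pipeline
  reproduces the *structure* of those results (call counts, attrition,
  fold enrichments, omega contrasts) under planted conditions.
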