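---
title: "Detecting and characterizing nuclear-embedded mitochondrial DNA segments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing nuclear-embedded mitochondrial DNA segments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fragments of the mitochondrial genome occasionally integrate into nuclear
chromosomes during double-strand-break repair. These nuclear-embedded
mitochondrial DNA segments (NUMTs) are polymorphic in human populations:
beyond the hundreds fixed in the reference assembly, individuals carry
insertions that are absent from the reference and segregate like any other
structural variant. They matter practically (NUMT-derived reads masquerade
as heteroplasmic mtDNA variants and can mimic paternal mtDNA transmission)
and scientifically (their junctions record the repair mechanism that created
them, and their sequences are molecular fossils of the mtDNA that existed at
insertion time).

`numtatlas` implements a complete short-read pipeline for this problem:
candidate detection from nuclear-mt discordant read pairs, base-pair
breakpoint refinement from soft-clipped split reads, junction mechanism
classification, detection of concatenated (multi-fragment) NUMTs from
mtDNA-mtDNA junctions, cohort-level unification with population frequency
classes, de novo (trio) and tumour-specific calling with exact binomial
insertion rates, permutation enrichment of insertion sites, and molecular
evolution of the inserted sequences (post-insertion variants, mutational
spectra, ancestral-allele-ratio ages). Because cohort-scale human data of
this kind are access-controlled, the package ships a synthetic-cohort
generator that produces paired-end alignments with planted NUMTs and a
machine-readable truth set; every pipeline stage is validated against that
truth.

## Detection model

A NUMT that is absent from the reference produces two signals in paired-end
alignments:

* **Discordant pairs** — fragments spanning an insertion junction with each
  mate cleanly anchored on one side align with one end on a nuclear contig
  and the other on the mitochondrial contig.
* **Split reads** — reads crossing the junction itself align partially, with
  the remainder soft-clipped.

Detection keeps read pairs with exactly one nuclear and one mitochondrial
end and discards any pair in which either mate has mapping quality zero
(applied to both mates; repeat-mediated mismapping is the dominant error
mode and MAPQ 0 marks it on either side). Anchors are clustered by
single-linkage at 500 bp, separately per nuclear contig and orientation
signature, where the signature is the (nuclear strand, mt strand) pair of
the anchors — the standard discordant-cluster convention. Single linkage in
one dimension reduces to splitting the sorted anchor starts at gaps above
500 bp, which is also what a brute-force all-pairs linkage yields; the tests
verify that equivalence. Distances are measured start-to-start.

Clusters below the support threshold are dropped. Two thresholds are used
throughout, mirroring a sensitive set (≥ 2 pairs) and a stringent set
(≥ 5 pairs); candidates within 1,000 bp on **both** genomes are grouped as
one NUMT, with the mtDNA distance computed circularly (control-region NUMTs
cross the origin). All internal coordinates are 0-based half-open; SAM
input/output and reported mtDNA positions convert at the boundary (1-based
inclusive), so there is exactly one convention inside the code.

## Breakpoints and junction mechanism

Split reads with a soft clip of at least 20 bp whose aligned portion lies
within 1,000 bp of a candidate are realigned: the full read is aligned
locally (match +1, mismatch −2, gaps forbidden — the simulator plants
substitutions only, and short-read indels at junctions are not modelled)
against the candidate's nuclear window (± 1,000 bp) and the full
mitochondrial genome, on both strands. For large subjects the dynamic
programming runs only inside windows pinned by exact 20-mer seeds from the
read's ends and middle, falling back to the full subject when no seed hits;
this changes nothing in the result for reads within the accepted identity
range, only the cost. A segment is accepted at ≥ 20 aligned bases and ≥ 90%
identity; a perfectly matching mt segment with more than one exact placement
is discarded as ambiguous (counted, not silently dropped).

The two segments' query intervals overlap where the junction carries
microhomology (the shared bases align to both references) and leave a gap
where non-templated bases were inserted; exactly one of
`overlap > 0`, `gap > 0`, or neither is possible per read. Breakpoints are
the modal positions across supporting split reads, per junction side, with
ties resolved to the smaller coordinate (determinism); a side is reported
only with ≥ 3 split reads, and a candidate with two well-separated
well-supported nuclear breakpoints is flagged complex rather than forced
into the one-nuclear/two-mt shape. Because reads are stored
reference-forward, the *query* order of segments flips for reverse-oriented
inserts; the physical junction side is therefore derived from the nuclear
segment's strand, not from query order.

Junction classification re-derives microhomology from the reference: the
longest identical overlap (scanned to 30 bp) between the nuclear flank and
the mt flank across the called junction. Non-templated junction bases
observed in the split reads make the insertion class; otherwise
microhomology length ≥ 1 is MMEJ-like and zero is blunt. The three classes
partition all junctions by construction. The reported breakpoint sits at the
mt-proximal end of any homology tract, and the recorded length lets a
consumer recover the ambiguity interval — within a microhomology tract the
true junction is genuinely unknowable.

Sequence context tallies the trinucleotide centred on each breakpoint base
(± 1 bp, reverse-complemented for reverse-oriented inserts; the anchoring of
the window is a convention, stated here because nothing in the junction
model fixes it). Poly-C extension counts breakpoints whose k ∈ {2, 3, 4}
bases immediately beyond the mt breakpoint are all C (all G on the minus
strand) against an i.i.d. mononucleotide null, N·f_C^k with f_C the mt
genome C frequency, with a binomial test. The i.i.d. null is the simplest
defensible background; a positional or dinucleotide background would change
the expected counts and is deliberately not assumed.

## Concatenated NUMTs

Multi-fragment (mega-)NUMTs reveal themselves through split reads whose two
segments both lie on the mitochondrial genome. Only reads aligning *solely*
to mtDNA count: a read whose second segment aligns as well or better to the
nuclear genome is excluded, which removes outer nuclear-mt junction reads
and chance flank similarities. Junctions are collapsed across samples at
± 5 bp (realignment jitter; the collapsing tolerance is a convention) and
then filtered in order: (1) ≥ 3 split reads in at least one individual;
(2) ≥ 2 split reads per retained carrier; (3) neither position inside the
D-loop terminus exclusion windows — junctions at the control-region ends
cannot be distinguished from true mtDNA with short reads, so positions
16,470–16,569 and 1–100 are excluded by default (the window width is
configurable; no principled width exists, this one is conservative);
(4) circular separation ≥ 50 bp, since closer pairs are indistinguishable
from mtDNA deletions. On fixtures where each junction violates at most one
filter the cascade's output is order-independent.

Trio transmission uses presence = ≥ 1 split read in a parent (maximal
sensitivity for excluding de novo status): child + father only is
father-transmitted, child + mother only mother-transmitted, both or neither
indeterminate, with child-only flagged as a candidate de novo. Carriers of
rare junctions (F < 1%) are cross-referenced for whether they share a NUMT
call.

## Cohort statistics, trios and tumours

Cohort unification reuses the 1,000 bp both-genomes single-linkage rule
across samples; representative coordinates are medians of member
breakpoints (refined breakpoints preferred over cluster footprints), ties
to the smaller coordinate. Carrier frequency F is computed over individuals
(one genome each); classes are common (F ≥ 1%), rare (0.1% ≤ F < 1%) and
ultra-rare (F < 0.1%), boundaries inclusive on the common/rare side, with
private = confined to one family (singletons are their own family). A call
is "known" when a known-NUMT interval overlaps the call extended by 500 bp
flanks, regardless of the mtDNA fragment — known status concerns the
nuclear site, not the insert.

De novo calls require ≥ 5 discordant pairs in the child and no parental
evidence; parental evidence is screened at the permissive ≥ 2-pair level on
calls made with `min_support = 1`, a deliberate asymmetry (sensitive where
an error creates a false de novo). The junction-spanning sequence must also
lack a second near-perfect nuclear placement (≥ 95% identity over ≥ 90%
length vetoes), a desk-scale analogue of checking de novo sequences against
whole-genome assemblies. Tumour-specific calls require ≥ 5 pairs in the
tumour and none in the matched normal (optionally absence from all
non-cancer genomes); lost NUMTs are the mirror image with ≤ 1 stray tumour
pair tolerated.

Insertion rates are exact quotients with Clopper–Pearson 95% intervals
(Beta-quantile form; lower bound 0 at zero events, upper bound 1 at
saturation). The 2×2 carrier association reports the sample odds ratio
(a·d)/(b·c) with a 0.5 continuity correction only when a cell is zero, the
two-sided Fisher exact p under the probability-mass rule, and a
normal-approximation interval on the log odds ratio alongside the exact
test's conditional interval — the two intervals differ in general and both
are exposed.

## Permutation enrichment

The observed statistic is the number of NUMTs whose ± 100 bp flank
intersects an annotation track. Null replicates place the same number of
positions uniformly on the same chromosome as each observed NUMT
(count-and-chromosome matching; flanks are fixed-width so no length
matching is needed, and chromosome matching preserves large-scale
composition). The two-tailed empirical p is 2·(1 + r)/(N + 1) with r the
as-or-more-extreme count in the observed direction, doubled and capped at
1 — the add-one rule keeps p ≥ 2/(N+1) and never exactly zero. The Y
chromosome is excluded throughout. Because the statistic is a discrete
count, the doubled two-tailed p is conservative when the number of
positions is very small; with a couple of hundred positions, as in
cohort-scale use and in the calibration benchmark (200 positions per test),
the null rejection rate at 0.05 sits within two points of nominal.

The same machinery drives mtDNA-region enrichment (uniform null on the
circular genome; regions from a packaged rCRS/MitoMap-convention table — a
configuration file, user-overridable, with the 22 tRNAs combined into one
region), nearest-feature distance summaries (distance 0 inside a feature;
chromosomes without features yield an infinite sentinel and are excluded
from summaries with their count reported), a 100 bp-window Pearson
correlation between NUMT and mtDNA-deletion breakpoints, and an OLS
regression of per-chromosome NUMT counts on chromosome length plus eleven
log2-transformed genomic-feature proportions (rank deficiency is an error
naming the collinear columns, not a silent drop).

## Molecular evolution

Per (NUMT, carrier), insert-derived reads — the aligned portions of
mt-mapped reads within the fragment span, all in mt-forward orientation —
are assembled by greedy overlap-layout consensus: repeatedly merge the pair
of contigs with the longest exact suffix–prefix overlap ≥ 25 bp (ties to
the lexicographically smaller merged string), with base calls by column
majority over all placed reads. Contigs that never reach an exact overlap
are placed onto the largest contig tolerating ≤ 10% mismatches so minority
alleles still vote; failing that the assembly is flagged fragmented and the
largest contig is used. Exact 50–50 column ties resolve to the reference
base. The 25 bp threshold is comfortable at 150 bp reads and ≥ 15×
coverage, where adjacent read starts are ~20 bp apart.

Variants are consensus-versus-mtDNA mismatches passing an ordered cascade:
NUMTs shorter than 1,000 bp only (longer assemblies are unreliable);
variants more than 5 bp from both fragment breakpoints (junction artefacts);
reference-allele concordance; single-nucleotide changes only; exclusion of
the rCRS low-complexity regions (66–71, 300–316, 513–525, 3,106–3,107,
12,418–12,425, 16,182–16,194 — the same alignment artefacts affect NUMT
consensus as mtDNA variant calling, and the exclusion is toggleable); and
removal of carriers whose variant count exceeds the cohort mean + 3 sd.
NUMT-specific status then removes variants carried by more than 50% of a
common or rare NUMT's carriers (75% for ultra-rare) — those likely predate
the insertion. Survivors form group A; group B removes singletons; group C
keeps variants seen in ≥ 2 members of one family. C ⊆ B ⊆ A by
construction, and a clean simulated cohort yields zero variants.

Coding effects use codon lookup under the vertebrate mitochondrial genetic
code, strand-aware; variants outside protein-coding regions get effect NA
but still count in the 96-class pyrimidine-centred trinucleotide spectrum
(purine-reference variants are reverse-complemented first). An optional
signature matrix yields cosine similarities; no signature data are shipped.

Ages come from the ancestral-allele ratio: at sites where the human and
chimpanzee mitochondrial sequences differ, a NUMT frozen at insertion time
carries the ancestral allele at every human-lineage change that postdates
the insertion. With r the fraction of informative sites matching the human
allele, age = (1 − r) × 6 Myr — the linear form that follows from mutations
accruing uniformly on the human mtDNA lineage since a 6 Myr divergence.
Sites are classified per carrier and accepted only when more than half of
the carriers agree (per-individual classification with majority agreement;
aggregating on a cohort consensus instead would hide carrier disagreement).
Filters: fragment length 50–1,000 bp, ≥ 1 informative site, ≥ 2 carriers,
concatenated NUMTs excluded.

## The synthetic cohort generator

Donor haplotypes are nuclear reference sequences with mtDNA-derived inserts
spliced at declared positions, each insert carrying its declared junction
spec (microhomology bases appear once; non-templated bases belong to no
reference), optional post-insertion variants restricted to declared
carriers, and an age signal: each human-chimp informative site in the
fragment reverts to the ancestral allele with probability `age_fraction`,
so `age_fraction` equals expected age / 6 Myr. The packaged mitochondrial
and chimpanzee-ancestral sequences are deterministic synthetic stand-ins
(16,569 bp; 8% divergence, a realistic mitochondrial figure) — real
sequences can be supplied as FASTA. Every donor keeps an explicit block map
from donor to reference coordinates, so simulated reads are aligned by
construction: uniform fragment placement at the design depth, fragment
lengths Normal(400, 50) truncated at the read length (150 bp), junction
reads soft-clipped at the junction, MAPQ 60 except in declared decoy-repeat
regions (MAPQ 0), sequencing errors off by default (detection thresholds
are count-based; error modelling is orthogonal and available as a uniform
substitution rate). The simulation is a pure function of the design and its
seed.

One subtlety is deliberate: the generator *realizes* its declared junction
ambiguity exactly. The nuclear flank bases at each insertion point are
adjusted so the observable microhomology equals the declaration and no
spurious alignment extension crosses the junction, and fragments whose
forced flank bases cannot satisfy those constraints are re-drawn
(`sample_numts`). Without this, accidental 1–2 bp homology would make
"exact breakpoint recovery" ill-defined rather than a testable property.

What the generator does **not** emulate: GC and coverage bias, indels and
realistic error profiles, contamination, heterozygosity (one haplotype per
sample), reference NUMTs already present in the assembly, and free
cytoplasmic mtDNA reads. Passing tests therefore demonstrate the logic of
the calling rules and estimators under clean signal, not robustness to
real-data artefacts — the MAPQ-0 decoy mechanism and the error-rate switch
exist precisely so robustness questions can be posed explicitly.

## Validation benchmarks and problem sizes

The `benchmark_*` functions fix the study conditions used by the validation
suite and the analysis scripts: detection on 20 samples at 30× with ten
NUMTs of 100–2,000 bp across a 100 kb nuclear genome (recall at the
sensitive threshold, precision, blunt-junction breakpoint exactness); trio
calling on 50 trios with five child-only and five inherited events; one
concatemer with a deletion-like (< 50 bp) and a D-loop-terminus decoy;
permutation calibration over 400 null tests at N = 1,000 with 200 positions
each; age recovery over 50 NUMTs of 450–950 bp at `age_fraction` 0.25
(planted age 1.5 Myr) with two carriers each. In the age benchmark,
carriers are assigned so no genome carries two NUMTs with overlapping mt
fragments: overlapping fragments in one genome contaminate each other's
consensus pile-up (a real paralogy effect worth studying, but one that
would confound a calibration benchmark). These sizes complete in a few
minutes on one CPU; they are desk-scale by design, chosen so the whole
validation runs routinely rather than occasionally.

## Known limitations

* Breakpoint exactness is guaranteed only for blunt junctions; within a
  microhomology tract the breakpoint is ambiguous by biology, and the
  reported position is a convention (mt-proximal end).
* The concatemer detector cannot see junctions at the D-loop termini — the
  exclusion windows trade sensitivity for specificity there, as any
  short-read method must.
* The greedy assembler assumes low-error reads; it is not a general-purpose
  assembler and fragments under heavy error or very low coverage.
* The age estimator's clock is linear in the ancestral-allele ratio and
  saturates for very old insertions; with few informative sites individual
  ages are noisy and only cohort-level means are meaningful.
* Fisher's exact p uses the probability-mass rule; the tail-doubling rule
  would give slightly different two-sided p-values.
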