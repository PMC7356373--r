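---
title: "Methods: screening yeast genomes for domestication signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening yeast genomes for domestication signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`domestiscan` reconstructs, at desk scale, the genomic workflow used to
characterize *Saccharomyces cerevisiae* populations and their lifestyles:
per-strain consensus sequences aligned to a reference are quality-masked
and reduced to a concatenated SNP alignment; highly heterozygous strains
are phased from read fragments; a distance phylogeny with bootstrap
support recovers population clades; marker genes diagnostic of
domestication are screened for presence and integrity; gene copy numbers
are estimated from coverage ratios; *MEL* α-galactosidase alleles are
typed against a labelled panel; and a rule set converts each strain's
marker profile plus its isolation niche into a wild / domesticated /
feral call.

The package's synthetic-data module is first-class: it generates the
reference, the strain panels, the coverage and the truth tables under the
same statistical assumptions the analysis makes, so every downstream
claim is tested by recovery rather than by fiat.

# Consensus masking and the SNP matrix

A consensus base is kept iff its Phred quality is at least Q40
(`phred_accuracy(40)` = 99.99%); "below Q40" is strict, so a Q40 base
survives. Anything that is not an unambiguous base or a two-base IUPAC
heterozygous code is masked to `N`.

A column enters the SNP matrix iff (i) at least 85% of strains carry a
single unambiguous base at that position and (ii) at least two distinct
bases occur among those calls. Two genuinely open readings of the
call-rate rule exist: site-level call rate (adopted here) versus a
requirement on the variant allele's frequency. The latter would discard
nearly every biologically informative site, so the call-rate reading is
used; heterozygous IUPAC calls count as *ambiguous* for the rule, because
heterozygous strains are phased separately and an unphased genotype call
contributes no single allele. The fraction comparison is carried out in
integer arithmetic on the threshold rounded to four decimals
(`n_call * 10^4 >= round(f * 10^4) * n`), so boundary cases such as 6/7 ≈
0.857 against 0.85 are decided exactly and reproducibly.

Ambiguous calls are written as `N` in the concatenated alignment; the
column map records `(index, chrom, pos)` with 1-based positions
(internally the generator uses 0-based half-open arithmetic only where
splicing requires it; every reported coordinate is 1-based inclusive).

# Phasing

Strains with strictly more than 20,000 qualifying heterozygous sites
(IUPAC call, quality ≥ Q40) are selected; the threshold is applied
genome-wide, which is the natural reading when a single selection is made
per strain. Phasing is a greedy fragment-graph algorithm: sites in
genomic order; each new site joins the phase supported by the majority of
fragments linking it to already-phased sites, ties toward phase 0;
fragments conflicting with both inferred phases at ≥ 2 sites are dropped
once (emulating the exclusion of misaligned-read errors) and the
component re-phased. One haplotype is chosen uniformly at random per
connected component — per component rather than per strain, because
components carry independent phase information; the seed and every choice
are recorded. Strains whose heterozygous-site count exceeds twice the
panel median are flagged as possibly >2n.

# Phylogeny

Trees are neighbor-joining on either the proportion of differing sites
(p-distance) or the Tamura 1992 three-parameter distance

d = −h·ln(1 − P/h − Q) − ((1 − h)/2)·ln(1 − 2Q),  h = 2θ(1 − θ),

with P and Q the transition and transversion proportions and θ the GC
fraction of the two sequences pooled (computed per pair, over the
pairwise-deleted comparable sites). Saturated pairs (log argument ≤ 0)
return `NA` and abort matrix construction with a pointer to the
p-distance. Ambiguous sites are pairwise-deleted throughout; whether
complete deletion was used in the original gene trees is unknowable from
the text, and pairwise deletion wastes less signal on panels with
scattered Ns.

A full maximum-likelihood treatment is deliberately out of scope: the
consumed outputs are clade membership and support, which the distance
tree reproduces on the package's panels. Branch lengths from a SNP-only
alignment are inflated by ascertainment (invariant sites are absent) and
are labelled as SNP-scale; they should not be read as substitutions per
genomic site. Bootstrap support is the fraction of column-resampled
replicates containing each bipartition; negative NJ branch lengths are
clamped to zero, taxa are sorted by label before tree construction so
ties resolve deterministically, and rooting places the root at the
midpoint of the outgroup's pendant edge.

# Marker screen

Each marker is located by exact 31-mer seeding: the fraction of the
query's k-mers found in the strain sequence calls presence (≥ 0.5),
absence (< 0.1) or a partial hit (between the bands). These bands and k
are package choices — at k = 31 a 2% diverged copy retains ~53% of its
k-mers and is still called present, while ~5% divergence falls to
partial, which is why the *MEL* screen passes every allele-panel
reference as an additional query (divergent allele groups share almost no
exact 31-mers with any single query). Seeded hits are confirmed by global
pairwise alignment (match +1, mismatch −1, gap open 2, extend 1) and
identity is reported over aligned non-gap columns; presence with
identity < 0.95 raises a divergent-allele flag (the situation of a
distinct *RTM1* allele).

CDS integrity distinguishes the two inactivation classes: an indel whose
length is not a multiple of three (frameshift) and an in-frame stop
strictly before the reference terminal codon (premature stop, as in the
olive-clade *SUC2*). Aquaporin lesions are matched against a signature
table of known population types; premature stops must match at the
codon, frameshifts at the signed length with a ±15 bp positional
tolerance because affine alignment can slide a gap within repeats. A
lesion set matching no known type is "novel" — deliberately so for wild
high-sugar populations, whose private inactivations must not be read as
domestication.

The STA1 promoter scan aligns the reference promoter to the located
region and reports the largest contiguous gap run in the strain sequence.
This alignment uses its own scoring (gap open 25, extension 0.25): a
kilobase deletion must stay a single cheap run. With ordinary extension
costs the optimal alignment absorbs a long deletion as a mismatch wall
against downstream sequence, and with a cheap opening cost it fragments
the run around accidental matches; the high-open/cheap-extension pair
makes the single-run representation optimal across deletion lengths from
1 bp to nearly the whole promoter. When not even one seed k-mer survives
(deletion of essentially the entire promoter), the scan returns `NA`
with a warning rather than a guess.

# Copy number

Copy number is median depth over the gene divided by median depth over
all nuclear positions pooled. Pooling (rather than per-chromosome medians
averaged) is one of two defensible readings of "the coverage of each
nuclear chromosome"; pooling was chosen because it is well-defined for
any chromosome count and identical to the per-chromosome value in the
package's single-chromosome default. Medians, not means, at both levels,
for robustness. Both the raw ratio and the nearest integer (half away
from zero) are reported, since it is not stated whether published integer
copy numbers were rounded ratios. At 50× depth and gene lengths in the
1.4–2 kb range the integer estimate is correct in ≥ 99% of seeded
replicates pooled over multiplicities 1–12; the residual misses sit at
the highest multiplicities, where the sampling noise of a median over
~10 read-length-correlated blocks approaches half a copy.

# MEL typing

The synthetic allele panel encodes the published divergence structure:
Asian I, Asian II, Asian-American and European each 5% from a hidden
common ancestor (≈ 10% pairwise), the African I/II and South American
block ≈ 20% from the Asian block, African II carrying a premature stop
(a pseudogene), and outgroup sequences placed with the African block.
Every group has its own stem branch so that two-reference groups remain
clades when queries nest inside them.

Assignment minimizes the mean Tamura-92 distance to each group's
references (mean rather than best single reference, to damp within-group
variance); the margin to the runner-up is reported and margins < 0.01
are flagged ambiguous. Recombinants are detected in 200 bp windows every
50 bp: the allele is chimeric when a contiguous prefix and suffix of
windows are won by different groups, each spanning ≥ 25% of windows, and
the breakpoint is reported as the window range around the switch. Window,
step and span are package choices — the original recombinant was found by
phylogenetic inspection, which prescribes no parameters. Phenotype
discordance (melibiose-negative strains with apparently functional genes)
is representable only as annotation, never inferred from sequence.

# Lifestyle classification

The rule set is data, not code. Default signatures: any of regions A/B/C
present; an aquaporin inactivation matching a *known domesticated* type;
*RTM1* present; *STA1* present; *MEL* copy number ≥ 4. Calls:
fermentation niche + ≥ 1 signature → domesticated; arboreal niche + ≥ 1
signature → feral; natural niche (arboreal or high-sugar) + 0 signatures
→ wild; otherwise unclassified. A high-sugar wild strain may carry a
novel-type aquaporin lesion without losing wild status, since such
inactivations arise naturally in sugar-rich niches. The niche is
user-supplied isolation metadata and is never inferred. A MAL-expansion
signature can be added through the generic copy-number mechanism but is
not in the default set because no threshold for it is established.
No closed list of domestication signatures exists in the literature this
mirrors; the default set is assembled from the marker analyses above and
is explicitly editable, which is also the honest representation of what
is, in the original, expert judgment applied clade by clade.

# The synthetic generator: what it does and does not emulate

Each population preset fixes a SNP divergence from the reference backbone
(0.01–0.025 in the defaults), an absolute heterozygous-site count (1,000–
2,000 for diploid-like strains; 25,000 for the >2n beer preset, placing
it above the phasing threshold), marker states, the STA1 promoter state,
a *MEL* group and per-strain copy multiplicities (the olive preset cycles
4, 5, 6, 10, 11 — the last two being the largest arrays on record for
that clade), and the truth lifestyle. Strains of a preset share ~93% of
their derived variants (each backbone variant kept with probability 0.95
plus 2% private variants), giving clean clade signal. Heterozygosity is
two haplotypes differing at randomly placed sites, encoded as IUPAC codes
in the consensus. Reads are placed uniformly with Poisson counts and no
sequencing-error model by default (the Q40 mask models quality, not
errors, and error-free reads keep downstream oracles exact). Depth over
the *MEL* locus is boosted to multiplicity × genome depth, emulating
reads from all array copies mapping onto the single reference locus.
Markers sit at fixed catalog loci identical across strains, so
presence/absence logic is isolated from locus discovery.

Length-changing lesions (frameshifts, the 1162-bp promoter deletion)
are physically present in each strain's *assembly*, which is what the
marker screen consumes; the reference-coordinate consensus keeps the
intact allele at such loci so that SNP-matrix coordinates stay aligned.
Absent markers appear as `N` runs in the consensus and as unrelated
sequence in the assembly, with zero read coverage.

Not emulated: recombination maps, indel polymorphism outside lesions,
contamination, mitochondria, structural variation of marker loci, GC
coverage bias, and sequencing error. Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical assumptions,
not robustness to artifacts real short-read data can show; the Q40 mask
and the conflict-dropping step in phasing are the only error-facing
mechanisms, and they are exercised by explicit error injection
(quality strings, fragment error rates) rather than by a read simulator.

# Problem sizes and defaults

The default study panel is eight single-strain populations on one 250 kb
chromosome — large enough for >25,000 SNP columns, 25,000 heterozygous
sites in the polyploid-like preset, every marker locus with ≥ 500 bp
spacing, and a genome in which absent-marker loci (zero coverage) remain
a small minority of nuclear positions so the genome-median depth stays
unbiased — while keeping a full pipeline run in seconds. Read length
defaults to 150 bp and depth to 50×, ordinary values for the platform
class the analysis assumes; neither is stated in the source material.
Clade-recovery tests use two strains per population and 100 bootstrap
replicates; the *MEL* gene tree uses 1,000 replicates at 1.4 kb. The
copy-number recovery study uses 108 seeded replicates across
multiplicities 1–12 on 2 kb genes at 50×.

# Known limitations

* The marker screen's exact-k-mer seeding is blind beyond ~7% divergence
  with a single query; sensitivity is recovered by querying with allele
  panels, as done for *MEL*, not by approximate seeding.
* The promoter scan measures one dominant deletion; multiple comparable
  deletions in the same promoter would be reported by their largest run
  only.
* Copy-number estimates assume array copies are near-identical to the
  reference locus (reads map there); diverged paralogs would undercount.
* The lifestyle rules are a reproducible approximation of per-clade
  expert judgment; strains from unknown niches are unclassified by
  design rather than guessed.
* SNP-scale branch lengths carry ascertainment bias; only topology and
  support are meant for interpretation.
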