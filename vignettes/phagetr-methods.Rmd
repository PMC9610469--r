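---
title: "Methods and design of phagetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of phagetr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phagetr` characterizes tailed-phage (*Caudoviricetes*) genomes that
carry terminal repeats, from raw sequence features through ecology and
phenotype association. This vignette explains the models and decision
rules each stage implements, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## Terminal repeats

A genome assembled through a circular replication intermediate begins
and ends with the same sequence (direct terminal repeat, DTR); a
protein-primed replicator ends with the reverse complement of its start
(inverted terminal repeat, ITR). `detect_terminal_repeats()` calls a
repeat when the two ends match **exactly** over at least `min_len`
nucleotides (default 20 nt). Exact matching is deliberate: the
convention this threshold comes from uses identical termini, and a
20-nt exact match already has a ~10⁻¹² chance per genome of arising in
random sequence, so no mismatch tolerance is needed at this length.
The search is capped at half the sequence length so the two copies
cannot overlap. The ITR condition is nested in the repeat length
(a k-nt match implies a (k−1)-nt match), so the detector reports the
leading run of agreement between the sequence and its reverse
complement; the DTR condition is not nested and every candidate length
is probed, with cheap single-base anchors before each full comparison.
Note the detector reports the *longest* match, which can exceed a
planted repeat by a few bases when flanking background happens to agree.

## Skew profiles

GC skew (G−C)/(G+C) and AT skew (A−T)/(A+T) are computed in 1001-nt
windows placed every 200 nt starting at position 1, for as long as a
complete window fits. A window with a zero denominator yields `NA`.
The cumulative GC skew (running sum over windows, missing windows
contributing zero) gives the classic V-shaped curve at the replication
origin of bidirectionally replicating genomes.

## Intragenomic repeats and DGR candidates

`find_self_repeats()` reproduces a BLASTN self-comparison screen at
desk scale with an internal seed-and-extend aligner: exact 11-mer
seeding, merging of co-diagonal seeds (gaps up to 60 nt), and ungapped
X-drop extension (+1 match / −2 mismatch, drop 12). Identity is matches
divided by alignment columns. Gapped extension is not attempted — the
downstream contract is thresholds on length (≥ 100 nt) and identity
(≥ 80%), and at those thresholds ungapped chains of exact seeds
recover duplications while a 75%-identity copy (mismatch every ~4 nt)
cannot seed. The trivial self-identity diagonal is excluded and
symmetric pairs are reported once, with `start_a < start_b`.

A diversity-generating retroelement (DGR) candidate is a reverse
transcriptase gene plus a repeat pair with at least one repeat within
`proximity` of the RT gene. The source description of this signature
says only "close proximity" without a number; the default here is
**1000 nt, a package choice**, configurable per call. Repeat pairs that
merely restate the genome's terminal repeat are excluded when the
terminal-repeat call is supplied.

## Genetic-code assignment

Some gut phages reassign a stop codon: code 4 reads TGA as tryptophan,
code 15 reads TAG as glutamine. Under the standard bacterial code 11
the genes of such genomes shatter at the recoded codon; reading the
codon as sense fuses them back into long ORFs. `assign_genetic_code()`
exploits exactly this signal:

- ORFs are maximal stop-to-stop stretches in all six frames, trimmed to
  the first ATG/GTG/TTG start, minimum 300 nt, with greedy
  non-overlapping selection by descending length.
- The default coding score is the summed length of the selected ORFs.
  A gene caller's per-gene coding scores can be substituted through the
  `scores` adapter of `score_coding_potential()` when reproducing a
  score-based pipeline exactly; the length total preserves the decisive
  fusion signal while keeping the package self-contained.
- An alternative code is assigned only to sequences of at least 20 kb,
  and only when its total **strictly exceeds** 1.10 × the standard-code
  total ("exceeds by 10%" is read as a strict inequality). Below 20 kb
  the standard code is always kept — short sequences do not provide
  enough ORF mass for a reliable comparison. If both alternative codes
  clear the margin the higher score wins; an exact tie falls back to
  code 11 (conservative, since the tie carries no signal).

## Marker taxonomy

Taxonomic assignment consumes profile-search hit tables rather than
running the searches: hits at E ≤ 0.001 are retained, and protein
annotation requires ≥ 100 aa of the protein covered by a profile's hits
(envelope coordinates, overlaps merged), the maximal-coverage profile
winning (ties: lower E-value, then profile id). The class
*Caudoviricetes* call requires a terminase-large-subunit (TerL) hit
spanning three diagnostic motif columns (second acidic residue of the
Walker B motif, first acidic residue of nuclease motif I, the acidic
residue of nuclease motif II); these are consumed as per-hit boolean
flags because profile column bookkeeping belongs to the search tool,
while the decision rule belongs here. A *Herpesviridae* MCP hit on the
same sequence overrides TerL (herpesviruses carry an evolutionarily
related terminase). *Nucleocytoviricota* calls are additionally gated
on an external validator score > 2 with at least one recovered marker.
Conflicting non-TerL markers — a combination never expected in real
data — yield `unassigned` with a warning rather than a silent
preference.

## vOTU clustering

Species-level clustering is greedy centroid clustering over pairwise
ANI records: sequences are visited longest-first (ties by id); a
sequence joins the earliest centroid with ANI ≥ 95% and ≥ 85% of the
**member** sequence covered by the alignments, else founds a new
centroid. Interpreting the coverage threshold against the member
(shorter) sequence is what lets near-complete subsequences be absorbed
into longer centroids. ANI is the alignment-length-weighted mean
identity; alignments may be supplied as BLAST-style tables or computed
with the internal aligner.

Representatives: if a vOTU has members with terminal repeats, the
terminal-repeat member whose length is the median of those members'
lengths is chosen — a complete genome of typical length. With an even
member count the arithmetic median falls between two lengths; the
member closest to it is taken, ties going to the shorter genome and
then the lexicographically smaller id (the even-count case is not
specified by the rule's source; this tie-break is a package choice
made for determinism). Without terminal-repeat members, the longest
TerL-encoding member is used, falling back to the longest overall.

## Quantification

Abundance of a vOTU in a sample is `(N·10⁶)/(L·S)` — reads mapped to
the representative genome per million sample reads, normalized by
genome length — and is zero when breadth of coverage is **below 75%**;
exactly 75% detects (strict reading of "below"). `N` is taken from the
mapping record rather than inferred from depth mass, matching the
separate breadth/count computations of standard mappers. Prevalence is
the percent of a cohort's samples with detection; "highly prevalent"
requires strictly more than 5% in at least one cohort.

## Stability testing

The test asks whether phage community profiles from the same individual
years apart are more similar than profiles from different individuals.
Bray–Curtis dissimilarity `Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ)` is computed for
intra-individual cross-timepoint pairs and for inter-individual pairs
**within each timepoint separately** (then pooled); vOTUs detected
nowhere and samples with nothing detected are excluded first. The
observed statistic is the p-value of a **two-sided unpaired rank-sum
test** with normal approximation, tie correction and continuity
correction. The procedure this follows names a "signed-rank" test but
states unpaired two-sided parameters; the parameters are authoritative
— intra and inter pair sets have different sizes and no natural
pairing, so only the unpaired test is defined. Each of the (default)
10,000 iterations permutes the dissimilarity values across the pooled
pair slots and recomputes the rank-test p-value; since the pooled
values are fixed, only the rank subset assigned to the intra group
changes, which makes each iteration a draw of rank sums. The empirical
p-value is the fraction of permuted p-values **strictly below** the
observed one (ties do not count), so its resolution is 1/iterations.
All inter-individual pairs are used rather than a subsample.

## Host prediction

Three routes, then reconciliation:

- **Prophage fragments**: host-genome fragments ≥ 1000 nt flanking
  prophage contigs are matched to microbial references at ≥ 95%
  identity and ≥ 1000 nt alignment length; each fragment is assigned
  the target with maximal merged query coverage; more than 100
  fragments per vOTU are subsampled to 100 under the supplied seed.
  Fragment assignments conflicting at the host phylum level void the
  vOTU's prediction; otherwise the consensus lineage (deepest shared
  rank prefix) is reported.
- **CRISPR spacers**: matches are deduplicated — several spacers of one
  host on exactly the same phage region, or one spacer on several
  regions, collapse to the highest-scoring match. A host links to a
  vOTU on one full-length match at ≥ 95% identity over the spacer, or
  on at least two deduplicated matches at ≥ 80% ("multiple" is read as
  ≥ 2). Identity is always computed over the full spacer length.
  The internal matcher (`match_spacers()`) scans both strands allowing
  the mismatch budget implied by the identity floor; its score
  (+2 match / −3 mismatch) only ranks matches during deduplication.
  Phylum-conflicting links void the prediction.
- **Co-abundance**: per-cohort Spearman correlations between taxon and
  vOTU abundances (taxa present in more than 10 samples of the cohort)
  are pooled on the Fisher-z scale, `z = atanh(r)`, variance
  `1/(n−3)`, with the Sidik–Jonkman heterogeneity estimator: initial
  `τ₀² = mean((z−z̄)²)`; weights `u = 1/(v/τ₀²+1)`; `τ² =
  Σu(z−μᵤ)²/(k−1)`; pooled weights `1/(v+τ²)`. Homogeneous inputs
  (τ₀² = 0) fall back to the fixed-effect pool, and a single cohort
  reduces to its own estimate. Each vOTU's host is the taxon with the
  minimal Benjamini–Hochberg FDR across all pairs (ties: larger
  |pooled r|, then name). Correlations of exactly ±1 are shrunk to
  ±0.999999 before the z transform.

When prophage- and CRISPR-based predictions disagree at the phylum
level, the prophage prediction wins — physical attachment of host
sequence to the prophage contig is more direct evidence than a spacer
match. The co-abundance call is reported alongside with a phylum
agreement flag, never overriding sequence-based evidence.

## Association analysis

For each (vOTU, phenotype) pair, detection is regressed on the
phenotype by logistic regression (IRLS via `glm`, tolerance 10⁻⁸, 100
iterations) in two models: adjusted for age and sex, and additionally
for the log-transformed abundance of the predicted host. Zeros in host
abundance are handled with a pseudocount of **half the smallest nonzero
abundance in the analysis** (the source procedure does not state its
zero handling; this choice is scale-respecting and standard).
Continuous phenotypes are standardized for coefficient comparability;
sex is a binary indicator. Complete separation or non-convergence flags
the fit and excludes it from FDR correction, which is applied within
each model family. Comparing the two models is the point: an
association that vanishes under host adjustment is parsimoniously
explained by the host, not the phage.

## The synthetic-data generator

The generator produces inputs with planted, exactly known truth.

- **Genomes** are i.i.d. nucleotides at a requested GC fraction —
  which makes spurious ≥ 20-nt terminal matches and ≥ 100-nt
  self-repeats vanishingly improbable — with elements planted in:
  terminal repeats copied (or reverse-complemented) onto both ends;
  genes laid out left to right separated by 12-nt walls containing a
  TAA stop in every frame on both strands, so reading frames never run
  across gene boundaries under any candidate code; an optional RT gene
  with a repeat pair (one copy ~100 nt away, one distant); and
  protospacers overwritten at requested positions (collisions with
  planted elements are rejected). Genes are 330–370 random sense
  codons; under codes 4/15 the reassigned stop codon is included as a
  sense codon at 6% per position. Test genomes pack genes to roughly
  85–90% coding density, the realistic value for tailed phages, whose
  genomes are famously compact; at sparse coding density the
  informationless background itself inflates alternative-code scores
  (fewer stop codons means longer random ORFs), which is a property of
  random sequence, not of the assignment rule.
- **Communities**: log-abundances are standard normal latent variables
  per individual; a coupled (taxon, vOTU) pair shares a Gaussian copula
  whose Pearson correlation 2·sin(π·ρ/6) yields the target Spearman ρ
  exactly in the large-sample limit. The second timepoint adds
  N(0, σ) noise on the log scale (σ = 0 gives identical profiles).
  Detection is a positive latent (~50% prevalence). Phenotypes are
  built from linear predictors on the latent log host abundance
  (host-mediated) or on phage detection (direct), through a logistic
  link for binary phenotypes.
- **Depth tracks**: uniform read starts, truncated at the 3' end;
  dropout intervals are zeroed after accumulation, emulating an
  unmappable region.

What the generator does **not** emulate: sequencing errors and read
noise, assembly artifacts and chimeras, GC-dependent coverage bias,
compositionality of real abundance data, phylogenetic correlation
among taxa, and real CRISPR array structure. Passing tests therefore
demonstrate that the decision rules and statistics are implemented
correctly and recover planted signals under their stated assumptions —
not that those signals survive every artifact of real metagenomes.

## Problem sizes and numerical choices in the test suite

The suite exercises: the terminal-repeat detector against a brute-force
substring oracle on 1000 random genomes with planted repeats of 19–500
nt; genetic-code recovery on 200 25-kb genomes (100 alternative-code,
100 standard); greedy clustering against an independent brute-force
execution on 200 random instances of up to 50 sequences; the
meta-analysis against an independently coded reference on 1000 random
instances (and against `metafor` where available); the stability test
on a 338-individual, 200-vOTU longitudinal community; and the
association scan's host-adjustment behavior over 100 simulated scans
of 800 samples. These sizes were chosen to give stable pass/fail
behavior at comfortable runtimes on a single CPU.

Seeds are explicit arguments everywhere randomness occurs, and
generators restore the caller's RNG state. Coordinates are 1-based
inclusive throughout, matching BLAST-style tables. All thresholds
compare as documented (strict where the defining phrase is strict:
"> 5%" prevalence, "> 0.9" plasmid score, "below 75%" breadth,
"exceeds by 10%" coding score).

## Known limitations

- The internal aligner is ungapped; repeats interrupted by indels are
  reported as separate pairs or missed. Precomputed alignment tables
  can be supplied wherever alignments are consumed.
- The default coding score (ORF length) is a stand-in for a gene
  caller's coding statistic; both reach the same decision through the
  stop-codon fusion signal, but per-gene scores from an external
  caller can be injected for exact reproduction of a score-based
  pipeline.
- Genetic-code assignment considers one code per genome; genomes mixing
  codes across regions are outside scope.
- Host prediction reports lineages as supplied in the taxonomy tables;
  no remote taxonomy retrieval is attempted.
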