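---
title: "Methods: DpnII tag profiling, from reads to simplex clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DpnII tag profiling, from reads to simplex clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assay and its analysis object

DpnII digital gene expression (DGE) profiling represents each
polyadenylated transcript by a short tag anchored at the DpnII
recognition site (`GATC`) closest to the polyA tail: the protocol
captures the restriction site plus the downstream bases, and the
analysis object throughout this package is the **20-base tag** —
`GATC` + 16 transcript bases. (The physical read may carry one extra
base; the simulator emits 20-mers directly, since every mapping,
filtering and counting step operates on 20-mers.) Expression is
measured by counting tags; each library is normalized to one million
**TPM** (tags per million), which makes profiles *compositional*: only
relative abundances are meaningful, and the per-library total is fixed
by construction.

Three facts drive the whole analysis design:

1. `GATC` is its own reverse complement, so every genomic occurrence
   carries a potential tag on *each* strand. A within-gene tag on the
   opposite strand from the gene model is evidence of antisense
   transcription.
2. Incomplete digestion and alternative 3' ends spread abundance over
   several DpnII sites of a transcript. Sites are therefore ranked
   from the 3' end (rank 1 = 3'-most, the intended site), and the
   rank-1/rank-2 usage split is a fidelity measure of the protocol.
3. Short tags map ambiguously: only uniquely mapping tags can be
   assigned to loci, and everything locus-level is computed on that
   subset.

# Pipeline stages

**Ingestion.** Reads are collapsed to unique sequences with counts;
tags that are not exactly 20 nt, contain `N`, or contain the library
adapter `GTCGGACTGTAGAACT` as a substring are removed (the adapter
16-mer is shorter than the tag, so containment — not equality — is the
correct test). TPM is `raw * 1e6 / total`, stored at 4 decimal places
by default; the storage precision is explicit and configurable because
the per-library sum is only guaranteed to be 10^6 within the rounding
tolerance (0.5e-4 per tag).

**Virtual-tag index.** `enumerate_virtual_tags()` finds every GATC in
every contig and emits the plus-strand 20-mer when
`gatc_start + 20 <= contig length` and the minus-strand 20-mer
(reverse complement of `[gatc_start - 16, gatc_start + 4)`) when
`gatc_start >= 16`. Windows containing `N` are skipped rather than
padded: only fully defined 20-mers can match an observed tag.
Coordinates are 0-based half-open internally and converted to 1-based
only at file boundaries (GFF3, TSV). The index lives in memory; the
intended scale (a mammalian genome's worth of virtual tags) fits
comfortably.

**Rescue.** A filtered tag absent from the genome is rescued when
exactly one substitution at 1-based tag positions 5–20 (the `GATC`
anchor occupies 1–4) yields an indexed tag — implemented by
enumerating all 16 × 3 = 48 substitution neighbors, and cross-checked
in the tests against an exhaustive Hamming scan. EST matching is
exact-substring on either strand, with no mismatch allowance.

**Annotation.** A locus boundary is the union span of its transcripts,
introns included, so a "within locus" tag may be intronic. Orientation
is strand equality with the locus. "On the 3' terminus" means the tag
equals a rank-1 or rank-2 site of *any* transcript of the locus (the
two 3'-most sites, pooled over transcripts — a locus-level OR; no
canonical-transcript convention is imposed). Upstream distances for
distance distributions are computed **genomically** from the gene
model's 3' end for both orientations: a single definition that is
also valid for antisense and intronic tags, for which transcript-space
distance is undefined. Tags inside two antiparallel overlapping loci
are sense to one and antisense to the other; they are flagged
(`confound`) and reported once per (tag, locus) pair rather than
silently resolved.

**Filter cascade.** The significance filter keeps a tag iff
`max TPM >= 2` in some library *or* it is present (TPM > 0) in at
least 10 libraries (an OR, with both clause counts reported). The
named sets satisfy, by construction, `Os-F = Os-fG ⊎ Os-fNG`,
`Os-fgu-PC ⊆ Os-fgU ⊆ Os-fG ⊆ Os-G`, with the single-mismatch and EST
overlays non-exclusive subsets of `Os-fNG`. Note that the 2 TPM clause
is depth-dependent: at simulated depths of 10^4–10^5 reads a singleton
tag is 10–100 TPM and passes, whereas at realistic depths (millions of
reads) singletons fall below 2 TPM and are removed; the tests
therefore exercise the filter's clause logic directly on hand-built
fixtures.

**Robust statistics.** The M-estimator of location (MEL) is a one-step
Huber estimate: one Newton step from the median, scaled by the
normal-consistent MAD, with bending constant 1.28 (the conventional
default giving ≈95% Gaussian efficiency); for a symmetric sample it
equals the mean, and for a degenerate sample (MAD 0) it returns the
median. The MAD scale estimate uses consistency factor 1.4826
(configurable to 1), which matters because standardized
transcript-length axes are in MAD units. Abundance-weighted inferred
transcript length per library is the plain TPM-weighted mean of the
lengths of the NM transcripts whose DpnII sites the tags hit
(robustness enters through the MEL/MAD standardization against the
reference distribution of all NM lengths, not through the weighted
mean itself); each tag inherits the transcript in which its site has
the smallest rank, ties broken by the longest transcript — a rule the
assay itself does not dictate, fixed here for determinism.

**Housekeeping detection.** A locus qualifies as constitutively
expressed only with positive sense TPM in *every* library; candidates
are ranked by ascending coefficient of variation (sample sd / mean,
ties broken by locus id). CV ranking is scale-free, which suits
TPM-normalized data.

**Clustering.** Because profiles are compositions, distances are
computed in Aitchison geometry: `d(x, y) = ||clr(x) − clr(y)||` with
`clr(p) = log p − mean(log p)`. This metric is scale- and
perturbation-invariant — exactly the invariances a
closed-to-a-million profile requires. Zeros are pervasive in tag
data and log-ratios need strict positivity, so closure adds a
pseudocount (default 1 raw count per part, Laplace-style,
configurable). Agglomeration is complete linkage on the pairwise
distance matrix; with continuous data, equal-distance ties have
probability zero, and the implementation is deterministic given the
input order. Tag-level clustering operates on the filtered,
uniquely-mapping (`Os-fgU`) tag universe; mitochondrial clustering
uses one part per organelle locus with sense + antisense TPM pooled.

**Multi-mapper attribution.** Uniquely mapping tags are the analysis
currency, but a locus whose 3'-terminal tag also occurs at a second,
intergenic location (pseudogene- or assembly-duplication-style) then
has its dominant tag excluded, which visibly skews that locus's
sense/antisense balance and the mitochondrial/nuclear split.
`assign_multi_single_locus()` restores the abundance of multi-mapping
tags that have exactly one within-locus site (all other sites
intergenic) as an *optional* augmentation of these partitions; it is
used by the recovery measurements and acceptance script, while the
default annotation remains strictly unique-mapping.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions against which everything else is validated.

*Genome* (`sim_genome_spec()`): 4 contigs × 50 kb, 60 nuclear loci
with 1–4 exons (exon 150–400 nt, terminal exon 300–400 nt, introns
100–300 nt) and 1–3 transcripts sharing the 3' end but varying 5'
extent; transcript classes NM/XM/NR at 0.7/0.2/0.1. Naturally
occurring GATCs are scrubbed from locus neighborhoods and 2–3 DpnII
sites are planted in each 3'-terminal exon, so every site, tag and
rank is known exactly. 10% of loci are placed antiparallel inside a
host locus (kept clear of the host's terminal exon so host site ranks
stay intact); 5% of 3'-terminal tags are copied to an intergenic
location (multi-mapper generator, realized as whole-locus effects);
3% of loci are generated siteless, mirroring the typical share of
gene models without a predicted DpnII sequence. A dedicated `MT`
contig carries 11 single-exon organelle genes, 2 of them siteless
(the COX3/ND3 situation of transcripts with no DpnII site).

*Libraries* (`sim_library_spec()`): reads are drawn per locus from an
expression profile (log-normal by default), with site rank 1 at
p = 0.915 and rank 2 at p = 0.085 — the observed primary/secondary
3'-site usage split — and any remaining mass decaying geometrically
over upstream ranks (the upstream usage law is not an observed
quantity; it is exposed as a parameter rather than asserted).
Antisense reads arise at 0.103 for nuclear loci and 0.044 for
mitochondrial loci (typical within-locus antisense abundance shares),
and use a more 3'-biased rank law (p₁ = 0.98), reproducing the
tendency of antisense tags to sit near the terminus. Reads from
mitochondrial loci occur at 0.114 (typical organelle share of
within-locus abundance). Noise: independent per-base substitutions at
0.002 (no indels — the protocol is fixed-length), adapter-artifact
reads at 0.013 (the adapter's observed share of raw tags), reads with
an indeterminate base at 0.005. Every read carries exactly one ground
truth record.

*Atlas* (`generate_atlas()`): libraries are assigned cyclically to
planted groups; each group up-shifts a random quarter of the loci
(and a third of the mitochondrial loci) by `separation` = 2 on the
log scale, with within-group multiplicative log-normal noise
(sd 0.15). Base-quality models, polymorphism between individuals,
fragment-length and GC bias are deliberately *not* modeled — so
passing recovery tests demonstrates correctness of the analysis
chain under the stated read model, not robustness to those real-data
phenomena. Real draft-genome pathologies (assembly gaps, collapsed
repeats, mis-assembled models beyond the planted 3'-displacement
fixture) are likewise out of scope.

# Numerical and design choices

* Determinism: every stochastic entry point takes a seed and restores
  the caller's RNG state; identical seeds give byte-identical outputs.
* TPM precision 4 decimals; normalization tolerance is
  0.5e-4 × (number of tags).
* Distance-space choice for Figures-style ECDFs/histograms: genomic
  distance to the model 3' end (see Annotation above); ECDFs count
  unique tag sequences unweighted, histograms are TPM-weighted — both
  are provided because they answer different questions (sequence
  diversity vs abundance mass).
* Mismatch rescue positions are 1-based 5–20 on the 20-mer; rescue
  refuses tags that already map (pipeline-misuse guard). EST matching
  is exact-only.
* "Present" in the significance filter means TPM > 0 (equivalently,
  raw count ≥ 1).
* The Aitchison/clr distance and pseudocount closure are this
  package's choices for simplex clustering; enumeration-data
  clustering tools differ in their zero handling, and the pseudocount
  is exposed for that reason.
* Degenerate inputs: empty read sets, empty atlases, all-zero
  profiles, missing mitochondrial loci and single-profile clustering
  all either no-op cleanly or raise a named error, as exercised by
  the tests.

# Problem sizes

The test suite validates oracle equivalences (brute-force 20-mer
scan, exhaustive Hamming rescue, naive complete linkage, direct
MEL/MAD implementations) on small random instances, and runs the full
pipeline end-to-end on a 12-library × 10^5-read atlas over the
default 4 × 50 kb genome — large enough that binomial 3σ bands on the
planted rates (0.915/0.085 site usage, 0.103/0.044 antisense, 0.114
mitochondrial) are a few parts per thousand, and small enough to run
in seconds. `scripts/acceptance.R` re-runs exactly that configuration
from a command-line seed. Cluster recovery is asserted at adjusted
Rand index 1.0 under the default separation of 2.

# Known limitations

* Junction-spanning tags (20-mers crossing an exon boundary) are
  reported as genome-unmappable rather than mapped across the splice;
  quality-aware mapping and indel alignment are out of scope.
* Locus assignment of multi-mapping tags beyond the single-within-locus
  rule is left to the investigator; the package reports, it does not
  adjudicate.
* The significance filter's 2 TPM clause is depth-dependent (see
  above); cross-depth comparisons should scale it.
* Gene-model errors are detected only as distributional signatures
  (e.g. displaced-model distance spikes); no automatic model
  correction is attempted.
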