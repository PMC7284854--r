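---
title: "Methods: models, parameters and design choices in crisprmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in crisprmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprmine)
```

This vignette is the package's own account of its methods: what each stage
computes, which parameters matter and why their defaults were chosen, what
the synthetic-data generator does and does not emulate, and where the
design was genuinely open.

## Coordinates and containers

All internal coordinates are 0-based half-open (`[start, end)`), converted
to 1-based inclusive only when writing GFF3; the round trip through
`write_locus_gff()`/`read_locus_gff()` is the identity on intervals.
Ambiguity characters outside A/C/G/T are normalised to `N` on input, and
`N` never matches in any scan or alignment — a deliberately conservative
rule that aborts repeat extension rather than guessing. Results are plain
tibbles or small S3 objects with `tidy()`/`glance()`/`autoplot()` methods,
so outputs compose with dplyr pipelines; `GRanges` appears only at the
GFF3 boundary.

## Array detection

`find_arrays()` re-implements de novo repeat-spacer discovery:

1. index exact k-mers (`kmer_seed_len = 12`);
2. keep k-mers recurring with a period between
   `min_repeat_len + min_spacer_len` (41) and
   `max_repeat_len + max_spacer_len` (105) and chain them into candidate
   unit sets of at least `min_repeats = 3` copies;
3. extend each chain column-by-column outward, growing a consensus. A
   column is accepted when at most one unit mismatches the column
   majority, that unit is terminal, and its cumulative mismatch count
   stays within `max_repeat_mismatches = 3`. Interior copies of real
   repeats are essentially identical, so demanding interior unanimity is
   what keeps boundary calls exact even for short arrays;
4. a terminal unit that exhausts its budget mid-extension (typically a
   degenerate terminal repeat whose mutation shifted its seed k-mer) is
   dropped and re-found afterwards by scanning the expected period window
   for the best Hamming match to the consensus; both terminal units are
   finally re-placed at their best-matching offset, which corrects
   single-base shifts that survive the mismatch budget;
5. overlapping candidates resolve by repeat count, then leftmost start.

Length brackets (repeats 23–50 nt, spacers 18–55 nt) cover observed repeat
biology (29–36 nt across the subtypes modelled here) with margin.
`min_repeats = 3` reflects that two-copy "arrays" cannot be distinguished
from generic dispersed repeats; the smallest arrays reported in genus-wide
surveys have four spacers, comfortably above this floor. The detector is
strand-symmetric and invariant to contig order (output sorts by contig id,
then start).

With three to five repeat copies, a random boundary column can satisfy the
acceptance rule with probability of order `4^-(m-2)` per side, so
single-column overextension is possible in principle on the very smallest
arrays; terminal re-placement removes the observed cases, and the residual
risk vanishes by `m ≈ 8`.

**Orientation.** Real arrays acquire spacers at the leader end while the
trailer-end repeat decays. `orient_array()` flips an array so that a
uniquely degenerate terminal repeat (two or more mismatches from the
consensus) sits rightmost — the trailer/ancestral end — and marks the call
confident; arrays without that signal are left unchanged and downstream
genotyping tries both orientations.

## Annotation and classification

`find_orfs()` scans all six frames of the flanking windows
(`flank_window = 20000` bp each side) with the bacterial genetic code,
keeping the longest ORF per stop codon (start codons ATG/GTG/TTG) of at
least `min_orf_aa = 100` aa — long enough to exclude spurious micro-ORFs
while retaining the smallest cas genes (Cas2 is around 100 aa; the panel's
representative is 110 aa). `score_cas()` aligns each ORF locally
(BLOSUM62, gap open 11 / extend 1) against the bundled panel and converts
scores to E-values with Karlin–Altschul statistics (gapped BLOSUM62
parameters λ = 0.267, K = 0.041) scaled to the full panel size; the hit
threshold of 1e-3 mirrors the protospacer threshold, an explicit
assumption since no separate cas-search threshold is standard. Panel
entries whose length differs from the ORF by more than two-fold are
skipped as they cannot yield a qualifying full-gene hit.

Classification is purely presence-based (gene order and strand are
ignored, so rearranged operons — a rearranged I-G locus, for example —
classify identically): orphan when no cas hit; *cas9* ⇒ Type II, then
*csn2* ⇒ II-A, else *cas1* + *cas2* ⇒ II-C, else II\*; *cas3* ⇒ Type I,
then *cas8c* ⇒ I-C, *cse1/cas8e* with *cse2* or *cas6e* ⇒ I-E, *cas8u2* or
the Cas1–Cas4 fusion ⇒ I-G, else I\*. When one contig carries several
arrays, each ORF is credited to the nearest array by interval midpoints,
so co-resident Type I and Type II systems classify independently.

**The bundled panel is synthetic.** Real Cas reference sets live in
external databases; the shipped
`inst/extdata/cas_panel_synthetic.fasta` holds one generated
representative per gene per subtype at realistic lengths (the II-A Cas9 is
1383 aa — a 4152 bp gene — and the II-C Cas9 1142 aa / 3429 bp). Synthetic
panel entries are mutually unrelated, which makes classification *easier*
than with homologous real families; what the tests demonstrate is the
machinery (ORF calling, alignment statistics, rules), not discrimination
between closely related gene families. Users with a curated panel can pass
it to `cas_panel(path)` using the same `id|gene|type|subtype` headers.

## Protospacer search and PAM model

`search_protospacers()` performs seeded local nucleotide alignment
(match +2 / mismatch −3, gap open 5 / extend 2) of each spacer against
both strands of every invader record, with E-values from Karlin–Altschul
statistics (λ solved from the scoring system under uniform base
composition, K = 0.41, search size = total database length). Both
inclusion thresholds are strict inequalities: E < 1e-3 and identity >
85.0%, so hits at exactly either boundary are excluded. Identity is
matches over alignment columns including gaps — recorded here because
identity definitions vary between tools.

`extract_flanks()` returns 10 bp on each side *in protospacer
orientation* (minus-strand hits are reverse complemented first, so
"upstream" always means 5′); flanks truncated at record edges are flagged
and the frequency matrix right-aligns upstream flanks at the protospacer
boundary so truncation cannot shift columns.

`infer_pam()` chooses the flank side by system type (Type I 5′, Type II
3′) and builds a 4 × 10 frequency matrix with a 0.5 pseudocount per base.
Information content per column is `2 − H` bits computed on the observed
proportions (with `0·log 0 = 0`), so a perfectly conserved column scores
the full 2 bits; the pseudocount smooths only the reported frequencies.
A consensus is called when at least `min_hits = 5` flanks are available
and a position reaches `call_threshold = 1` bit; these two knobs
operationalise the qualitative "not clear" judgment and are exposed as
arguments. Because a PAM is by definition protospacer-adjacent, the
consensus reports the contiguous run of called positions nearest the
protospacer; a degenerate position inside the motif (the N of a TAN-type
PAM) simply fails the threshold and is not called. Both per-subtype and
per-species grouping are possible by subsetting the flank table before
calling `infer_pam()` — pooling by subtype is the default because hit
counts are usually the limiting factor.

## RNA structure

Secondary structure uses deterministic base-pair maximization (the
Nussinov recursion) instead of thermodynamic minimum-free-energy folding:
it needs no energy model, is exactly reproducible, and stem/loop/handle
*geometry* — all the pipeline reports — agrees with the designed
structures. The trade-off is explicit: no free energies, no pseudoknots,
and co-axial effects are ignored. Rules: Watson-Crick plus G·U wobble
(T read as U), minimum loop of 3 unpaired bases, ties among maximal-pair
structures broken toward the most-3′ paired region and then maximal stem
contiguity via an index-sum criterion in the traceback. The implementation
is verified against two independent oracles — a memo-free exhaustive
enumeration and an independently formulated DP — over *every* sequence up
to length 10 (1,398,100 sequences) and seeded length-24 samples.

The shipped Type I repeat templates are designed so the optimal structure
is provably unique (stems are C/G blocks, everything else A, so only C:G
pairs exist and the maximal nested matching is forced):

```{r geometry}
for (st in c("I-C", "I-E", "I-G")) {
  h <- fold_crrna(subtype_template(st)$repeat_seq)
  cat(sprintf("%-4s stem %d bp, loop %d nt, 3' handle %d nt\n",
              st, h$stem_len, h$loop_len, h$handle3_len))
}
```

This reproduces the subtype geometry the pipeline characterises: an 8 bp
stem with an 11 nt 3′ handle for I-C, 6 bp / 7 nt for I-E, 8 bp / 12 nt
for I-G. `mature_crrna_cut()` reports Cas5/Cas6 processing 8 nt from the
3′ end for I-C and I-G and 7 nt for I-E.

**tracrRNA.** `find_tracrrna()` scans the locus neighbourhood (outside the
array and cas CDS) for anti-repeat windows — reverse complements of the
repeat consensus within `max_mismatches = 3` over the full repeat length —
on both strands, extends each candidate 3′ to the end of the first poly-T
(≥ 4 T) terminator capped at +120 nt, and ranks by mismatches and the
subtype placement prior (upstream of *cas9* for II-C, between *cas9* and
*cas1* for II-A). The terminator heuristic stands in for an end-calling
method that has no published standard; the 120 nt cap brackets reported
tracrRNA lengths (around 108–137 nt). Anti-repeat complementarity is
orientation-symmetric, so the transcript orientation is taken relative to
the reported array consensus; on a reverse-complemented genome the same
anti-repeat window is found with the roles of the strands exchanged.

**Duplex.** `predict_duplex()` aligns the repeat antiparallel to the tracr
5′ end allowing one internal bulge of up to 3 nt on either strand, labels
lower stem (5′ of the bulge), bulge and upper stem, then folds the
remaining tracr tail — excluding the transcription terminator, which is
not a structural element — and reports nested components 5′→3′ as the
nexus followed by terminal hairpins. The shipped II-C template yields a
nexus plus two terminal hairpins at 109 nt total; II-A a nexus plus three
at 132 nt.

## Genotyping

Spacers are compared in id space after `build_dictionary()` unifies
identical sequences and reverse complements under one id; matching is
exact because spacers are either acquired identically or are different
(tolerating point mutations within spacers is deliberately out of scope).
`align_arrays()` anchors arrays at the trailer end, clusters strains by
single linkage on shared trailer suffixes of at least `min_shared = 3`
spacers (guarding against chance sharing), and right-justifies columns.
Arrays without a confident orientation — including plain spacer vectors —
are tried in both orientations and keep the one maximising total shared
suffix.

`detect_events()` calls, per strain within a subgroup: an *acquisition*
for the retained leader-end block beyond the subgroup-shared trailer; a
*deletion* when the strain's whole array is a strict trailer-suffix of
another strain's (they share acquired spacers, so the missing leader block
was lost — mirroring an isolate that lost its eight most recently acquired
spacers); and a *divergence* at the boundary of the shared block. Replay
(`replay_events()`) prepends each strain's retained acquisitions to the
shared block and must reproduce the observed arrays exactly — a round-trip
identity the tests enforce on every simulated lineage.

The simulator models deletion only for strains created as identical twins
of their predecessor, because a leader-block loss is only *identifiable*
when another strain retains the shared acquisitions; deletions applied to
a strain with unique acquisitions are indistinguishable from never having
acquired them. Deletion events are applied in strain order so a chain of
twins always roots at a strain with its full block.

## Phylogeny

`pairwise_distance()` computes p (mismatch fraction over aligned non-gap
columns of a global BLOSUM62 alignment) and corrects it to
`d = −ln(1 − p)`, the Poisson many-hits correction, capping p at 0.95
(beyond which the correction diverges; a warning reports the cap).
Pairwise alignments replace a progressive multiple alignment — a
deliberate simplification that avoids an external aligner and is standard
practice for distance-based trees at panel scale. `nj_tree()` implements
Saitou–Nei neighbor joining; negative branch lengths are clamped to zero
with the deficit moved to the sibling so Newick consumers see non-negative
lengths. On additive matrices the implementation recovers topology and
branch lengths exactly (property-tested against random trees, and
cross-checked against `ape::nj`). `bootstrap_support()` resamples each
pair's aligned columns per replicate — a pairwise analogue of the
classical column bootstrap, chosen to match the pairwise-distance design —
and reports the percentage of replicate trees containing each internal
split.

## What the simulator emulates, and what it does not

`simulate_genome()` plants one locus per genome: an array of distinct
30–40 nt spacers between identical repeats (the last repeat degenerate
with two mutations), a subtype-canonical operon back-translated from the
panel with uniform synonymous codons and a stop-codon guard before each
start (so ORF boundaries are exact), and for Type II a tracrRNA at the
canonical placement. Background sequence is i.i.d. uniform A/C/G/T, which
makes spurious long repeats vanishingly unlikely — the simplest null for
detector specificity. Each generator stage draws from an independent
substream of the user seed, so a genome and its invader database never
replay each other's random draws.

Real genomes differ in ways the simulator does not model: biased GC
content and codon usage, repeat families shared across loci, insertion
elements, repeat-internal mutations beyond the terminal copy, arrays split
across contig breaks, and homologous (rather than unrelated) cas gene
families. Passing tests therefore demonstrate correctness of the
algorithms under the stated model, not performance on RefSeq-scale data.

Default conditions follow the survey being modelled: array sizes in tests
span 4–200 spacers with Type I cohorts drawn around a mean of 60 spacers
and Type II around 25; repeat lengths are 33 (I-C), 29 (I-E) and 36
(I-G/II-A/II-C) nt; tracrRNAs are 109 nt (II-C) and 132 nt (II-A); the
motivating PAM scenario plants 5′-TTC-3′ in 12 invader records. Genomes
carry 2 × 20 kb of background so the full flanking window always exists
(about 41 kb plus locus per genome — scaled down from megabase genomes,
which affects only runtime, not the algorithms). The acceptance script
uses 50 detection simulations, 20 background genomes, 20 tracrRNA runs, 30
lineages and 50 additive matrices; these sizes keep the full run within a
few minutes while leaving sampling error far below the pass margins.

## Known limitations

- Arrays spanning contig breaks and repeat families across loci are out of
  scope; each contig is scanned independently.
- The folding model reports geometry, not energetics; structures with
  ties are resolved by a fixed deterministic rule.
- The Karlin–Altschul constants are the standard gapped BLOSUM62 values
  and a fixed K for the nucleotide system; E-values are meant for
  thresholding, not for cross-tool comparison.
- Genome-wide cas search (for arrays with no flanking hits) is exposed via
  `annotate_genome(genome_wide = TRUE)` but distant operons are credited
  to the nearest array, which is a heuristic.
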