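---
title: "Models and methods behind metaprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metaprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metaprof` profiles shotgun metagenomic samples taxonomically (via 16S/18S
rRNA fragments) and functionally (via predicted genes). This vignette
documents the models, the tunable parameters, the numerical conventions,
and the design decisions that were genuinely open — together with what the
simulation-based validation does and does not demonstrate about real data.

## 1. The rRNA profile HMM

### Model

The detector is a classic match/insert/delete profile HMM estimated from a
reference multiple alignment:

* Alignment columns with a gap fraction below `match_frac` (default 0.5)
  become match states; all other columns feed the insert state flanking
  the preceding match state.
* Match and insert emissions, and all transitions, receive Laplace (+1)
  pseudocounts. Transition distributions are position-specific, with all
  nine type pairs (M/I/D to M/I/D) permitted; the begin state behaves like
  match state 0 and the exit transition is counted toward M.
* Scores are log2-odds ("bits") against the background base composition
  of the whole alignment (also Laplace-smoothed so no log is infinite).
  `N` emits at background in every state, contributing exactly 0 bits.

### Scoring

A 100 bp read covers a small window of a full-length rRNA model, which
forces *local* alignment: the Viterbi scan (implemented in C++) allows
free entry into and exit out of any match state, so every reported
alignment starts and ends in a match state and flanking read residues are
unpenalized. Both strands are scanned in memory; the higher-scoring
strand wins, ties resolve to `+` for determinism, and fragments are
re-oriented to the model strand before reporting.

The exact same path grammar is implemented twice: once as the C++ dynamic
program, and once as an explicit exhaustive path enumeration in the test
suite. For every model with up to 4 match states and every read up to 6
bases the two agree to 1e-9 bits, which pins down the boundary conventions
(entry/exit, delete chains, insert loops) rather than just the headline
recurrence.

### Calling threshold

The paper-style workflow gives no explicit score threshold, so the default
is a package convention: `0.25 bits × L` where `L` is the number of match
states (75 bits for the 300-state fixture model). On the fixture bundle
this cleanly separates reads genuinely inside a planted rRNA region
(scores well above 90 bits even at ~6% total divergence) from background
windows (best local scores around 10–30 bits); recall on fully contained
windows exceeds 95% with a false-positive rate under 1%. The threshold
scales with model length, not read length, so it should be revisited for
models much longer or shorter than a few hundred states.

## 2. Mapping and taxonomic assignment

The mapper replaces a general-purpose aligner with an explicit
seed-then-align scheme so that its behaviour is fully specified and
testable: exact k-mers (default `k = 8`) nominate candidate references on
either query strand; each candidate is aligned by affine-gap
Smith–Waterman (match +1, mismatch −1; a gap of length g costs 2 + g,
i.e. `gapOpening = 2`, `gapExtension = 1` in the convention Biostrings
uses, which the tests exploit for cross-checking). Percent identity is
matches over *all* alignment columns, gaps included. One best hit is
kept; ties break by score, then identity, then lexicographic reference
id, then `+` strand. Because each per-query result is a pure function of
the query and the index, chunked multi-worker execution cannot change any
output — the determinism tests assert byte-identical results for 1 and 8
workers.

Lineages are assigned by identity truncation: the hit's reference lineage
is kept down to the deepest rank whose threshold the identity reaches
(species 97, genus 95, family 90, order 85, class 80, phylum 75; domain
always assigned), deeper ranks becoming `Unclassified`. Whether the
original tools truncated by identity, used a lowest common ancestor, or
accepted top-hit species outright is not documented; truncation-by-
identity is this package's explicit choice because it is monotone,
single-hit based, and directly testable. The thresholds are conventional
rRNA practice and are configurable per run.

Counts aggregate into per-rank profiles in which `Unclassified`-terminated
paths are ordinary rows, so two invariants hold by construction and are
asserted on every constructed profile: counts at every rank sum to the
total assigned reads, and relative abundances sum to 1.

**Integration.** Profiles of one sample against several databases are
integrated as the arithmetic mean of relative abundances over databases
(absent taxa contribute 0), renormalized. The mean is the simplest
symmetric choice; the source work says only that multi-database results
"can be integrated". Integration matters: on the fixture community the
habitat-matched database alone recovers the genus structure at E ≈ 3.6
while the deliberately diverged general database reaches E ≈ 23 (about a
fifth of its reads fall just below the 95% genus threshold and land in
`Unclassified`); their integration sits at E ≈ 12. That spread is the
package's miniature reproduction of why multi-database annotation with a
habitat-specific reference outperforms any single general database.

## 3. The error-rate statistic

For N taxa at one rank with actual abundances V and predicted abundances
V′ (matched by name over the union of supports, zero-filled):

E = 100 · sqrt( Σ (V_i − V′_i)² ).

The source rendering of this formula is typographically unreadable; the
implementation follows its verbal description as a Euclidean distance on
a percent scale, which also matches the magnitude of the published
error-rate tables. Because the normalization genuinely cannot be
recovered from the text, `error_rate()` exposes `none` (default),
`sqrt_n` (÷√N) and `half` (÷2) variants. E restricted to a common
support is a metric (symmetry, identity, triangle inequality are
property-tested on random triples).

## 4. Functional analysis

* **Gene prediction** is an explicit 6-frame ORF finder (starts ATG/GTG/
  TTG, leftmost start after the previous in-frame stop, stop codon
  included in the reported sequence, minimum length 300 nt by default,
  open ORFs at contig edges allowed). It deliberately stands in for
  HMM-trained gene callers whose error models are out of scope here;
  externally produced gene calls can enter the same downstream functions
  as FASTA. Its output is verified against an independent brute-force
  frame scan on random contigs, and strand symmetry
  (predict ∘ revcomp = flip ∘ predict) holds exactly.
* **Identification** transfers annotations from the single best protein
  hit (identity scoring on amino acids, protein k-mer seeds with
  `k = 4`); genes without a hit remain unannotated rather than receiving
  a default.
* **GOSlim rollup**: the reflexive ancestor closure of a gene's GO terms
  over `is_a` and `part_of` (the two relations generic slim practice
  follows) is intersected with the slim set; each slim term counts at
  most *once per gene*, so duplicated annotation lists cannot inflate a
  profile — whether the original counted per gene or per term occurrence
  is undocumented, and once-per-gene is the choice least sensitive to
  annotation redundancy. The profile keeps the `top_n = 20` most
  abundant slim terms per namespace (ties by term id).
* **SEED rollup**: every annotated gene contributes one count to its
  exact 4-level hierarchy path; marginals at levels 1–4 are all equal to
  the number of annotated genes (asserted against a direct group-by).

## 5. The simulator and fixture bundle

`simulate_reads()` emulates a whole-genome read simulator at exactly the
level the evaluation needs: multinomial genome choice from the abundance
vector, uniform start, uniform strand, then independent per-base
substitutions to a uniformly chosen different base. Defaults are 100 bp
reads at a 1% substitution rate; the 2–3 most abundant taxa are fixed
manually (fixture default 0.30/0.20/0.15) and the remainder drawn
symmetric-Dirichlet(1), i.e. uniformly on the simplex, as the natural
reading of "defined randomly". No indels, no quality decay, no
platform-specific artifacts: validation against this generator shows the
chain recovers what it was given under idealized substitution noise, not
that it is robust to homopolymer errors, chimeras or coverage bias in
real data.

The fixture bundle plants one 300 bp rRNA-like region (a ~5% mutated copy
of a shared consensus, mirroring 16S conservation) in each of eight 10 kb
genomes. All genomes and regions share one length so that rRNA-read
recovery is unbiased with respect to abundance — with unequal lengths the
recovered fractions would be reweighted by region/genome length ratios,
confounding the recovery test with a property of the fixture. The two
reference databases differ only in their distance to the truth: habitat
refs are exact copies of each genome's region, general refs are a further
~3% diverged. One seed drives the whole bundle; the same seed yields a
byte-identical directory.

## 6. Numerical and format conventions

* All coordinates are 0-based half-open; minus-strand features are
  reported on forward-strand coordinates.
* All table output is UTF-8, Unix newlines, fixed 6-decimal abundances,
  deterministic sort orders — so reruns are byte-identical and tests can
  compare files directly. The same applies to the SVG/HTML exports
  (fixed 4-decimal geometry, hash-derived colors, `Unclassified` gray).
* Wedge layouts conserve angle exactly: sibling sweeps sum to the parent
  sweep, ring 1 sums to 360°; one layout engine serves taxonomic, SEED
  and (flat) GOSlim profiles.
* FASTQ is fixed to Phred+33; lineage tables are
  `ref_id TAB semicolon-joined-7-rank-lineage` with `Unclassified`
  padding — the original database file dialects are undocumented, so
  these dialects are the package's own, chosen for a bit-exact test
  surface.
* Problem sizes used by the validation suite: the end-to-end recovery
  check runs 20,000 reads (2 × 10^6 bases) against both databases; the
  acceptance script measures the substitution rate on 200,000 bases;
  oracle grids use models of up to 4 match states with reads up to 6
  bases, where exhaustive enumeration is exact. These sizes give the
  statistical checks comfortable binomial margins (e.g. 3σ on 2 × 10^5
  bases is ±0.07 percentage points around 1%) while keeping a full run
  in a few CPU-minutes.

## 7. Known limitations

* The ORF caller over-calls relative to trained gene finders on real
  contigs (any sufficiently long start-to-stop stretch is reported);
  downstream identification filters most spurious calls, but gene
  *counts* should not be interpreted as gene-finder output.
* Identity-threshold truncation cannot express conflicting evidence from
  multiple near-best hits (no LCA), and no 16S copy-number correction is
  applied — abundances are raw read fractions.
* The Viterbi scan reports a single best fragment per read; reads
  spanning two rRNA features (impossible in the fixture, rare in
  practice at 100 bp) would yield only the better one.
* E-values are not computed anywhere; all calling decisions are score- or
  identity-threshold based and should be recalibrated if model length or
  scoring parameters change materially.
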