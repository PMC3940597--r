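# metaprof

Taxonomic and functional profiling of shotgun metagenomes in R.

Shotgun sequencing of a microbial community yields short reads from many
genomes at once. Two questions dominate downstream analysis: *who is
there* (the taxonomic structure, from domain down to species, usually read
off the 16S/18S rRNA gene) and *what can they do* (the functional
structure of the predicted gene set). `metaprof` implements a complete,
self-contained chain for both, aimed at microbiome researchers who want a
scriptable, fully reproducible pipeline with no external database or
aligner dependencies — plus a read simulator with ground-truth tracking so
every step can be validated quantitatively.

## The method

**Taxonomic arm.** rRNA fragments are detected with a profile hidden
Markov model (match/insert/delete states, Laplace-smoothed emissions and
transitions estimated from a reference alignment, log2-odds scores against
the alignment background). Every read is scanned on both strands by a
local Viterbi algorithm with free entry/exit at any match state — a 100 bp
read covers only a small window of a full-length rRNA model, so local
alignment is essential. Fragments above the calling threshold (default
0.25 bits per match state) are mapped to one or more taxonomy-annotated
reference databases with a k-mer seeded Smith–Waterman aligner
(match +1, mismatch −1, affine gaps −2/−1; single best hit with
deterministic tie-breaking). Each hit's reference lineage is truncated at
the deepest rank supported by its percent identity (species 97, genus 95,
family 90, order 85, class 80, phylum 75 by default) and counts are
aggregated into per-rank abundance profiles; profiles from several
databases can be integrated (mean relative abundance, renormalized) to
mitigate single-database bias.

**Comparison.** Predicted and actual community structures with abundances
V'_i and V_i over N taxa are compared with the error rate

    E = 100 · sqrt( Σ_i (V_i − V'_i)² )

the Euclidean distance between the two structures on a percent scale
(larger E = higher error). Multi-sample tables, neighbor-joining trees of
the extracted fragments (p-distance on pairwise global alignments) and
Krona-style multi-ring SVG/HTML views round out the comparison toolkit.

**Functional arm.** Assembled contigs (from any assembler) are scanned for
open reading frames on all six frames; predicted proteins are identified
by best-hit transfer from an annotated protein set, and annotations are
rolled up two ways: GO terms are tracked through the GO DAG (`is_a` +
`part_of`, reflexive closure, counted once per gene) to a GOSlim subset,
and SEED-style function ids are expanded to their exact 4-level hierarchy
paths with mass-conserving marginals at every level.

**Simulator.** `simulate_reads()` draws reads multinomially across genomes
from an abundance vector (the 2–3 most abundant taxa fixed manually, the
rest Dirichlet-random), uniform start and strand, and independent per-base
substitutions (defaults: 100 bp reads, 1% error rate), recording a truth
table (source genome, interval, strand, error count) for every read.

## Worked example

```r
library(metaprof)

# a fully ground-truthed miniature dataset
bundle <- make_fixture_bundle(file.path(tempdir(), "demo"), seed = 42)
genomes <- read_fasta(bundle$genomes)

# simulate a shotgun sample: 100 bp reads, 1% substitution errors
ab <- draw_abundances(n_taxa = 8, n_manual = 3,
                      manual_values = c(0.30, 0.20, 0.15), seed = 7)
spec <- community_spec(genomes, ab, n_reads = 5000, seed = 11)
sim <- simulate_reads(spec)

# train the rRNA profile HMM and extract fragments (both strands)
hmm <- build_profile_hmm(read_fasta(bundle$rrna_alignment, allow_gaps = TRUE))
hmm
#> profile_hmm: L = 300 match states; consensus AAAACTCCATGTGTAACTCC...
frags <- extract_fragments(sim$reads, hmm)
nrow(frags)
#> [1] 162

# map fragments to the habitat-matched database and build the profile
idx <- build_kmer_index(read_fasta(bundle$db_habitat), k = 8)
hits <- map_all(seq_records(frags$read_id, frags$fragment), idx)
lineages <- read_lineage_table(bundle$db_habitat_lineage)
profile <- build_taxonomic_profile(assign_lineages(hits, lineages), "habitat")
profile
#> taxonomic_profile [habitat]: 162 assigned reads; 13 species-level paths
head(profile$ranks$genus, 3)
#>                                                 path count       rel
#> 1 Bacteria;Phylum_A;Class_1;Order_1;Family_1;Genus_1    44 0.2716049
#> 2 Bacteria;Phylum_A;Class_2;Order_3;Family_3;Genus_3    36 0.2222222
#> 3 Bacteria;Phylum_A;Class_2;Order_4;Family_4;Genus_4    27 0.1666667

# compare against the simulator's ground truth
truth <- truth_abundances(sim$truth)
names(truth) <- sprintf("Genus_%d",
                        as.integer(sub("genome0?", "", names(truth))))
error_rate(truth, abundance_vector(profile, "genus"))
#> [1] 9.211876
```

Of 5,000 simulated reads, 162 carry a detectable rRNA fragment (the
planted regions cover ~3% of each genome, and only reads overlapping them
substantially are callable). All 162 map back to the habitat database,
and the genus-level community structure recovered from that ~30× smaller
subsample is 9.2 error-rate points from the ground truth — dominated by
subsampling noise, not misassignment. The three manually fixed genera
(0.30/0.20/0.15) head the profile in the right order.

`run_pipeline()` (or the thin CLI at `inst/cli/metaprof.R`) chains all of
the above — extraction, per-database profiling, integration, comparison,
functional rollups, visualization — into one output directory with a
manifest recording every parameter and default.

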