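---
title: "Assembling plant organelle genomes from syncmer graphs: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling plant organelle genomes from syncmer graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the model each stage
implements, the parameters that matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
design choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The sparsification model

Reads are homopolymer compressed before anything else. The dominant error
mode of CCS/HiFi data is a ±1 change in the length of a homopolymer run;
collapsing every run to a single base (and remembering the run lengths)
makes such errors invisible, at the cost of deferring base-level accuracy to
a run-length consensus taken per k-mer position (closest integer to the mean;
ties round half up, a deterministic choice consistent with "closest integer"
everywhere else).

A k-mer of the compressed sequence is a *closed syncmer* iff the hash of its
first or last s-mer is less than or equal to the hash of every other s-mer
it contains (ties qualify). Two properties make this the right selection
rule for assembly:

* consecutive closed syncmers are guaranteed to overlap
  (p<sub>i+1</sub> − p<sub>i</sub> < k), so a read is fully represented,
  between its first and last syncmer, by its syncmer vector;
* the expected spacing on random sequence is (k − s + 1)/2, so with
  k = 1001, s = 31 the data is sparsified by a factor of about 485 (the
  acceptance script measures 483–486 on 5 Mb of uniform random DNA).

**Parameters.** `k` (hoco bases, odd — an odd-length hoco k-mer can never be
its own reverse complement, which keeps the vertex pairing total): 1001 by
default, 301 in the heavier tests ("test profile"), smaller still in unit
tests. `s ≤ 31` so an s-mer packs into 62 bits; the s-mer hash is the 2-bit
encoding of min(x, revcomp(x)) passed through a fixed invertible 64-bit
mixer, hence *perfect* (collision-free) and strand-canonical. The k-mer hash
used for table lookup is a seeded FNV/mix construction; its collisions are
expected and resolved by sequence comparison, with first-seen order deciding
entry indices. Reads are split at `N` into independent fragments; fragments
shorter than k contribute nothing.

## 2. The graph and its invariants

Every table entry induces a vertex pair (+i, −i); every read adjacency adds
one unit of coverage to a directed edge and its complement, so the graph is
Watson–Crick complete by construction (`verify_wc_complete` checks the edge
symmetry including coverage and overlap equality). Edge overlaps are
k − (p<sub>i+1</sub> − p<sub>i</sub>); when repeat structure makes several
distances appear for one vertex pair, the largest distance (smallest
overlap) is kept.

## 3. Error correction

Syncmers with frequency below ϑ (default 3) are potential errors; maximal
runs of them on a read form error blocks. The block plus its flanking
trusted syncmers delineates a target subsequence ξ which is re-threaded
through the error-trimmed graph by DFS, scoring path prefixes with a banded
prefix edit distance (band half-width ⌈εl⌉+1). A descent stops when the
prefix distance reaches εl, the path sequence reaches (1+ε)l, or there is no
successor; τ completed descents abort the block. The best distance ê must
satisfy ê ≤ εl and ê < ω·ẽ against the second-best *distinct* path.

Two derived details matter and are easy to get wrong:

* **The alignment target runs through the right boundary k-mer.** The
  required path must end at the right-boundary vertex, but a target ending
  at the last *error* k-mer is typically overshot by half a k-mer when the
  boundary is appended — more when corruption silently removed syncmer
  positions — and the (1+ε)l stopping rule would then terminate descents
  before the boundary. Extending the target through the boundary k-mer
  aligns the two endpoints; in simulation this is the difference between
  ~84% and ~98% of blocks corrected.
* **Overshoot is charged.** Path prefixes are scored with d+g semantics
  (min over j of D[q][j] + (l − j)); freezing the score once the target is
  consumed would let every extension of a perfect path tie with it and
  manufacture spurious ambiguity.

Defaults ϑ=3, ε=0.01, τ=10 000, ω=0.7. ε should reflect the per-base
accuracy of the data; unit tests that run at k=31 raise ε to 0.05 because
εl < 1 at that scale forbids any correction at all.

After correction the table frequencies are recounted from the corrected
vectors and the graph rebuilt. Run-length accumulators are *not* recounted:
the consensus denominator is the number of occurrences actually accumulated,
which is what makes consensus lengths stable under correction.

## 4. Cleaning, unitigs, disentangling

The coverage filter c is a user parameter (five times the estimated haploid
nuclear depth is the working default) and is what separates organelle from
nuclear sequence, including all but the youngest NUMTs/NUPTs, because k is
large. Tips shorter than 10 kb (uncompressed consensus bp) and two-arm
bubbles shorter than 100 kb are then removed iteratively to a fixed point
(hard cap 16 rounds). Two guards refine the classic bubble rule:

* an arm is never popped against its own complement — a single-copy region
  flanked by an inverted repeat pairs with itself under endpoint matching
  and is one sequence, not a bubble;
* arms must be within 10% in length — variant bubbles (errors, diverged
  repeat copies) have near-equal arms, whereas two unrelated genomes joined
  by a shared segment do not, and those must survive for read-phased
  disentangling.

Disentangling counts, for every node, the reads supporting each spanning
triplet. A triplet dominated (below λ = 0.1 of both its row and column
maximum) marks the node resolvable; the node is replaced by one copy per
non-dominated triplet, each wired to exactly its in/out context, with the
original coverage split across copies in proportion to their read support.
This is topologically equivalent to building concatenated compound nodes and
re-unitigging, but conserves sequence length and handles the figure-eight
case (both flanks the same node) cleanly. Rounds repeat, with reads remapped
each round, until convergence (cap 16).

Read mapping is seed-and-extend at the k-mer level: the first k-mer of the
read present in the graph seeds the walk; extension must find the next read
k-mer exactly where the graph expects it. After disentangling a k-mer can
occur in several copies, so the mapper tracks parallel placements (cap 16)
and returns a path only when they agree.

## 5. Classification

Hits are significant at e ≤ 1e−6 and score ≥ 300. Components are processed
in descending order of their stronger organelle score (the sort key was a
genuinely open choice; the maximum of the two sums matches the tentative
argmax labelling most directly), each tentatively labelled by that argmax, flipped
plastid→mitochondrion when a plastid component already exists and the
mitochondrial score reaches one third of the plastid score, and finally
gated: at least 3 (plastid) or 1 (mitochondrion) of its genes must beat the
running per-gene best scores, which accepted components then update for both
organelle namespaces. The flip is one-directional by design. The result is
invariant to permutation of the input hit rows (tested).

## 6. Path resolution

Copy numbers are the fixed point of d̄ = Σlᵢdᵢ/Σlᵢcᵢ, c = max(1, ⌊d/d̄⌉),
initialised from the minimum depth (single-copy unitigs dominate organelle
components, so the minimum is an adequate single-copy anchor). Enumeration
expands multi-copy nodes, consumes copies in index order (which kills
copy-permutation duplicates), starts from both orientations of every node,
records maximal walks at DFS leaves, and deduplicates by a canonical key:
copy labels erased, then the lexicographic minimum over both strand readings
and (for walks closable by an existing edge) all rotations. Only the longest
circular and longest linear walks are kept. For the canonical quadripartite
graph this yields exactly two circular conformations.

Selection: longest wins; a circular candidate is preferred when at least 90%
of the longest linear one; equal lengths are broken by the number of reads
spanning the path's junctions (both directions summed). Note that the two
quadripartite conformations traverse the *same four* bidirected junctions,
so junction support genuinely cannot separate them — that is why plastome
orientation uses gene order and flip-flop analysis uses IR-spanning
triplets instead.

If the primary is non-circular, integer edge visits t are optimised within
[min(cᵢ,cⱼ)−3, max(cᵢ,cⱼ)+3] (clamped at 0) minimising
Σ(|c−t⁻|/2 + |c−t⁺|/2 + |t⁻−t⁺|)·log l — brute force when the solution
space is ≤ 1e8 (an incremental odometer in C++), otherwise simulated
annealing (geometric cooling 0.95 from T₀=10, 200 proposals per temperature,
±1 moves, fixed seed 42, seed exposed). The optimised t then constrain a
second enumeration round as edge multiplicities, with node copies implied by
the side sums; treating the visits as hard edge constraints (rather than as
revised node copy numbers) was a genuinely open design point, resolved this
way because it preserves exactly the information the optimiser added.

Plastome orientation computes Spearman's rank correlation between the
packaged 71-gene reference order and the observed circular gene order of
each conformation — evaluated in both strand readings, since a circular
path's reading direction is arbitrary — after rotating the observed order to
start at the shared gene with the smallest reference rank (making the
statistic rotation-invariant). The winner is rotated (strand-flipped if
needed) to begin at the *psbA* start; absence of *psbA* downgrades to a
warning.

The inverted-repeat finder seeds exact 31-mer matches between the sequence
and its reverse complement, clusters seeds by antidiagonal with a 50 bp
merge tolerance, requires 95% seed coverage per merged segment, and takes
the largest segment pair as IRa/IRb (IRa is the repeat following the LSC,
giving the conventional LSC–IRa–SSC–IRb order). Detection runs on two
rotations of the circle so repeats straddling the origin are found. A
planted exact repeat may be recovered a few bases longer than planted when
its flanks coincidentally extend the match — the detector reports the true
maximal repeat, and the acceptance test computes that oracle explicitly.

Flip-flop support counts reads whose mapped path fully covers the
IR-through triplet of each structural form and tests the two counts against
a binomial(0.5); with no IR-spanning read the p-value is `NA` (an IR longer
than the longest read is exactly this case).

## 7. The synthetic world

The generator emulates what the pipeline is sensitive to: circular genomes
with exact IRs/DRs and shared inter-organelle segments (optionally diverged
by per-base substitution, which creates the bubble structures that cleaning
merges and disentangling resolves); coverage stratification (organelle ≫
nuclear, exercised via a low-depth linear "nuclear" component); lognormal
read lengths with mean ≈15 kb truncated to 5–25 kb; wraparound sampling of
circles on both strands; and a ~1% total error rate split as 0.1%
substitutions plus 0.9% homopolymer run-length (±1) errors on runs of length
≥ 2. That split is the stated world for every "1% error" test: a literal 1%
substitution rate would corrupt essentially every k-mer (at any k ≥ 300 the
mean clean gap is far below k), turning whole reads into boundary-less error
blocks that the method excludes by rule — no parameterisation of the
corrector can meet a 95% correction target in that world, whereas the
HiFi-like split meets it with margin (~98% in the acceptance run).
Homopolymer errors never delete a base (runs of length 1 are untouched):
a ±1 run-length error at an isolated base is an indel, not a homopolymer
error, and real HiFi chemistry concentrates these errors at genuine
homopolymers.

What the generator does **not** emulate: chimeric reads and adapter
artefacts, quality values, non-uniform coverage along the molecule,
heteroplasmy beyond the two flip-flop forms, and sequence divergence between
IR copies. A green end-to-end test therefore establishes correctness of the
graph algebra, the correction logic and the structural reasoning — not
robustness to every artefact of real instruments.

## 8. Numerical and degenerate-input notes

* Distances/overlaps are integers in hoco space; uncompressed coordinates
  come from per-position run-length consensus, with first-writer-wins on
  the overlap positions of adjacent k-mers (identical for error-free data).
* Tie-breaks are deterministic everywhere: DFS children by descending edge
  coverage then vertex id; bubble survivors by coverage×length then smaller
  first entry; component processing by score then id; candidate selection
  by support then canonical key.
* Caps: 64 expanded nodes and 1e7 DFS states in enumeration (error, with
  advice to raise the coverage filter), 16 rounds for cleaning and
  disentangling, 1000 EM iterations (non-convergence is an error, not a
  silent truncation).
* Empty inputs: empty FASTA yields zero records; a graph with no hits
  yields no labels; a component with a single circular unitig resolves
  trivially.

## 9. Known limitations

Very short IRs (below the syncmer spacing) may not branch the graph at all;
the IR finder still reports them from the resolved sequence. The mapper
drops reads whose placement stays ambiguous rather than guessing, which
slightly undercounts triplet support in heavily duplicated graphs. The
second-round edge-visit search treats the optimised visits as hard caps;
graphs whose true structure needs more visits than c±3 per edge are out of
reach by construction. Base-level polishing beyond run-length consensus is
out of scope.
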