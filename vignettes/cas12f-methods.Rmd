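---
title: "Methods: mining and characterizing compact Cas12f systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and characterizing compact Cas12f systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, rules, and numerical choices behind
cas12ftools: what each stage computes, which parameters matter and why
their defaults are what they are, what the simulators do and do not
emulate, and where the design was genuinely open.

## The mining model

A compact type V-F locus consists of a single-effector *cas* gene
(400-700 aa), a CRISPR repeat-spacer array nearby, and a tracrRNA
transcribed from the noncoding sequence between them. The miner encodes
the three published identification criteria directly: (i) native gene
organization — a Cas12f-like ORF adjacent to an array; (ii) a predicted
tracrRNA with secondary structure; (iii) an anti-repeat able to base-pair
with the crRNA repeat.

**Homology gate.** Candidate ORFs (bacterial code; ATG/GTG/TTG starts;
maximal ORFs, i.e. first start after the previous in-frame stop) are
scored against user-supplied reference Cas12f proteins. The built-in gate
seeds on a shared protein 4-mer, aligns locally with BLOSUM62 and affine
gaps (11/1), and converts the raw score to a Karlin–Altschul E-value,
`E = K m n exp(-lambda S)` with the standard gapped-BLOSUM62 constants
(lambda = 0.267, K = 0.041). The default threshold is E ≤ 1e-10. The gate
is a pluggable contract so a production run can swap in tabular `tblastn`
output (`tblastn_gate()`) without touching downstream logic; desk-scale
runs and all tests use the built-in gate so no external binary is
required. Per-pair `m n` is used as the search space; against a single
reference this is the conservative choice and the planted/random
separation spans >100 orders of magnitude, so the gate is insensitive to
the exact normalization.

**Size gate.** 400-700 aa, inclusive, applied to the translated ORF
without the stop. Both gates must pass.

**Catalytic-residue check.** The two characterized reference effectors
carry their RuvC catalytic aspartates at positions 228/406 (433-aa
effector) and 210/388 (415-aa effector); alanine conversion at any one
abolishes cleavage. `check_ruvc_motif()` aligns candidate to reference
globally (BLOSUM62, 11/1) and maps each reference position through the
alignment columns; `present` requires an aspartate at the mapped column.
Alignments covering under 50% of the reference cannot support position
mapping and fail conservatively. The zinc-finger check has no published
numeric criterion; it is a configurable C4-type motif scan
(`C..C.{8,40}C..C`) and is flagged experimental.

**Array detector.** A CRT-family seed-and-extend scheme: an exact 8-mer
repeated 16-105 bp ahead seeds a candidate; the first two copies are
extended to their maximal exact repeat; further copies are chained in
both directions, each within a Hamming budget of 20% of the repeat
length against the first copy, with spacers constrained to 15-60 bp and
repeats to 18-45 bp. All candidate arrays are collected, deduplicated,
and selected greedily (more copies, then longer repeat, then leftmost;
non-overlapping). The consensus repeat is the column majority with ties
to the lexicographically smallest base. `min_repeats` defaults to 2
because compact loci can carry very short arrays. Orientation is *not*
guessed at detection time — both readings of the consensus are carried
forward and the anti-repeat scan resolves polarity, because pairing to a
transcribed tracrRNA is the only evidence the locus itself offers.

**Locus pairing.** Each candidate gene pairs with the nearest array on
its contig within 10 kb (the distance is not published; 10 kb generously
covers the intergenic spans seen in compact loci while excluding
unrelated arrays). The gene-to-array gap minus any intervening ORF of
≥100 codons forms the noncoding search space for the tracrRNA.

## The anti-repeat rule

The mature crRNA repeat derives from the 3' ~22 nt of the direct repeat,
so the scan queries the 22-nt DR suffix (transcribed) against every
window of the noncoding region, both strands, as an ungapped antiparallel
RNA duplex. A window is an anti-repeat when it forms **at least 9
Watson-Crick pairs (A-U / C-G)** and **at least 65% of the 22 positions
paired counting G-U wobble** — with denominator 22 the effective integer
floor is 15 paired positions. Both thresholds are sharp: 8 WC with any
wobble count fails; 9 WC with 14 total fails; 9 WC with 15 total passes.
Pairing is ungapped because the rule counts pairs inside a fixed window,
which leaves no room for indels; N pairs with nothing. The 65%
denominator could arguably be the number of scorable positions rather
than the window length; the window was chosen as the plain reading and
is the stricter of the two for N-containing windows.

Overlapping hits on a strand are resolved by keeping the hit with the
most WC pairs, then most total pairs, ties leftmost. Accepted hits are
extended **150 nt upstream** — upstream meaning 5' on the tracrRNA
transcript — clamped at the region boundary with a logged warning.

**Structure screen.** "Conserved secondary structure" has no published
quantitative definition, so the screen is a declared heuristic with two
knobs: a candidate passes with at least `min_hairpins = 2` hairpin loops
each closed by a stacked stem of at least `min_stem = 4` pairs. The
default folder is a maximum-base-pairing dynamic program (Nussinov
recursion; WC + wobble; minimum loop 3; deterministic traceback that
leaves a base unpaired unless pairing strictly gains and picks the
smallest partner index; score = −pairs so lower is more stable). Maximum
base pairing over-pairs random sequence relative to a thermodynamic
model, so the screen annotates candidates rather than dropping them —
pipeline recovery is decided by the pairing rule, and the structure
fields travel with each candidate for downstream triage. An `RNAfold`
adapter (`fold_rnafold()`) satisfies the same folder contract for
thermodynamic folding.

## sgRNA design

The single guide is tracrRNA + `GAAA` tetraloop + mature repeat + spacer,
with a 20-nt spacer default (the optimum for these effectors; 15-30
accepted) and an optional 3' `TTTTATTTTTTT` stability tail stored as its
transcript in RNA output and as DNA in expression-cassette export. The
PAM sits strictly 5' of the protospacer (type V convention); spacer
search accepts any IUPAC pattern and scans both strands. Stem
stabilization enumerates all combinations of 1..`max_edits` annotated
stem pairs that are not already C-G/G-C, replacing each with C-G, in
lexicographic order of edited positions. Enumeration is deliberately
unranked: variant activity is a wet-lab readout, not something this
toolkit predicts.

## PAM inference

The randomized library places 7 random bases behind a fixed flank;
`count_pam_kmers()` anchors each read on the flank (one mismatch
tolerated, absorbing sequencing error; first match wins) and tallies the
k-mer at the anchored offset, counting unanchored and N-containing reads
separately. Enrichment for k-mer *x* is the pseudocounted frequency
ratio `((t_x + p)/T) / ((c_x + p)/C)` with p = 0.5, descending, ties
lexicographic; survivor-depleted mode inverts the ratio so active PAMs
rank first in both readouts, making the two modes exactly reciprocal.
The profile takes the top 1000 ranked k-mers (the conventional logo
input) unweighted into a position frequency matrix; information content
per position is `2 + sum f log2 f` bits; the IUPAC consensus keeps, per
position, every base at ≥ 50% of the maximum base frequency, and renders
leading/trailing positions under 0.3 bits as N (flagged uninformative).

One structural caveat drove a design addition. When the true PAM is
sparse — e.g. a YTTH preference admits only 384 of the 16384 7-mers — a
fixed top-1000 window *must* pad the profile with ≥ 616 background
k-mers, which dilutes degenerate positions (an H position tops out at
0.415 bits even undiluted) below both the inclusion and trim thresholds
no matter how deep the library is. `enriched_kmers()` therefore filters
the ranking to supported, enriched k-mers (≥ 2 product reads and ≥
2-fold enrichment — a one-read k-mer in a product library is
indistinguishable from carryover) before the top-K cap, and the
count-weighted PFM option uses product-read weights so residual
background k-mers, which carry few reads, contribute proportionally
little. Under the simulator's study conditions (activity 0.9 vs 0.01,
100k reads) this recovers the planted YTTH and NCCD consensi in 20/20
seeded replicates, while the unfiltered top-1000 path remains the
default for real libraries, whose active k-mer sets are typically graded
and larger.

Run-off cut-site mapping re-expresses per-strand read-end positions as bp
downstream of the PAM 3' boundary and reports per-strand histograms,
modes (ties to the smaller position), their absolute difference as the
modal overhang (0 = blunt; these effectors produce staggered ends within
21-25 bp of the PAM), and the overall range.

## Indel quantification

Reads align to the amplicon with affine-gap global-in-read alignment
(match +2, mismatch −2, gap open −6 for the first gap base, −1 per
additional — the scaled semantics of a `bwa mem -A2 -O3 -E1` call);
both orientations are tried and the better kept, so calls are
orientation-invariant. Alignments under 60% identity are unaligned and
excluded from the denominator. Indels are left-normalized before any
window logic so homopolymer placement is deterministic.

The expected cut defaults to PAM+23, the midpoint of the 21-25 bp
run-off range, and the quantification window is 10 bp wide centered on
it (`[cut−5, cut+5)`). A read is **edited** iff at least one indel
overlaps the window; substitutions never count (for a nuclease assay the
NHEJ signature is indels, and counting substitutions would absorb
sequencing error into the editing rate). The published methods phrase
describing "desired edits without indels within a 10-bp window" is
base-editor boilerplate; the nuclease reading — indel-in-window ⇒
edited — is the implemented interpretation. The window rule makes a
clean testable prediction: an indel at distance d from the cut flips
classification exactly when the window width crosses 2d, which the test
suite sweeps explicitly. The indel frequency is
`100 × edited / (total − unaligned)`; allele keys are the reads' base
strings over the reference window (insertions included), so the
unedited allele keys to the reference window sequence; deletion centers
are reported relative to the PAM 3' end, where these effectors cluster
PAM-distal, beyond the protospacer.

## Simulators and what passing tests mean

All generators are seeded and bit-reproducible. `simulate_locus()` lays
out flank / in-frame stop / reverse-translated cas ORF (uniform seeded
codon draw — no codon-usage model) / noncoding gap with a planted
anti-repeat window constructed to pair with the DR suffix at *exactly*
the requested WC and wobble counts / repeat-spacer array / flank. Two
constructions keep the truth sharp: spacer and flank boundary bases are
assigned so repeat extension stops exactly at the planted repeat
boundaries (exact for up to 4 copies), and the noncoding gap is
deterministically sanitized — bases mutated from the seeded stream,
never inside the planted window — until the scanner reports exactly the
planted hit (or none when the planted counts are below threshold) under
both DR readings and the gap carries no ORF long enough to be excised.
Sanitization is needed because with a G/U-rich repeat suffix a few
random windows per kilobase clear the 9/15 rule by chance; a pipeline
run on real genomes should expect such hits, and the merge rule plus
structure annotations are what triage them.

`simulate_pam_library()` draws uniform 7-mers into the anchored
construct and retains each read with probability 0.9 (motif match) or
0.01 (background) — product-enriched readout, no PCR resequencing model,
no quality-dependent errors. `simulate_amplicon_reads()` allocates reads
to alleles by largest remainder so small fixtures carry exact counts (a
multinomial mode exists for statistical tests) and injects substitution
errors only.

The tests therefore demonstrate correctness of the *rules* — threshold
sharpness, oracle equivalence against brute-force enumerations
(six-frame ORF scan, exhaustive seed-pair arrays, all-offset anti-repeat
enumeration, brute-force maximum pairing at ≤16 nt, IUPAC window scan),
planted-truth recovery, and estimator calibration — not performance on
real genomes, where repeat degeneracy, IS elements, and sequencing
artifacts are harsher than anything the generators emulate.

## Problem sizes and numerical notes

The standard suites run oracle comparisons on ~50 random instances per
operation (sequences up to a few kb), a 12-cell planted-locus truth
table, 20 seeded replicates per PAM motif at 100k reads, and amplicon
fixtures at n = 100-2000 — sizes chosen so each behavioral claim is
exercised well inside a coffee break while keeping multiple independent
replicates behind every stochastic assertion. Ties are broken
deterministically everywhere (lexicographic k-mers, leftmost hits,
smallest pairing partner, alphabetical consensus bases) so identical
inputs give identical outputs; the only randomness is user-seeded. The
reference proteins bundled under `inst/extdata/` are *synthetic
stand-ins* — correct lengths (433/415 aa) and catalytic aspartate
positions (228/406, 210/388) planted on otherwise random sequence, as
their filename and headers state — used so position-mapping logic is
testable without redistributing published supplementary sequences.

## Known limitations

The built-in folder maximizes pairing, not free energy; use the RNAfold
adapter when stem topology matters. The homology gate's E-value is an
approximation calibrated for gapped BLOSUM62 scoring, adequate for a
1e-10 gate but not for borderline calls. The array detector requires one
exact 8-mer between the first two copies and reports at most the
non-overlapping greedy-optimal arrays. Editing quantification models
single-amplicon short reads; paired-end merging, large deletions
spanning amplicon ends, and translocations are out of scope.
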