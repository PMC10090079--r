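# cas12ftools

Discovery and characterization toolkit for hypercompact type V-F
CRISPR-Cas12f systems, for computational biologists mining bacterial
genome assemblies for miniature genome-editing effectors and
characterizing them from sequencing assays.

Cas12f effectors are 400-700 aa RNA-guided nucleases — less than half the
gene size of SpCas9 — that pair with a tracrRNA and target 5' T-/C-rich
PAMs, making them attractive for single-AAV delivery. This package
implements the full desk side of their discovery and characterization:

- **Locus mining** — ORF calling (bacterial code, ATG/GTG/TTG starts), a
  translated-homology gate against reference Cas12f proteins (local
  BLOSUM62 alignment with a Karlin–Altschul E-value, default E ≤ 1e-10;
  `tblastn` adapter for production scale), a 400-700 aa size gate, and a
  RuvC catalytic-aspartate check by global-alignment position mapping
  (e.g. D228/D406 or D210/D388 on the two reference effectors).
- **CRISPR array detection** — CRT-style seed-and-extend repeat-spacer
  detector (repeat 18-45 bp, spacer 15-60 bp, ≤20% mismatch to the
  column-majority consensus).
- **tracrRNA prediction** — anti-repeat scan of the cas-array noncoding
  gap against the 22-nt 3' end of the direct repeat: a window is accepted
  with ≥9 Watson-Crick (A-U/C-G) pairs and ≥65% of the 22 positions
  paired counting G-U wobble; accepted hits are extended 150 nt upstream
  and screened by secondary structure (built-in maximum-base-pairing
  folder; `RNAfold` adapter).
- **sgRNA design** — tracrRNA–GAAA-tetraloop–crRNA scaffold assembly
  (20-nt spacer default, optional `TTTTATTTTTTT` 3' stability tail),
  PAM-constrained spacer search (IUPAC patterns, both strands), and
  combinatorial A-U→C-G stem-stabilization variant libraries.
- **PAM profiling** — 7N randomized-library readout: anchored k-mer
  tallies, treated/control enrichment ranking, top-K position frequency
  matrix, per-position information content, IUPAC consensus, logo-matrix
  export, and run-off cut-site mapping (these effectors cut 21-25 bp
  downstream of the 5' PAM with staggered ends).
- **Editing outcomes** — amplicon-seq indel quantification: global-in-read
  affine alignment (match +2 / mismatch −2 / gap −6,−1), left-normalized
  indels, edited = any indel inside a 10-bp window centered on the
  expected cut (PAM+23 by default), allele tables, deletion
  position/size profiles.
- **Simulators** — seeded, bit-reproducible generators for every input:
  planted Cas12f loci with exact anti-repeat pairing counts, randomized
  PAM libraries under a planted activity model, and amplicon reads with
  planted allele mixes.

## Worked example

Mine a simulated locus and quantify a simulated editing experiment:

```r
library(cas12ftools)

refs <- read_protein_fasta(system.file("extdata",
  "synthetic_cas12f1_standins.faa", package = "cas12ftools"))
os <- unname(refs[1])                      # 433-aa synthetic stand-in

repeat40 <- "GTTTCAATCCACGCGCCCATAGGGATTCGAAATTGAAGGT"
sim <- simulate_locus(os, repeat40, anti_repeat_wc = 12,
                      anti_repeat_wobble = 3, seed = 42)
g <- sim$genome
loci <- pair_locus(scan_cas_candidates(g, c(Os = os)),
                   find_crispr_arrays(g), g)
loci <- lapply(loci, predict_tracr, genome = g)
print(loci[[1]])
#> Cas12f locus model on contig1
#>   cas gene [152,1454) +, 433 aa, E=1.92e-290 (ref Os)
#>   array [1955,2205), 4 repeats; distance 501 bp
print(loci[[1]]$tracr_candidates[[1]])
#> tracrRNA candidate, 172 nt, strand + [1504,1676)
#>   anti-repeat: 12 WC + 3 wobble (68.2% paired)
```

The locus model carries the candidate gene (homology E-value, size), the
repeat-spacer array with its consensus repeat, and the tracrRNA candidate
whose anti-repeat satisfied the 9-WC / 15-of-22 pairing rule: the planted
12 WC + 3 wobble pairs over the 22-nt window are 68.2% paired.

```r
set.seed(1)
amp <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
amp <- paste0(substr(amp, 1, 80), "TTTA", "CCATTACAGTAGGAGCATAC",
              substr(amp, 105, 200))
ref <- amplicon_ref(amp, pam_start = 80, pam_end = 84)
reads <- simulate_amplicon_reads(ref, alleles = list(
  list(name = "WT",   proportion = 0.7, type = "wt"),
  list(name = "del3", proportion = 0.3, type = "del",
       pos = ref$expected_cut - 1, len = 3)), n_reads = 100, seed = 5)
quantify_edits(reads$reads, ref)
#> Editing summary: 100 reads ( 0 unaligned )
#>   indel frequency: 30.0% (30 edited / 100 aligned)
#>   top alleles:
#>      allele  n pct edited
#>  ACAAGCAAGG 70  70  FALSE
#>     ACAAAGG 30  30   TRUE
```

The allele keys are the reads' base strings over the 10-bp quantification
window: 70 reads match the reference window, 30 carry the planted 3-bp
deletion.

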