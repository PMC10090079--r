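# Shared fixtures, built in code at test time.

standin_proteins <- function() {
  read_protein_fasta(system.file("extdata", "synthetic_cas12f1_standins.faa",
                                 package = "cas12ftools"))
}

# a 40-nt direct repeat used across locus fixtures (G/U-capable suffix)
fixture_repeat <- "GTTTCAATCCACGCGCCCATAGGGATTCGAAATTGAAGGT"

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# amplicon with a TTTA PAM at [80, 84) and a 20-nt protospacer
fixture_amplicon <- function(seed = 3) {
  set.seed(seed)
  amp <- random_dna_str(200)
  amp <- paste0(substr(amp, 1, 80), "TTTA", "CCATTACAGTAGGAGCATAC",
                substr(amp, 105, 200))
  amplicon_ref(amp, pam_start = 80, pam_end = 84)
}

# DNA window that pairs with the DR suffix at exactly (wc, wobble)
planted_window <- function(dr_rna, wc, wobble) {
  cas12ftools:::plant_anti_repeat(dr_rna, wc, wobble)
}
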