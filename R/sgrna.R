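# the poly-U-interrupted DNA tail fused to the sgRNA 3' end for stability
SGRNA_DNA_TAIL <- "TTTTATTTTTTT"

check_rna <- function(x, what = "RNA part") {
  check_alphabet(x, alphabet = c("A", "C", "G", "U", "N"), what = what)
}

#' Assemble a single-guide RNA scaffold
#'
#' The sgRNA used by compact type V-F effectors is the tracrRNA fused to
#' the mature crRNA through a GAAA tetraloop:
#' tracr - GAAA - repeat - spacer, optionally followed by the stabilizing
#' 3' tail (DNA `TTTTATTTTTTT`, stored transcribed in the RNA sequence).
#' A 20-nt spacer is the default (optimal for these effectors).
#'
#' @param tracr_part tracrRNA portion (RNA).
#' @param repeat_part mature-repeat portion (RNA).
#' @param spacer spacer (RNA), length 15-30.
#' @param tetraloop fusion tetraloop (RNA).
#' @param u_tail append the stabilizing 3' tail.
#' @return list of class `sgrna` with the parts and the full `sequence`.
#' @export
assemble_sgrna <- function(tracr_part, repeat_part, spacer,
                           tetraloop = "GAAA", u_tail = FALSE) {
  tracr_part <- check_rna(tracr_part, "tracr part")
  repeat_part <- check_rna(repeat_part, "repeat part")
  spacer <- check_rna(spacer, "spacer")
  tetraloop <- check_rna(tetraloop, "tetraloop")
  if (nchar(spacer) < 15 || nchar(spacer) > 30) {
    stop("spacer length must be in [15, 30] nt", call. = FALSE)
  }
  tail <- if (u_tail) transcribe(SGRNA_DNA_TAIL) else ""
  structure(list(
    tracr_part = tracr_part, tetraloop = tetraloop,
    repeat_part = repeat_part, spacer = spacer, u_tail = tail,
    sequence = paste0(tracr_part, tetraloop, repeat_part, spacer, tail)
  ), class = "sgrna")
}

#' @export
print.sgrna <- function(x, ...) {
  cat("sgRNA,", nchar(x$sequence), "nt",
      if (nzchar(x$u_tail)) "(with 3' U-tail)" else "", "\n")
  cat("  tracr", nchar(x$tracr_part), "nt | ", x$tetraloop, " | repeat",
      nchar(x$repeat_part), "nt | spacer", nchar(x$spacer), "nt\n")
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Export an sgRNA as a DNA expression cassette
#'
#' @param sgrna an `sgrna` object.
#' @return DNA string (U -> T).
#' @export
sgrna_cassette <- function(sgrna) rna_to_dna(sgrna$sequence)

#' Find spacer sites in a target under a 5' PAM constraint
#'
#' Type V convention: the PAM lies immediately 5' of the protospacer. Both
#' strands are searched; matching uses IUPAC degenerate codes (e.g. TTTR,
#' TTN, NCCD).
#'
#' @param target_seq target DNA (forward orientation).
#' @param pam_iupac PAM pattern over the IUPAC alphabet.
#' @param spacer_len protospacer length.
#' @return data.frame with columns start, end, strand (protospacer interval
#'   in forward 0-based half-open coordinates), pam, protospacer,
#'   spacer_rna.
#' @export
find_spacers <- function(target_seq, pam_iupac, spacer_len = 20L) {
  target_seq <- check_alphabet(target_seq, what = "target")
  pam_iupac <- toupper(pam_iupac)
  if (!all(seq_chars(pam_iupac) %in% names(IUPAC_MAP))) {
    stop("invalid IUPAC code in PAM pattern", call. = FALSE)
  }
  k <- nchar(pam_iupac)
  L <- nchar(target_seq)
  rows <- list()
  if (L >= k + spacer_len) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") target_seq else revcomp(target_seq)
      # fixed = "subject": IUPAC codes interpreted in the pattern only, so
      # an N in the target never satisfies a PAM position
      m <- Biostrings::matchPattern(pam_iupac, Biostrings::DNAString(s),
                                    fixed = "subject")
      for (p0 in BiocGenerics::start(m) - 1) {  # 0-based PAM start
        ps <- p0 + k
        if (ps + spacer_len > L) next
        proto <- substr(s, ps + 1, ps + spacer_len)
        if (strand == "+") {
          st <- ps; en <- ps + spacer_len
        } else {
          st <- L - (ps + spacer_len); en <- L - ps
        }
        rows[[length(rows) + 1]] <- data.frame(
          start = st, end = en, strand = strand,
          pam = substr(s, p0 + 1, p0 + k), protospacer = proto,
          spacer_rna = transcribe(proto), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), pam = character(),
                      protospacer = character(), spacer_rna = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Enumerate C-G stem-stabilization variants of an sgRNA scaffold
#'
#' Stem stabilization replaces A-U or mismatched (non C-G) annotated stem
#' base pairs with C-G; enumerating all combinations of 1..`max_edits`
#' eligible pairs yields the candidate library that a wet-lab screen would
#' rank (this tool does not predict activity). Variants are returned in
#' lexicographic order of their edited pair indices.
#'
#' @param sgrna an `sgrna` object.
#' @param stem_annotation data.frame with columns pos5, pos3: 1-based
#'   positions in the full sgRNA sequence of annotated stem pairs
#'   (5' partner, 3' partner).
#' @param max_edits maximum number of pairs edited in one variant.
#' @return list of variants; each has `edits` (data.frame pos5, pos3,
#'   old5, old3), `sequence`, and `pair_idx` (indices into the eligible
#'   pair list).
#' @export
enumerate_stem_cg_variants <- function(sgrna, stem_annotation,
                                       max_edits = 1L) {
  seq <- sgrna$sequence
  n <- nchar(seq)
  if (nrow(stem_annotation) > 0 &&
      (any(stem_annotation$pos5 < 1) || any(stem_annotation$pos3 > n) ||
       any(stem_annotation$pos5 >= stem_annotation$pos3))) {
    stop("stem annotation positions out of range", call. = FALSE)
  }
  v <- seq_chars(seq)
  eligible <- which(!(v[stem_annotation$pos5] == "C" &
                      v[stem_annotation$pos3] == "G") &
                    !(v[stem_annotation$pos5] == "G" &
                      v[stem_annotation$pos3] == "C"))
  if (length(eligible) == 0) return(list())
  variants <- list()
  for (m in seq_len(min(max_edits, length(eligible)))) {
    sets <- combn(seq_along(eligible), m)
    for (ci in seq_len(ncol(sets))) {
      idx <- eligible[sets[, ci]]
      w <- v
      ed <- stem_annotation[idx, , drop = FALSE]
      old5 <- w[ed$pos5]; old3 <- w[ed$pos3]
      w[ed$pos5] <- "C"; w[ed$pos3] <- "G"
      variants[[length(variants) + 1]] <- list(
        edits = data.frame(pos5 = ed$pos5, pos3 = ed$pos3,
                           old5 = old5, old3 = old3,
                           stringsAsFactors = FALSE),
        sequence = paste(w, collapse = ""),
        pair_idx = sets[, ci])
    }
  }
  variants
}
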