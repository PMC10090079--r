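#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats runif setNames
#' @importFrom utils head combn write.table
NULL

# IUPAC degenerate nucleotide codes -> base sets
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param code single IUPAC letter.
#' @return character vector of plain bases (subset of A, C, G, T).
#' @examples
#' iupac_to_bases("Y")
#' @export
iupac_to_bases <- function(code) {
  code <- toupper(code)
  if (!code %in% names(IUPAC_MAP)) {
    stop("invalid IUPAC code: ", code, call. = FALSE)
  }
  IUPAC_MAP[[code]]
}

#' Collapse a set of bases to its IUPAC degenerate code
#'
#' @param bases character vector over A, C, G, T (non-empty).
#' @return single IUPAC letter.
#' @examples
#' bases_to_iupac(c("C", "T"))
#' @export
bases_to_iupac <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 0 || !all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be a non-empty subset of A, C, G, T", call. = FALSE)
  }
  key <- paste(bases, collapse = "")
  codes <- vapply(IUPAC_MAP, function(b) paste(sort(b), collapse = ""), "")
  names(codes)[match(key, codes)]
}

#' Test whether a base matches an IUPAC code
#' @noRd
iupac_matches <- function(base, code) {
  base %in% iupac_to_bases(code)
}

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# validate a DNA string over a given alphabet; returns the uppercased string
check_alphabet <- function(x, alphabet = c("A", "C", "G", "T", "N"),
                           what = "sequence") {
  x <- toupper(x)
  bad <- setdiff(unique(seq_chars(x)), alphabet)
  if (length(bad) > 0) {
    stop(what, " contains invalid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' Construct a genomic interval (0-based, half-open)
#'
#' All coordinates inside the toolkit are 0-based half-open; conversion to
#' 1-based happens only at GFF3 export.
#'
#' @param contig_id contig identifier.
#' @param start 0-based start (inclusive).
#' @param end end (exclusive), must be greater than `start`.
#' @param strand "+" or "-".
#' @return one-row data.frame with columns contig_id, start, end, strand.
#' @export
interval <- function(contig_id, start, end, strand = "+") {
  stopifnot(start >= 0, end > start, strand %in% c("+", "-"))
  data.frame(contig_id = contig_id, start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

# simple conditional logger: emits message() unless quiet option set
toolkit_log <- function(..., module = "cas12ftools") {
  if (!isTRUE(getOption("cas12ftools.quiet", FALSE))) {
    message("[", module, "] ", ...)
  }
  invisible(NULL)
}

# run code with a local, restored RNG state under a fixed seed
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# random DNA string of length n from the current RNG stream
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
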