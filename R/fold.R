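# RNA pairing predicate for folding: WC + wobble
can_pair_rna <- function(a, b) PAIR_CLASS[a, b] > 0L

#' Fold RNA by maximum base pairing (Nussinov dynamic program)
#'
#' Built-in structure folder: maximizes the number of Watson-Crick plus
#' wobble pairs with a minimum hairpin loop of `min_loop` unpaired bases.
#' The traceback is deterministic: a position is left unpaired unless
#' pairing strictly increases the pair count, and the smallest pairing
#' partner index achieving the maximum is chosen. The score is the
#' negative pair count, so that lower scores mean more stable structures,
#' mirroring a free-energy-like convention.
#'
#' @param rna RNA string over A/C/G/U/N.
#' @param min_loop minimum unpaired bases inside a hairpin loop.
#' @return list with `structure` (dot-bracket) and `score` (-pair count).
#' @export
fold_nussinov <- function(rna, min_loop = 3L) {
  v <- seq_chars(check_alphabet(rna, alphabet = c("A", "C", "G", "U", "N"),
                                what = "RNA"))
  n <- length(v)
  if (n == 0) stop("empty RNA", call. = FALSE)
  db <- rep(".", n)
  if (n <= min_loop + 1) {
    return(list(structure = paste(db, collapse = ""), score = 0))
  }
  pairable <- PAIR_CLASS[v, v, drop = FALSE] > 0L  # n x n logical
  M <- matrix(0L, n, n)
  for (span in (min_loop + 1):(n - 1)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- M[i, j - 1]
      ks <- i:(j - min_loop - 1)
      ks <- ks[pairable[ks, j]]
      if (length(ks) > 0) {
        left <- vapply(ks, function(k) if (k > i) M[i, k - 1] else 0L, 0L)
        inner <- vapply(ks, function(k) if (k + 1 <= j - 1) M[k + 1, j - 1]
                        else 0L, 0L)
        vals <- left + 1L + inner
        best <- max(best, max(vals))
      }
      M[i, j] <- best
    }
  }
  # deterministic traceback
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i <= min_loop) next
    if (M[i, j] == M[i, j - 1]) {
      stack[[length(stack) + 1]] <- c(i, j - 1L)
      next
    }
    for (k in i:(j - min_loop - 1)) {
      if (!pairable[k, j]) next
      left <- if (k > i) M[i, k - 1] else 0L
      inner <- if (k + 1 <= j - 1) M[k + 1, j - 1] else 0L
      if (left + 1L + inner == M[i, j]) {
        db[k] <- "("; db[j] <- ")"
        if (k > i) stack[[length(stack) + 1]] <- c(i, k - 1L)
        if (k + 1 <= j - 1) stack[[length(stack) + 1]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }
  pairs <- sum(db == "(")
  list(structure = paste(db, collapse = ""), score = -pairs)
}

#' External thermodynamic folder adapter (RNAfold)
#'
#' Adapts ViennaRNA's `RNAfold` (must be on PATH) to the folder contract
#' used by [screen_structure()]: RNA in, dot-bracket and a stability score
#' (the minimum free energy, kcal/mol) out.
#'
#' @param rna RNA string.
#' @return list with `structure` and `score`.
#' @export
fold_rnafold <- function(rna) {
  if (Sys.which("RNAfold") == "") {
    stop("RNAfold not found on PATH", call. = FALSE)
  }
  out <- system2("RNAfold", "--noPS", input = rna, stdout = TRUE)
  line <- out[2]
  db <- sub("^([.()]+).*$", "\\1", line)
  mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
  list(structure = db, score = mfe)
}

# parse dot-bracket to a pair map: integer vector, p[i] = partner or NA
pair_map <- function(db) {
  v <- seq_chars(db)
  p <- rep(NA_integer_, length(v))
  st <- integer()
  for (i in seq_along(v)) {
    if (v[i] == "(") st <- c(st, i)
    else if (v[i] == ")") {
      j <- st[length(st)]; st <- st[-length(st)]
      p[i] <- j; p[j] <- i
    }
  }
  p
}

#' Count hairpin loops closed by a sufficiently stacked stem
#'
#' A hairpin is a pair (i, j) with every base strictly between i and j
#' unpaired; its stem length is the maximal run of exactly stacked pairs
#' (i-k, j+k) closing it. Only hairpins with stem length at least
#' `min_stem` are counted.
#'
#' @param db dot-bracket string.
#' @param min_stem minimum stacked stem length.
#' @return integer hairpin count.
#' @export
count_hairpins <- function(db, min_stem = 4L) {
  p <- pair_map(db)
  n <- length(p)
  count <- 0L
  for (i in seq_len(n)) {
    j <- p[i]
    if (is.na(j) || j <= i) next
    if (j - i > 1 && any(!is.na(p[(i + 1):(j - 1)]))) next  # not a hairpin
    stem <- 1L
    while (i - stem >= 1 && j + stem <= n &&
           !is.na(p[i - stem]) && p[i - stem] == j + stem) {
      stem <- stem + 1L
    }
    if (stem >= min_stem) count <- count + 1L
  }
  count
}
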