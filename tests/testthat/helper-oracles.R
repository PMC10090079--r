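# Brute-force oracles, written as plainly as possible and independent of
# the package's implementation paths.

oracle_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[oracle_chars(x)])), collapse = "")
}

# six-frame ORF scan: maximal ORFs (first start after the previous in-frame
# stop), ending at the stop codon or at the last complete codon of the contig
oracle_orfs <- function(seq, min_len_aa,
                        starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  code <- Biostrings::getGeneticCode("11")
  out <- list()
  L <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (frame in 0:2) {
      n <- (nchar(s) - frame) %/% 3
      if (n < 1) next
      cod <- substring(s, frame + 3 * (0:(n - 1)) + 1, frame + 3 * (0:(n - 1)) + 3)
      seg_start <- 1
      for (ci in seq_len(n)) {
        last <- ci == n
        if (cod[ci] %in% stops || last) {
          has_stop <- cod[ci] %in% stops
          seg <- seg_start:ci
          starts_here <- seg[cod[seg] %in% starts &
                               (if (has_stop) seg < ci else TRUE)]
          if (length(starts_here) > 0) {
            a <- starts_here[1]
            s0 <- frame + 3 * (a - 1)
            e0 <- frame + 3 * ci
            aa <- unname(code[cod[a:ci]])
            aa[is.na(aa)] <- "X"
            if (has_stop) aa <- aa[-length(aa)]
            prot <- paste(aa, collapse = "")
            if (nchar(prot) >= min_len_aa) {
              st <- if (strand == "+") s0 else L - e0
              en <- if (strand == "+") e0 else L - s0
              out[[length(out) + 1]] <- data.frame(
                start = st, end = en, strand = strand, protein = prot,
                partial = !has_stop, stringsAsFactors = FALSE)
            }
          }
          if (has_stop) seg_start <- ci + 1
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), protein = character(),
                      partial = logical(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end, df$strand), ]
  rownames(df) <- NULL
  df
}

# brute-force IUPAC PAM + spacer scan, no regular expressions
oracle_spacers <- function(target, pam, spacer_len) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  pv <- oracle_chars(pam)
  k <- length(pv)
  L <- nchar(target)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") target else oracle_revcomp(target)
    sv <- oracle_chars(s)
    for (p0 in 0:(L - k - spacer_len)) {
      if (L - k - spacer_len < 0) break
      ok <- TRUE
      for (q in seq_len(k)) {
        if (!(sv[p0 + q] %in% iupac[[pv[q]]])) { ok <- FALSE; break }
      }
      if (!ok) next
      proto <- substr(s, p0 + k + 1, p0 + k + spacer_len)
      st <- if (strand == "+") p0 + k else L - (p0 + k + spacer_len)
      en <- st + spacer_len
      out[[length(out) + 1]] <- data.frame(
        start = st, end = en, strand = strand,
        pam = substr(s, p0 + 1, p0 + k), protospacer = proto,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), pam = character(),
                      protospacer = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# brute-force anti-repeat enumeration over all offsets x both strands
oracle_anti_repeat <- function(region, dr_rna, window = 22, wc_min = 9,
                               frac_min = 0.65) {
  pair_type <- function(a, b) {
    wc <- (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "C" && b == "G") || (a == "G" && b == "C")
    wob <- (a == "G" && b == "U") || (a == "U" && b == "G")
    if (wc) 2 else if (wob) 1 else 0
  }
  dr <- oracle_chars(dr_rna)
  L <- nchar(region)
  out <- list()
  for (strand in c("+", "-")) {
    tx <- chartr("T", "U", if (strand == "+") region else
      oracle_revcomp(region))
    tv <- oracle_chars(tx)
    for (o in 0:(L - window)) {
      wrev <- tv[(o + window):(o + 1)]
      cls <- mapply(pair_type, dr, wrev)
      wc <- sum(cls == 2); wob <- sum(cls == 1)
      if (wc >= wc_min && (wc + wob) / window >= frac_min) {
        fs <- if (strand == "+") o else L - o - window
        out[[length(out) + 1]] <- data.frame(
          start = fs, end = fs + window, strand = strand, wc_pairs = wc,
          wobble_pairs = wob, total_pairs = wc + wob,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), wc_pairs = integer(),
                      wobble_pairs = integer(), total_pairs = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# exhaustive array detection: every seed pair enumerated by direct substring
# comparison; extension/chaining per the detector's declared contract
oracle_arrays <- function(seq, repeat_len = c(18, 45), spacer_len = c(15, 60),
                          min_repeats = 2, mmfrac = 0.2, seed_len = 8,
                          lookahead = c(16, 105)) {
  ch <- oracle_chars(seq)
  L <- length(ch)
  ham <- function(a0, b0, len) {
    sum(ch[(a0 + 1):(a0 + len)] != ch[(b0 + 1):(b0 + len)])
  }
  n_pos <- L - seed_len + 1
  kmers <- substring(seq, 1:n_pos, 1:n_pos + seed_len - 1)
  seed_pairs <- list()
  for (d in lookahead[1]:lookahead[2]) {
    if (d >= n_pos) break
    hit <- which(kmers[1:(n_pos - d)] == kmers[(1 + d):n_pos])
    if (length(hit) > 0) {
      seed_pairs[[length(seed_pairs) + 1]] <-
        cbind(i = hit - 1, j = hit - 1 + d)
    }
  }
  cands <- list()
  keys <- character()
  if (length(seed_pairs) > 0) {
    sp_mat <- do.call(rbind, seed_pairs)
    for (row in seq_len(nrow(sp_mat))) {
      i <- unname(sp_mat[row, "i"]); j <- unname(sp_mat[row, "j"])
      l <- 0
      while (i - l - 1 >= 0 && ch[i - l] == ch[j - l]) l <- l + 1
      r <- seed_len
      while (i + r < j - l && j + r < L && ch[i + r + 1] == ch[j + r + 1]) {
        r <- r + 1
      }
      u_start <- i - l; u_len <- l + r
      if (u_len < repeat_len[1] || u_len > repeat_len[2]) next
      v_start <- j - l
      spc <- v_start - (u_start + u_len)
      if (spc < spacer_len[1] || spc > spacer_len[2]) next
      budget <- floor(mmfrac * u_len)
      copies <- c(u_start, v_start)
      repeat {
        last <- copies[length(copies)]
        lo <- last + u_len + spacer_len[1]
        hi <- min(last + u_len + spacer_len[2], L - u_len)
        if (lo > hi) break
        d <- sapply(lo:hi, function(q) ham(q, u_start, u_len))
        if (min(d) > budget) break
        copies <- c(copies, (lo:hi)[which.min(d)])
      }
      repeat {
        first <- copies[1]
        hi <- first - u_len - spacer_len[1]
        lo <- max(first - u_len - spacer_len[2], 0)
        if (hi < lo) break
        d <- sapply(lo:hi, function(q) ham(q, u_start, u_len))
        if (min(d) > budget) break
        copies <- c((lo:hi)[which.min(d)], copies)
      }
      if (length(copies) < min_repeats) next
      key <- paste(c(u_len, copies), collapse = ",")
      if (key %in% keys) next
      keys <- c(keys, key)
      cands[[length(cands) + 1]] <- list(copies = copies, u_len = u_len)
    }
  }
  if (length(cands) == 0) return(list())
  score_select(cands, L)
}

score_select <- function(cands, L) {
  score <- sapply(cands, function(a) {
    length(a$copies) * 1e9 + a$u_len * 1e4 - a$copies[1] / L
  })
  chosen <- list(); occupied <- integer()
  for (k in order(-score)) {
    a <- cands[[k]]
    span <- (a$copies[1] + 1):(a$copies[length(a$copies)] + a$u_len)
    if (length(intersect(span, occupied)) > 0) next
    occupied <- c(occupied, span)
    chosen[[length(chosen) + 1]] <- a
  }
  chosen[order(sapply(chosen, function(a) a$copies[1]))]
}

# true brute force max base pairing: enumerate all nested pair sets
oracle_max_pairs <- function(rna, min_loop = 3) {
  v <- oracle_chars(rna)
  pairs_ok <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  best <- function(i, j) {
    if (j - i <= min_loop) return(0)
    b <- best(i, j - 1)              # j unpaired
    for (k in i:(j - min_loop - 1)) {
      if (pairs_ok(v[k], v[j])) {
        left <- if (k > i) best(i, k - 1) else 0
        inner <- if (k + 1 <= j - 1) best(k + 1, j - 1) else 0
        b <- max(b, left + 1 + inner)
      }
    }
    b
  }
  best(1, length(v))
}
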