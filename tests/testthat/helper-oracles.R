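# Independent oracles used by the unit and acceptance tests.  Each one
# recomputes a quantity by brute force, without touching the implementation
# path it checks.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

rc_str <- function(x) viroscout::revcomp(x)

make_reads <- function(seqs, quals = NULL, prefix = "r") {
  if (is.null(quals)) quals <- vapply(nchar(seqs), function(n)
    paste(rep(rawToChar(as.raw(30 + 33)), n), collapse = ""), character(1))
  data.frame(id = sprintf("%s%04d", prefix, seq_along(seqs)), seq = seqs,
             qual = quals, stringsAsFactors = FALSE)
}

qual_string <- function(q) intToUtf8(q + 33L)

# --- dedup oracle: all-pairs key comparison, first copy kept ---------------
oracle_dedup_first <- function(seqs, interval = c(5L, 55L)) {
  key <- function(s) if (nchar(s) < interval[2]) s
                     else substr(s, interval[1], interval[2])
  keys <- vapply(seqs, key, character(1))
  survivors <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    dup <- FALSE
    for (j in seq_len(i - 1)) if (keys[j] == keys[i]) { dup <- TRUE; break }
    survivors[i] <- !dup
  }
  survivors
}

# --- subtraction oracle: exhaustive ungapped window scan -------------------
# TRUE iff some min_len-window of the read aligns to some reference window
# (either strand) with <= max_mm mismatches, scanning every diagonal.
oracle_background <- function(seq, refs, min_len = 60L, max_mm = 2L) {
  for (q in c(seq, rc_str(seq))) {
    qv <- strsplit(q, "")[[1]]
    lq <- length(qv)
    if (lq < min_len) return(FALSE)
    for (ref in refs) {
      rv <- strsplit(ref, "")[[1]]
      lr <- length(rv)
      for (shift in (-(lq - 1)):(lr - 1)) {
        i0 <- max(1L, 1L - shift)
        i1 <- min(lq, lr - shift)
        if (i1 - i0 + 1 < min_len) next
        idx <- i0:i1
        mm <- as.integer(qv[idx] != rv[idx + shift] |
                           !(qv[idx] %in% c("A", "C", "G", "T")))
        cs <- cumsum(mm)
        w <- min_len
        n <- length(mm)
        wins <- cs[w:n] - c(0L, cs)[(w:n) - w + 1L]
        if (any(wins <= max_mm)) return(TRUE)
      }
    }
  }
  FALSE
}

# --- translated-search oracle: best ungapped diagonal segment --------------
# Kadane's maximum-subarray over every diagonal of the peptide pair; stop
# codons break segments.  Returns the best raw score and its query interval
# (0-based inclusive).
oracle_best_segment <- function(qpep, spep, smat) {
  qv <- strsplit(qpep, "")[[1]]
  sv <- strsplit(spep, "")[[1]]
  lq <- length(qv)
  ls <- length(sv)
  best <- list(score = -Inf, qs = NA, qe = NA)
  for (d in (-(lq - 1)):(ls - 1)) {
    i0 <- max(1L, 1L - d)
    i1 <- min(lq, ls - d)
    if (i1 < i0) next
    run <- 0
    run_start <- i0
    for (i in i0:i1) {
      a <- qv[i]
      b <- sv[i + d]
      if (a == "*" || b == "*") {
        run <- 0
        run_start <- i + 1L
        next
      }
      sc <- smat[utf8ToInt(a) + 1L, utf8ToInt(b) + 1L]
      if (run <= 0) {
        run <- sc
        run_start <- i
      } else run <- run + sc
      if (run > best$score) {
        best <- list(score = run, qs = run_start - 1L, qe = i - 1L)
      }
    }
  }
  best
}

# --- motif oracle: regex evaluation at every offset ------------------------
# Builds regular expressions from a compiled pattern's tokens (optional
# positions expanded to consume 0 or 1 residues) and tests each offset with
# R's regex engine.
oracle_scan <- function(protein, pattern) {
  tok_rx <- function(tk) {
    switch(tk$type,
           ANY = ".",
           UNCHARGED = paste0("[", paste(tk$residues, collapse = ""), "]"),
           EXACT = paste0("[", paste(tk$residues, collapse = ""), "]"),
           OPTIONAL_ANY = NA_character_)
  }
  opt_idx <- which(vapply(pattern$tokens, function(t) t$type == "OPTIONAL_ANY",
                          logical(1)))
  variants <- list()
  combos <- if (length(opt_idx) == 0) list(logical(0)) else {
    g <- expand.grid(rep(list(c(FALSE, TRUE)), length(opt_idx)))
    lapply(seq_len(nrow(g)), function(r) as.logical(g[r, ]))
  }
  for (cb in combos) {
    rx <- character(0)
    oi <- 0
    for (tk in pattern$tokens) {
      if (tk$type == "OPTIONAL_ANY") {
        oi <- oi + 1
        if (cb[oi]) rx <- c(rx, ".")
        next
      }
      rx <- c(rx, tok_rx(tk))
    }
    variants[[length(variants) + 1]] <-
      list(rx = paste0("^", paste(rx, collapse = "")), n = length(rx),
           used = any(cb))
  }
  n <- nchar(protein)
  rows <- list()
  for (s in 0:(n - 1)) {
    tail <- substr(protein, s + 1, n)
    for (v in variants) {
      if (nchar(tail) < v$n) next
      if (grepl(v$rx, tail)) {
        rows[[length(rows) + 1]] <- data.frame(
          pattern_name = pattern$name, start = s,
          window = substr(tail, 1, v$n), used_optional = v$used,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(pattern_name = character(0), start = integer(0),
                      window = character(0), used_optional = logical(0)))
  unique(do.call(rbind, rows))
}

# --- affine-gap alignment oracle: exhaustive enumeration -------------------
# All global alignments of two short sequences, scored with substitution
# matrix + per-run gap cost (open + extend * length); returns the best score.
oracle_best_global_score <- function(a, b, smat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(av) && j > length(bv)) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, score + smat[av[i], bv[j]], "m")
    }
    if (i <= length(av)) {  # gap in b
      pen <- gap_extend + if (state == "gb") 0 else gap_open
      rec(i + 1, j, score - pen, "gb")
    }
    if (j <= length(bv)) {  # gap in a
      pen <- gap_extend + if (state == "ga") 0 else gap_open
      rec(i, j + 1, score - pen, "ga")
    }
    invisible(NULL)
  }
  rec(1, 1, 0, "m")
  best
}

# scatter n_mut substitutions over a peptide, never touching the same
# position twice, always changing the residue
mutate_positions <- function(pep, n_mut) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  v <- strsplit(pep, "")[[1]]
  pos <- sample.int(length(v), n_mut)
  for (p in pos) v[p] <- sample(setdiff(aa20, v[p]), 1)
  paste(v, collapse = "")
}
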