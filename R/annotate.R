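# Genome annotation: ORF finding on linear and circular sequences, the
# degenerate motif grammar with parvovirus NS1/VP1 and polyomavirus LT
# hallmark panels, and ICTV-style species demarcation.

# Uncharged residue class: D, E, K, R and H are treated as charged
# (histidine counted charged); everything else in the 20-letter alphabet is
# uncharged.  All hallmark instances validate under this set.
UNCHARGED_AA <- strsplit("ACFGILMNPQSTVWY", "")[[1]]

#' Compile a degenerate motif notation into a token pattern
#'
#' Grammar (left-to-right, single pass): lowercase `x` and uppercase `X`
#' match any residue; lowercase `u` matches an uncharged residue; `-`
#' matches any residue or none (optional); an uppercase letter matches
#' itself; `P/Q` (letter, slash, letter) collapses into one position
#' matching either residue, attached to the letter preceding the slash
#' (stackable, e.g. `D/ED/E` is two two-residue positions).
#'
#' @param notation Pattern string over `A-Z`, `x`, `u`, `-`, `/`.
#' @param name Optional pattern name (defaults to the notation).
#' @param uncharged Residue set used for `u`.
#' @return A `vs_motif_pattern`: `name`, `notation`, `tokens` (list of
#'   `list(type, residues)` with type `EXACT`, `ANY`, `UNCHARGED` or
#'   `OPTIONAL_ANY`).
#' @export
compile_motif <- function(notation, name = notation,
                          uncharged = UNCHARGED_AA) {
  chars <- strsplit(notation, "")[[1]]
  tokens <- list()
  i <- 1
  while (i <= length(chars)) {
    c <- chars[i]
    if (c == "x" || c == "X") {
      tokens[[length(tokens) + 1]] <- list(type = "ANY", residues = NULL)
      i <- i + 1
    } else if (c == "u") {
      tokens[[length(tokens) + 1]] <- list(type = "UNCHARGED",
                                           residues = uncharged)
      i <- i + 1
    } else if (c == "-") {
      tokens[[length(tokens) + 1]] <- list(type = "OPTIONAL_ANY",
                                           residues = NULL)
      i <- i + 1
    } else if (grepl("^[A-WYZ]$", c)) {  # uppercase residue (X handled above)
      res <- c
      i <- i + 1
      while (i <= length(chars) && chars[i] == "/") {
        if (i + 1 > length(chars) || !grepl("^[A-Z]$", chars[i + 1]))
          stop("dangling '/' at offset ", i, " in '", notation, "'")
        res <- c(res, chars[i + 1])
        i <- i + 2
      }
      tokens[[length(tokens) + 1]] <- list(type = "EXACT", residues = res)
    } else if (c == "/") {
      stop("dangling '/' at offset ", i, " in '", notation, "'")
    } else {
      stop("unrecognized character '", c, "' at offset ", i,
           " in '", notation, "'")
    }
  }
  if (!any(vapply(tokens, function(t) t$type != "OPTIONAL_ANY", logical(1))))
    stop("pattern '", notation, "' has no mandatory position")
  structure(list(name = name, notation = notation, tokens = tokens),
            class = "vs_motif_pattern")
}

token_matches <- function(token, residue) {
  switch(token$type,
         ANY = TRUE,
         UNCHARGED = residue %in% token$residues,
         EXACT = residue %in% token$residues,
         OPTIONAL_ANY = TRUE)
}

optional_combos <- function(tokens) {
  n_opt <- sum(vapply(tokens, function(t) t$type == "OPTIONAL_ANY", logical(1)))
  if (n_opt == 0) return(list(logical(0)))
  # every subset of optional positions consuming 0 or 1 residues
  g <- expand.grid(rep(list(c(FALSE, TRUE)), n_opt))
  lapply(seq_len(nrow(g)), function(r) as.logical(g[r, ]))
}

# try to match `pattern` at 0-based offset `start` of residue vector `aa`;
# returns consumed window lengths (integer vector: one entry per optional
# usage combination that matches)
match_at <- function(tokens, aa, start, combos = optional_combos(tokens)) {
  wins <- integer(0)
  used <- logical(0)
  for (cb in combos) {
    pos <- start
    oi <- 0
    ok <- TRUE
    for (tk in tokens) {
      if (tk$type == "OPTIONAL_ANY") {
        oi <- oi + 1
        if (!cb[oi]) next  # consumes nothing
      }
      if (pos + 1 > length(aa) || !token_matches(tk, aa[pos + 1])) {
        ok <- FALSE
        break
      }
      pos <- pos + 1
    }
    if (ok) {
      wins <- c(wins, pos - start)
      used <- c(used, any(cb))
    }
  }
  list(window = wins, used_optional = used)
}

#' Scan a protein for degenerate motif matches
#'
#' Every window matching a pattern is reported; optional positions are
#' tried both consuming zero and one residues, and both variants are
#' reported when both match.
#'
#' @param protein Residue string.
#' @param patterns A `vs_motif_pattern` or list of them.
#' @param protein_id Identifier recorded in the output.
#' @return data.frame: `pattern_name`, `protein_id`, `start` (0-based
#'   residue offset), `window` (matched substring), `used_optional`.
#' @export
scan_motifs <- function(protein, patterns, protein_id = "protein") {
  if (inherits(patterns, "vs_motif_pattern")) patterns <- list(patterns)
  aa <- strsplit(protein, "")[[1]]
  rows <- list()
  for (pat in patterns) {
    min_len <- sum(vapply(pat$tokens, function(t) t$type != "OPTIONAL_ANY",
                          logical(1)))
    if (length(aa) < min_len) next
    combos <- optional_combos(pat$tokens)
    for (s in 0:(length(aa) - min_len)) {
      m <- match_at(pat$tokens, aa, s, combos)
      if (length(m$window) == 0) next
      for (v in seq_along(m$window)) {
        rows[[length(rows) + 1]] <- data.frame(
          pattern_name = pat$name, protein_id = protein_id, start = s,
          window = paste(aa[(s + 1):(s + m$window[v])], collapse = ""),
          used_optional = m$used_optional[v], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(pattern_name = character(0), protein_id = character(0),
                      start = integer(0), window = character(0),
                      used_optional = logical(0)))
  unique(do.call(rbind, rows))
}

#' Find ORFs on both strands of a genome
#'
#' ATG-initiated, stop-terminated open reading frames.  Circular sequences
#' are scanned as a doubled string; ORFs wrapping the origin are reported
#' once with `wraps_origin = TRUE`, and ORFs longer than the genome are
#' rejected.
#'
#' @param genome Nucleotide string (or a `vs_genome`).
#' @param circular Genome topology (taken from a `vs_genome` if given).
#' @param min_orf_length Minimum peptide length in codons.
#' @return data.frame: `start`, `end` (0-based half-open forward-strand
#'   nucleotide coordinates; `end` includes the stop codon and may exceed
#'   the genome length when wrapping), `strand`, `wraps_origin`, `peptide`.
#' @export
find_orfs <- function(genome, circular = FALSE, min_orf_length = 100L) {
  if (inherits(genome, "vs_genome")) {
    circular <- genome$topology == "circular"
    genome <- genome$seq
  }
  L <- nchar(genome)
  scan_seq <- if (circular) paste0(genome, genome) else genome
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") scan_seq else revcomp(scan_seq)
    for (off in 0:2) {
      pep <- translate_frame(s, off)
      if (pep == "") next
      aa <- strsplit(pep, "")[[1]]
      stops <- c(0L, which(aa == "*"), length(aa) + 1L)
      for (si in seq_len(length(stops) - 1)) {
        if (stops[si + 1L] - stops[si] < 2L) next
        seg <- (stops[si] + 1L):(stops[si + 1L] - 1L)
        if (seg[1] > length(aa)) next
        m_at <- seg[which(aa[seg] == "M")]
        if (length(m_at) == 0) next
        m1 <- m_at[1]
        stop_at <- stops[si + 1L]
        has_stop <- stop_at <= length(aa)
        if (!has_stop) next  # stop-terminated ORFs only
        n_codons <- stop_at - m1  # peptide codons (stop excluded)
        if (n_codons < min_orf_length) next
        # codon m1 occupies scan-string positions off + 3*(m1-1) + 1 .. +3
        nt_start0 <- off + 3L * (m1 - 1L)
        nt_end0 <- off + 3L * stop_at  # includes stop codon
        if (nt_end0 - nt_start0 > L) next  # longer than the genome: reject
        if (strand == "-") {
          SL <- nchar(s)
          tmp <- nt_start0
          nt_start0 <- SL - nt_end0
          nt_end0 <- SL - tmp
        }
        wraps <- FALSE
        if (circular) {
          if (nt_start0 >= L) next  # duplicate copy from the doubled string
          wraps <- nt_end0 > L
        }
        rows[[length(rows) + 1]] <- data.frame(
          start = nt_start0, end = nt_end0, strand = strand,
          wraps_origin = wraps,
          peptide = paste(aa[m1:(stop_at - 1L)], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), wraps_origin = logical(0),
                      peptide = character(0)))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hallmark motif panels
#'
#' Three panels of degenerate patterns: the parvovirus NS1 replication
#' panel (Walker A `GxxxxGKT/S`, Walker B `uuuuD/ED/E`, rolling-circle
#' replication motifs `xuHuHuuux` and `uxxYux-Kxx`), the parvovirus VP1
#' capsid panel (phospholipase A2 catalytic `HD` with a downstream `D` and
#' the `YLGPG` calcium-binding loop, evaluated in the N-terminal third of
#' the ORF), and the polyomavirus large T panel (`HPDKGG` DnaJ box,
#' `LXCXE` Rb-binding, Walker A `G/AxxxxGKT/S`, and the `CXXC`, `CLVC`,
#' `CFSC` zinc-binding clusters).
#'
#' @return Named list of panels; each panel is a list with `genus`,
#'   `region` (`"full"` or `"n_third"`), and `patterns` (compiled).
#' @export
hallmark_panels <- function() {
  list(
    parvovirus_NS1 = list(
      genus = "parvovirus NS1", region = "full",
      patterns = list(
        walker_a = compile_motif("GxxxxGKT/S", "walker_a"),
        walker_b = compile_motif("uuuuD/ED/E", "walker_b"),
        rcr1 = compile_motif("xuHuHuuux", "rcr1"),
        rcr2 = compile_motif("uxxYux-Kxx", "rcr2"))),
    parvovirus_VP1 = list(
      genus = "parvovirus VP1", region = "n_third",
      patterns = list(
        pla2_hd = compile_motif("HD", "pla2_hd"),
        pla2_d = compile_motif("D", "pla2_d"),
        ca_loop = compile_motif("YLGPG", "ca_loop"))),
    polyomavirus_LT = list(
      genus = "polyomavirus LT", region = "full",
      patterns = list(
        dnaj = compile_motif("HPDKGG", "dnaj"),
        lxcxe = compile_motif("LXCXE", "lxcxe"),
        walker_a = compile_motif("G/AxxxxGKT/S", "walker_a"),
        zn_cxxc = compile_motif("CXXC", "zn_cxxc"),
        zn_clvc = compile_motif("CLVC", "zn_clvc"),
        zn_cfsc = compile_motif("CFSC", "zn_cfsc"))))
}

# PLA2 catalytic D must sit 20-60 residues downstream of the HD hit
PLA2_D_SPACING <- c(20L, 60L)

#' Evaluate hallmark panels over a set of ORFs
#'
#' Each panel is scanned against each ORF peptide (the VP1 panel only
#' against the N-terminal third).  The VP1 panel additionally requires the
#' catalytic `D` 20-60 residues downstream of the `HD` hit.  A verdict
#' "consistent with <genus>" is issued per ORF iff every pattern in a
#' panel hits.
#'
#' @param orfs data.frame from [find_orfs()] (or a `vs_genome`'s `orfs`
#'   truth table); needs a `peptide` column.  Row names or a `name` column
#'   identify ORFs.
#' @param panels Panels from [hallmark_panels()].
#' @return List: `hits` (data.frame: `orf`, `panel`, `pattern`, `n_hits`,
#'   `first_offset`), `verdicts` (data.frame: `orf`, `panel`, `genus`,
#'   `complete`).
#' @export
hallmark_report <- function(orfs, panels = hallmark_panels()) {
  ids <- if (!is.null(orfs$name)) orfs$name else sprintf("orf%02d", seq_len(nrow(orfs)))
  hit_rows <- list()
  verdict_rows <- list()
  for (i in seq_len(nrow(orfs))) {
    pep <- orfs$peptide[i]
    for (pn in names(panels)) {
      panel <- panels[[pn]]
      region <- if (panel$region == "n_third")
        substr(pep, 1, max(1, nchar(pep) %/% 3)) else pep
      per_pattern <- list()
      for (qn in names(panel$patterns)) {
        m <- scan_motifs(region, panel$patterns[[qn]], protein_id = ids[i])
        per_pattern[[qn]] <- m
        hit_rows[[length(hit_rows) + 1]] <- data.frame(
          orf = ids[i], panel = pn, pattern = qn, n_hits = nrow(m),
          first_offset = if (nrow(m) > 0) min(m$start) else NA_integer_,
          stringsAsFactors = FALSE)
      }
      complete <- all(vapply(per_pattern, nrow, integer(1)) > 0)
      if (pn == "parvovirus_VP1" && complete) {
        # spacing constraint: D 20-60 residues downstream of an HD hit
        hd <- per_pattern$pla2_hd$start
        dd <- per_pattern$pla2_d$start
        complete <- any(vapply(hd, function(h) {
          any(dd >= h + PLA2_D_SPACING[1] & dd <= h + PLA2_D_SPACING[2])
        }, logical(1)))
      }
      verdict_rows[[length(verdict_rows) + 1]] <- data.frame(
        orf = ids[i], panel = pn, genus = panel$genus, complete = complete,
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hit_rows)
  verdicts <- do.call(rbind, verdict_rows)
  verdicts$verdict <- ifelse(verdicts$complete,
                             paste("consistent with", verdicts$genus), "")
  list(hits = hits, verdicts = verdicts)
}

#' Demarcation parameters
#'
#' @param ns1_identity_threshold Percent identity below which (strictly)
#'   the query replication protein marks a new-species candidate.
#' @return A `vs_demarcation_params` list.
#' @export
demarcation_params <- function(ns1_identity_threshold = 85) {
  structure(list(ns1_identity_threshold = ns1_identity_threshold),
            class = "vs_demarcation_params")
}

#' ICTV-style species demarcation on the replication protein
#'
#' A genome is a new-species candidate iff the maximum pairwise identity of
#' its NS1-like protein to every reference is strictly below the threshold
#' (default 85%).
#'
#' @param query_ns1 Query residue string.
#' @param reference_ns1s Named character vector of reference residue
#'   strings.
#' @param params A [demarcation_params()].
#' @param mode Alignment mode passed to [align_pair()]; the full-length
#'   (global) identity is the demarcation default.
#' @return List: `max_identity` (percent), `closest_reference`,
#'   `is_new_species_candidate`, `identities` (named vector).
#' @export
species_demarcation <- function(query_ns1, reference_ns1s,
                                params = demarcation_params(),
                                mode = "global") {
  stopifnot(length(reference_ns1s) > 0)
  ids <- vapply(reference_ns1s, function(r) {
    align_pair(query_ns1, r, mode = mode)$percent_identity
  }, numeric(1))
  best <- which.max(ids)
  list(max_identity = unname(ids[best]),
       closest_reference = names(reference_ns1s)[best],
       is_new_species_candidate =
         unname(ids[best]) < params$ns1_identity_threshold,
       identities = ids)
}

#' Export ORFs and motif hits as GFF3
#'
#' ORFs wrapping the origin of a circular genome are written as two
#' segments sharing an ID.
#'
#' @param orfs data.frame from [find_orfs()] with a `name` column (added
#'   if missing).
#' @param genome_id Sequence identifier.
#' @param genome_length Sequence length.
#' @param path Output path.
#' @param motif_hits Optional data.frame of motif hits (from
#'   [hallmark_report()]'s `hits`, joined to ORFs) - written as
#'   `sequence_motif` children when given.
#' @return `path`, invisibly.
#' @export
write_orfs_gff3 <- function(orfs, genome_id, genome_length, path,
                            motif_hits = NULL) {
  if (is.null(orfs$name)) orfs$name <- sprintf("orf%02d", seq_len(nrow(orfs)))
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome_id, genome_length))
  for (i in seq_len(nrow(orfs))) {
    s1 <- orfs$start[i] + 1L
    e1 <- orfs$end[i]
    attr <- sprintf("ID=%s;Name=%s", orfs$name[i], orfs$name[i])
    if (isTRUE(orfs$wraps_origin[i]) && e1 > genome_length) {
      segs <- rbind(c(s1, genome_length), c(1L, e1 - genome_length))
      for (r in 1:2)
        lines <- c(lines, paste(genome_id, "viroscout", "CDS", segs[r, 1],
                                segs[r, 2], ".", orfs$strand[i], "0",
                                paste0(attr, ";part=", r), sep = "\t"))
    } else {
      lines <- c(lines, paste(genome_id, "viroscout", "CDS", s1, e1, ".",
                              orfs$strand[i], "0", attr, sep = "\t"))
    }
  }
  if (!is.null(motif_hits) && nrow(motif_hits) > 0) {
    for (i in seq_len(nrow(motif_hits))) {
      lines <- c(lines, paste(
        genome_id, "viroscout", "sequence_motif", ".", ".", ".", ".", ".",
        sprintf("Name=%s;Parent=%s;offset=%s", motif_hits$pattern[i],
                motif_hits$orf[i], motif_hits$first_offset[i]), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
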