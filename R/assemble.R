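# Ensemble assembly: multi-k de Bruijn unitigs, partitioned sub-assembly,
# greedy overlap-layout-consensus merging, circular-genome detection.

#' Assembly parameters
#'
#' @param k_values Odd k-mer sizes for the de Bruijn passes.
#' @param min_kmer_count k-mers observed fewer times are dropped.
#' @param n_partitions Number of random read partitions sub-assembled
#'   independently before pooling.
#' @param olc_min_overlap Minimum suffix/prefix overlap (bases) for merging.
#' @param olc_min_identity Minimum overlap identity (fraction).
#' @param min_contig_length Contigs shorter than this are dropped unless
#'   circular.
#' @param circular_min_terminal_repeat Minimum exact terminal repeat for
#'   circularity detection.
#' @return A `vs_assembly_params` list.
#' @export
assembly_params <- function(k_values = c(21L, 31L, 41L), min_kmer_count = 2L,
                            n_partitions = 4L, olc_min_overlap = 35L,
                            olc_min_identity = 0.98, min_contig_length = 200L,
                            circular_min_terminal_repeat = 20L) {
  stopifnot(all(k_values %% 2 == 1), n_partitions >= 1)
  structure(list(k_values = as.integer(k_values),
                 min_kmer_count = as.integer(min_kmer_count),
                 n_partitions = as.integer(n_partitions),
                 olc_min_overlap = as.integer(olc_min_overlap),
                 olc_min_identity = olc_min_identity,
                 min_contig_length = as.integer(min_contig_length),
                 circular_min_terminal_repeat = as.integer(circular_min_terminal_repeat)),
            class = "vs_assembly_params")
}

#' Build a de Bruijn graph from reads
#'
#' Nodes are (k-1)-mers and edges are observed k-mers; k-mers and their
#' reverse complements are collapsed onto the lexicographically smaller
#' (canonical) form, and edges observed fewer than `min_kmer_count` times
#' are removed.
#'
#' @param reads Reads table or character vector of sequences.
#' @param k Odd k-mer size (< read length).
#' @param min_kmer_count Minimum k-mer multiplicity.
#' @return A `vs_dbg` list with `kmer` (canonical strings), `count`, `k`.
#' @export
build_dbg <- function(reads, k, min_kmer_count = 2L) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  tab <- count_kmers_cpp(seqs, as.integer(k), as.integer(min_kmer_count))
  if (length(tab$kmer) == 0) message("no k-mers survive at k=", k)
  structure(list(kmer = tab$kmer, count = tab$count, k = as.integer(k)),
            class = "vs_dbg")
}

#' Extract unitigs from a de Bruijn graph
#'
#' Each unitig is a maximal non-branching path; a perfect cycle (a circular
#' template covered end to end) is emitted as a linear sequence carrying a
#' (k-1)-base terminal redundancy.  Short dead-end spurs hanging off a
#' branching node (tips, < 2k bases) are clipped in one pass.
#'
#' @param graph A [build_dbg()] result.
#' @param clip_tips Clip short tips before emitting unitigs.
#' @return data.frame: `seq`, `kmer_coverage` (mean k-mer multiplicity),
#'   `n_kmers`, `cycle`.
#' @export
dbg_contigs <- function(graph, clip_tips = TRUE) {
  stopifnot(inherits(graph, "vs_dbg"))
  if (length(graph$kmer) == 0)
    return(data.frame(seq = character(0), kmer_coverage = numeric(0),
                      n_kmers = integer(0), cycle = logical(0)))
  u <- unitigs_cpp(graph$kmer, graph$count, graph$k, clip_tips)
  data.frame(seq = u$seq, kmer_coverage = u$kmer_coverage,
             n_kmers = u$n_kmers, cycle = u$cycle, stringsAsFactors = FALSE)
}

#' Partitioned multi-k sub-assembly
#'
#' Reads are split at random (seeded) into `n_partitions` groups; each group
#' is assembled independently at every k in `k_values` and the resulting
#' unitigs are pooled with provenance tags.  With one partition and one k
#' this degenerates to [build_dbg()] + [dbg_contigs()].
#'
#' @param reads Reads table or character vector.
#' @param params An [assembly_params()].
#' @param seed Integer seed for the partitioning.
#' @return data.frame of pooled fragments: `seq`, `kmer_coverage`,
#'   `partition`, `k`.
#' @export
partitioned_assembly <- function(reads, params = assembly_params(), seed = 1L) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  part <- with_seed(seed, {
    sample(rep_len(seq_len(params$n_partitions), length(seqs)))
  })
  out <- list()
  for (p in seq_len(params$n_partitions)) {
    sub <- seqs[part == p]
    for (k in params$k_values) {
      g <- build_dbg(sub, k, params$min_kmer_count)
      u <- dbg_contigs(g)
      if (nrow(u) > 0) {
        u$partition <- p
        u$k <- k
        out[[length(out) + 1]] <- u[, c("seq", "kmer_coverage", "partition", "k")]
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(seq = character(0), kmer_coverage = numeric(0),
                      partition = integer(0), k = integer(0)))
  do.call(rbind, out)
}

# exact-seed candidate overlaps: suffix of `a` onto prefix of `b`.
# returns the longest qualifying overlap length (0 if none).
best_suffix_prefix_overlap <- function(a, b, min_overlap, min_identity) {
  la <- nchar(a)
  lb <- nchar(b)
  starts <- integer(0)
  for (probe_at in c(1L, 17L)) {
    if (lb < probe_at + 15L) break
    seed <- substr(b, probe_at, probe_at + 15L)
    m <- gregexpr(seed, a, fixed = TRUE)[[1]]
    if (m[1] != -1) starts <- c(starts, as.integer(m) - (probe_at - 1L))
  }
  starts <- unique(starts[starts >= 1])
  best <- 0L
  best_mm <- 0L
  for (p in starts) {
    L <- la - p + 1L
    if (L < min_overlap || L > lb || L >= la) next  # containment handled apart
    mm <- str_mismatches(substr(a, p, la), substr(b, 1, L))
    if (mm <= floor((1 - min_identity) * L) && L > best) {
      best <- L
      best_mm <- mm
    }
  }
  c(overlap = best, mismatches = best_mm)
}

# is `small` contained in `big` at >= min_identity? seed probes from the
# start and middle of `small` (both strands handled by the caller).
is_contained_in <- function(small, big, min_identity) {
  ls <- nchar(small)
  lb <- nchar(big)
  if (ls > lb) return(FALSE)
  for (probe_at in unique(c(1L, max(1L, ls %/% 2 - 8L)))) {
    if (ls < probe_at + 15L) next
    seed <- substr(small, probe_at, probe_at + 15L)
    m <- gregexpr(seed, big, fixed = TRUE)[[1]]
    if (m[1] == -1) next
    for (q in as.integer(m)) {
      off <- q - probe_at  # position of small[1] in big, 0-based
      if (off < 0 || off + ls > lb) next
      mm <- str_mismatches(small, substr(big, off + 1L, off + ls))
      if (mm <= floor((1 - min_identity) * ls)) return(TRUE)
    }
  }
  FALSE
}

#' Greedy overlap-layout-consensus merging
#'
#' Fragments fully contained in a longer fragment (at the identity
#' threshold, either strand) are removed; remaining fragments are merged
#' greedily, longest qualifying suffix/prefix overlap first (both strands
#' considered), with consensus over overlap columns taken from the longer
#' fragment on disagreement.  Deterministic given the input: fragments are
#' processed sorted by length, then sequence.
#'
#' @param fragments Character vector of sequences (contigs and/or reads),
#'   or a data.frame with a `seq` column.
#' @param params An [assembly_params()].
#' @return List: `contigs` (character vector of merged sequences),
#'   `n_merges`, `n_contained`.
#' @export
olc_merge <- function(fragments, params = assembly_params()) {
  seqs <- if (is.data.frame(fragments)) fragments$seq else fragments
  seqs <- unique(seqs[nchar(seqs) > 0])
  seqs <- seqs[order(-nchar(seqs), seqs)]
  min_id <- params$olc_min_identity
  min_ov <- params$olc_min_overlap
  # containment removal (scan short fragments against longer ones)
  contained <- logical(length(seqs))
  n_cont <- 0L
  if (length(seqs) > 1) {
    rcs_all <- revcomp(seqs)
    for (i in rev(seq_along(seqs))[-length(seqs)]) {
      for (j in seq_len(i - 1)) {
        if (contained[j]) next
        if (is_contained_in(seqs[i], seqs[j], min_id) ||
            is_contained_in(rcs_all[i], seqs[j], min_id)) {
          contained[i] <- TRUE
          n_cont <- n_cont + 1L
          break
        }
      }
    }
  }
  pool <- seqs[!contained]
  pool_rc <- as.list(if (length(pool)) revcomp(pool) else character(0))
  n_merges <- 0L
  # candidate overlaps for one ordered/orientated pair of pool members.
  # relative arrangements per ordered pair: a+b, a+rc(b), rc(a)+b
  # (rc(a)+rc(b) is the reverse complement of the b+a arrangement).
  pair_cands <- function(i, j) {
    out <- list()
    orients <- list(c("f", "f"), c("f", "r"), c("r", "f"))
    for (oo in orients) {
      a <- if (oo[1] == "f") pool[[i]] else pool_rc[[i]]
      b <- if (oo[2] == "f") pool[[j]] else pool_rc[[j]]
      ov <- best_suffix_prefix_overlap(a, b, min_ov, min_id)
      if (ov[["overlap"]] > 0)
        out[[length(out) + 1]] <- data.frame(
          i = i, j = j, ao = oo[1], bo = oo[2], L = ov[["overlap"]],
          stringsAsFactors = FALSE)
    }
    out
  }
  pool <- as.list(pool)
  cands <- list()
  for (i in seq_along(pool))
    for (j in seq_along(pool))
      if (i != j) cands <- c(cands, pair_cands(i, j))
  cands <- if (length(cands)) do.call(rbind, cands) else NULL
  active <- rep(TRUE, length(pool))
  repeat {
    if (is.null(cands) || nrow(cands) == 0) break
    live <- active[cands$i] & active[cands$j]
    cands <- cands[live, , drop = FALSE]
    if (nrow(cands) == 0) break
    ord <- order(-cands$L, cands$i, cands$j, cands$ao, cands$bo)
    top <- cands[ord[1], ]
    a <- if (top$ao == "f") pool[[top$i]] else pool_rc[[top$i]]
    b <- if (top$bo == "f") pool[[top$j]] else pool_rc[[top$j]]
    L <- top$L
    # consensus over the overlap: the longer fragment wins disagreements
    ov_cons <- if (nchar(a) >= nchar(b)) substr(a, nchar(a) - L + 1, nchar(a))
               else substr(b, 1, L)
    merged <- paste0(substr(a, 1, nchar(a) - L), ov_cons,
                     substr(b, L + 1, nchar(b)))
    active[c(top$i, top$j)] <- FALSE
    n_merges <- n_merges + 1L
    # fragments now contained in the merged sequence are absorbed
    merged_rc <- revcomp(merged)
    for (k in which(active)) {
      if (is_contained_in(pool[[k]], merged, min_id) ||
          is_contained_in(pool[[k]], merged_rc, min_id)) {
        active[k] <- FALSE
        n_cont <- n_cont + 1L
      }
    }
    pool[[length(pool) + 1]] <- merged
    pool_rc[[length(pool_rc) + 1]] <- merged_rc
    active <- c(active, TRUE)
    mi <- length(pool)
    new_cands <- list()
    for (k in which(active)) {
      if (k == mi) next
      new_cands <- c(new_cands, pair_cands(mi, k), pair_cands(k, mi))
    }
    if (length(new_cands))
      cands <- rbind(cands, do.call(rbind, new_cands))
  }
  list(contigs = unlist(pool[active]), n_merges = n_merges,
       n_contained = n_cont)
}

#' Detect circularity by terminal-repeat collapse
#'
#' If the contig's prefix and suffix share an exact repeat of at least
#' `min_terminal_repeat` bases, the repeat is collapsed once and the contig
#' flagged circular.  A repeat extending to half the contig (e.g. a
#' single-base or short-period sequence) is ambiguous and left unchanged.
#'
#' @param seq A contig sequence.
#' @param min_terminal_repeat Minimum exact repeat length.
#' @return List: `seq` (collapsed when circular), `circular`, `ambiguous`,
#'   `repeat_length`.
#' @export
detect_circularity <- function(seq, min_terminal_repeat = 20L) {
  len <- nchar(seq)
  max_l <- len %/% 2
  found <- 0L
  if (max_l >= min_terminal_repeat) {
    for (L in seq(max_l, min_terminal_repeat, by = -1)) {
      if (substr(seq, 1, L) == substr(seq, len - L + 1, len)) {
        found <- L
        break
      }
    }
  }
  if (found == 0L || max_l < min_terminal_repeat)
    return(list(seq = seq, circular = FALSE, ambiguous = FALSE,
                repeat_length = 0L))
  if (found == max_l)  # repeat runs into itself: degenerate, do not collapse
    return(list(seq = seq, circular = FALSE, ambiguous = TRUE,
                repeat_length = found))
  list(seq = substr(seq, 1, len - found), circular = TRUE, ambiguous = FALSE,
       repeat_length = found)
}

#' Assemble reads end to end
#'
#' Runs partitioned multi-k de Bruijn assembly, pools the unitigs together
#' with the reads, OLC-merges them, filters by length, detects circularity,
#' and maps reads back onto the final contigs for support and coverage.
#'
#' @param reads Reads table or character vector.
#' @param params An [assembly_params()].
#' @param seed Integer seed (partitioning).
#' @return List: `contigs` data.frame (`id`, `seq`, `length`, `circular`,
#'   `mean_coverage`, `n_support`), `support` (list of read indices per
#'   contig), `singlets` (indices of reads in no contig).
#' @export
assemble_reads <- function(reads, params = assembly_params(), seed = 1L) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  pooled <- partitioned_assembly(seqs, params, seed)
  frags <- c(pooled$seq, seqs)
  merged <- olc_merge(frags, params)
  contigs <- merged$contigs
  circ <- lapply(contigs, detect_circularity,
                 min_terminal_repeat = params$circular_min_terminal_repeat)
  cseq <- vapply(circ, `[[`, "", "seq")
  is_circ <- vapply(circ, `[[`, logical(1), "circular")
  keep <- nchar(cseq) >= params$min_contig_length | is_circ
  cseq <- cseq[keep]
  is_circ <- is_circ[keep]
  ord <- order(-nchar(cseq), cseq)
  cseq <- cseq[ord]
  is_circ <- is_circ[ord]
  # support: map each read onto the contigs (seeded containment, both strands)
  support <- vector("list", length(cseq))
  assigned <- rep.int(NA_integer_, length(seqs))
  seq_rcs <- if (length(seqs)) revcomp(seqs) else character(0)
  for (ci in seq_along(cseq)) {
    target <- if (is_circ[ci]) paste0(cseq[ci], cseq[ci]) else cseq[ci]
    for (ri in which(is.na(assigned))) {
      if (is_contained_in(seqs[ri], target, params$olc_min_identity) ||
          is_contained_in(seq_rcs[ri], target, params$olc_min_identity)) {
        assigned[ri] <- ci
      }
    }
    support[[ci]] <- which(assigned == ci)
  }
  # a "contig" backed by a single read is that read: demote it to a singlet
  demote <- lengths(support) < 2 & !is_circ
  for (ci in which(demote)) assigned[support[[ci]]] <- NA_integer_
  cseq <- cseq[!demote]
  is_circ <- is_circ[!demote]
  support <- support[!demote]
  assigned <- match(assigned, which(!demote))
  mean_cov <- vapply(seq_along(cseq), function(ci) {
    sum(nchar(seqs[support[[ci]]])) / nchar(cseq[ci])
  }, numeric(1))
  contigs_df <- data.frame(
    id = sprintf("contig%03d", seq_along(cseq)), seq = cseq,
    length = nchar(cseq), circular = is_circ, mean_coverage = mean_cov,
    n_support = lengths(support), stringsAsFactors = FALSE)
  list(contigs = contigs_df, support = support,
       singlets = which(is.na(assigned)))
}

#' Write contigs as FASTA with coverage and circularity in the description
#'
#' @param contigs Contig data.frame from [assemble_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  write_fasta(contigs[, c("id", "seq")], path,
              desc = sprintf("length=%d coverage=%.1f topology=%s",
                             contigs$length, contigs$mean_coverage,
                             ifelse(contigs$circular, "circular", "linear")))
  invisible(path)
}
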