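# Read preprocessing: positional-key deduplication, Phred tail trimming,
# adaptor clipping, and host/bacterial subtraction by ungapped
# seed-and-extend alignment.

#' Preprocessing parameters
#'
#' @param dup_key_interval 1-based inclusive positions of the deduplication
#'   key (default positions 5..55 from the 5' end).
#' @param qual_threshold Phred threshold for 3' tail trimming.
#' @param adaptors Character vector of adaptor base strings.
#' @param min_read_length_after_trim Reads shorter than this after trimming
#'   are discarded.
#' @return A `vs_preprocess_params` list.
#' @export
preprocess_params <- function(dup_key_interval = c(5L, 55L),
                              qual_threshold = 20L,
                              adaptors = "CTGTCTCTTATACACATCTCCGAGCCCACGAGA",
                              min_read_length_after_trim = 50L) {
  stopifnot(length(dup_key_interval) == 2, dup_key_interval[1] >= 1,
            dup_key_interval[2] >= dup_key_interval[1])
  structure(list(dup_key_interval = as.integer(dup_key_interval),
                 qual_threshold = as.integer(qual_threshold),
                 adaptors = adaptors,
                 min_read_length_after_trim = as.integer(min_read_length_after_trim)),
            class = "vs_preprocess_params")
}

#' Subtraction parameters
#'
#' A read is background if it has an ungapped alignment of at least
#' `min_aligned_length` consecutive bases to a reference (either strand)
#' with at most `max_mismatches` mismatches and no gaps.
#'
#' @param min_aligned_length Minimum ungapped aligned segment (bases).
#' @param max_mismatches Maximum mismatches within the segment.
#' @param seed_length Exact seed length used before extension; must not
#'   exceed `floor((min_aligned_length - max_mismatches) / (max_mismatches
#'   + 1))` for the seed-and-extend search to be equivalent to the
#'   exhaustive window scan (the default 20 is exactly that bound for
#'   60 bases / 2 mismatches).
#' @return A `vs_subtraction_params` list.
#' @export
subtraction_params <- function(min_aligned_length = 60L, max_mismatches = 2L,
                               seed_length = 20L) {
  stopifnot(max_mismatches >= 0, seed_length <= min_aligned_length)
  structure(list(min_aligned_length = as.integer(min_aligned_length),
                 max_mismatches = as.integer(max_mismatches),
                 seed_length = as.integer(seed_length)),
            class = "vs_subtraction_params")
}

dedup_key <- function(seq, interval) {
  key <- substr(seq, interval[1], interval[2])
  short <- nchar(seq) < interval[2]
  key[short] <- seq[short]  # short reads are keyed on their full sequence
  key
}

#' Remove positional-key duplicates
#'
#' Reads are duplicates if their bases over the key interval (default
#' positions 5 to 55 from the 5' end) are identical; one copy of each
#' duplicate group is kept.  Grouping is exact string equality (N matches
#' only N); reads shorter than the key interval are keyed on their full
#' sequence.
#'
#' @param reads Reads table (`id`, `seq`, `qual`).
#' @param params A [preprocess_params()].
#' @param seed Seed for the random-survivor mode.
#' @param keep `"first"` keeps the first-seen read of each group
#'   (reproducible default); `"random"` keeps a seeded random copy.
#' @return List: `reads` (survivors, input order preserved), `removed`
#'   (count).
#' @export
dedup <- function(reads, params = preprocess_params(), seed = 1L,
                  keep = c("first", "random")) {
  keep <- match.arg(keep)
  if (nrow(reads) == 0) return(list(reads = reads, removed = 0L))
  key <- dedup_key(reads$seq, params$dup_key_interval)
  if (keep == "first") {
    sel <- !duplicated(key)
  } else {
    sel <- logical(nrow(reads))
    groups <- split(seq_len(nrow(reads)), key)
    with_seed(seed, {
      for (g in groups) sel[g[sample.int(length(g), 1)]] <- TRUE
    })
  }
  list(reads = reads[sel, , drop = FALSE], removed = sum(!sel))
}

#' Trim low-quality 3' tails
#'
#' Scanning from the 3' end, bases are removed while their quality is below
#' the threshold, stopping at the first base with quality at or above it;
#' internal low-quality bases are retained.  Qualities are trimmed in
#' lockstep.  Reads trimmed to zero length are kept in the table but
#' flagged for discard via a zero-length sequence.
#'
#' @param reads Reads table.
#' @param threshold Phred threshold (default 20).
#' @return Reads table with trimmed `seq`/`qual`.
#' @export
trim_quality <- function(reads, threshold = 20L) {
  if (nrow(reads) == 0) return(reads)
  lens <- nchar(reads$qual)
  big <- utf8ToInt(paste(reads$qual, collapse = "")) - 33L
  ok <- big >= threshold
  grp <- rep.int(seq_len(nrow(reads)), lens)
  keep_to <- integer(nrow(reads))  # 0 = discard everything
  hit <- which(ok)
  if (length(hit) > 0) {
    ghit <- grp[hit]
    last <- !duplicated(ghit, fromLast = TRUE)
    offs <- c(0L, cumsum(lens))[ghit[last]]
    keep_to[ghit[last]] <- hit[last] - offs
  }
  reads$seq <- substr(reads$seq, 1L, keep_to)
  reads$qual <- substr(reads$qual, 1L, keep_to)
  reads
}

#' Clip adaptor run-through from read 3' ends
#'
#' The earliest read position where either (a) the remaining read suffix
#' exactly equals a prefix of an adaptor of at least 8 bases, or (b) the
#' full adaptor matches with at most 1 mismatch, is clipped to the read
#' end.  Shorter matches (below 8 exact bases) are not treated as evidence.
#'
#' @param reads Reads table.
#' @param adaptors Character vector of adaptor base strings.
#' @return Reads table with clipped `seq`/`qual`.
#' @export
trim_adaptor <- function(reads, adaptors) {
  stopifnot(length(adaptors) > 0, all(nchar(adaptors) >= 8))
  if (nrow(reads) == 0) return(reads)
  nonempty <- which(nchar(reads$seq) >= 8)
  if (length(nonempty) == 0) return(reads)
  sv <- Biostrings::DNAStringSet(reads$seq[nonempty])
  clip_at <- rep.int(NA_integer_, nrow(reads))
  for (a in adaptors) {
    la <- nchar(a)
    cand <- vector("list", length(nonempty))
    m8 <- Biostrings::vmatchPattern(substr(a, 1, 8), sv)
    m1 <- Biostrings::vmatchPattern(a, sv, max.mismatch = 1)
    st8 <- Biostrings::startIndex(m8)
    st1 <- Biostrings::startIndex(m1)
    for (k in seq_along(nonempty)) {
      starts <- sort(unique(c(st8[[k]], st1[[k]])))
      if (length(starts) == 0) next
      i <- nonempty[k]
      len <- nchar(reads$seq[i])
      for (p in starts) {
        L <- len - p + 1
        if (L < 8) next
        hit <- if (L <= la) {
          substr(reads$seq[i], p, len) == substr(a, 1, L)
        } else {
          str_mismatches(substr(reads$seq[i], p, p + la - 1), a) <= 1
        }
        if (hit) {
          clip_at[i] <- min(clip_at[i], p, na.rm = TRUE)
          break
        }
      }
    }
  }
  sel <- !is.na(clip_at)
  reads$seq[sel] <- substr(reads$seq[sel], 1L, clip_at[sel] - 1L)
  reads$qual[sel] <- substr(reads$qual[sel], 1L, clip_at[sel] - 1L)
  reads
}

#' Build a background-subtraction index
#'
#' @param references Named character vector of reference sequences, or a
#'   data.frame with `id` and `seq` (for example from [read_fasta()]).
#' @param params A [subtraction_params()].
#' @return A `vs_subtraction_index`.
#' @export
build_subtraction_index <- function(references, params = subtraction_params()) {
  if (is.data.frame(references)) {
    refs <- setNames(references$seq, references$id)
  } else refs <- references
  stopifnot(length(refs) > 0)
  bad <- vapply(refs, function(s) {
    mean(strsplit(s, "")[[1]] %in% DNA_BASES) < 0.5
  }, logical(1))
  if (any(bad))
    warning("reference(s) with >50% non-ACGT bases: ",
            paste(names(refs)[bad], collapse = ", "))
  structure(list(refs = refs, params = params),
            class = "vs_subtraction_index")
}

#' Classify reads as background (host/bacterial) or not
#'
#' A read is background if an ungapped alignment of at least
#' `min_aligned_length` consecutive read bases to a reference (either
#' strand) exists with at most `max_mismatches` mismatches and no gaps,
#' found by exact seeding and diagonal window scanning.  N bases count as
#' mismatches.  Reads shorter than `min_aligned_length` are never
#' background.
#'
#' @param reads Reads table (or character vector of sequences).
#' @param index A [build_subtraction_index()].
#' @return data.frame: `background` (logical), `ref`, `ref_start`, `strand`
#'   of the first qualifying window (NA when not background).
#' @export
is_background <- function(reads, index) {
  stopifnot(inherits(index, "vs_subtraction_index"))
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  p <- index$params
  res <- subtract_flags_cpp(seqs, unname(index$refs), p$seed_length,
                            p$min_aligned_length, p$max_mismatches)
  data.frame(background = res$background,
             ref = names(index$refs)[res$ref],
             ref_start = res$ref_start, strand = res$strand,
             stringsAsFactors = FALSE)
}

#' Remove background reads
#'
#' @param reads Reads table.
#' @param index A [build_subtraction_index()].
#' @return List: `reads` (retained, order preserved), `removed` (count),
#'   `flags` (the [is_background()] table).
#' @export
subtract <- function(reads, index) {
  flags <- is_background(reads, index)
  list(reads = reads[!flags$background, , drop = FALSE],
       removed = sum(flags$background), flags = flags)
}

#' Run the full preprocessing stage
#'
#' Stages run in fixed order: deduplication, quality tail trimming, adaptor
#' clipping, length filtering, background subtraction.  The read count is
#' monotonically non-increasing across stages.
#'
#' @param reads Reads table.
#' @param params A [preprocess_params()].
#' @param index Optional [build_subtraction_index()]; `NULL` skips
#'   subtraction.
#' @param seed Seed (random-survivor deduplication mode only).
#' @param dedup_keep Passed to [dedup()].
#' @return List: `reads` (survivors), `report` (per-stage counts
#'   data.frame), `subtraction_flags`.
#' @export
preprocess <- function(reads, params = preprocess_params(), index = NULL,
                       seed = 1L, dedup_keep = "first") {
  report <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0), removed = integer(0))
  log_stage <- function(stage, n_in, n_out) {
    report <<- rbind(report, data.frame(stage = stage, n_in = n_in,
                                        n_out = n_out, removed = n_in - n_out))
  }
  n0 <- nrow(reads)
  dd <- dedup(reads, params, seed = seed, keep = dedup_keep)
  log_stage("dedup", n0, nrow(dd$reads))
  tq <- trim_quality(dd$reads, params$qual_threshold)
  log_stage("quality_trim", nrow(dd$reads), nrow(tq))
  ta <- trim_adaptor(tq, params$adaptors)
  log_stage("adaptor_trim", nrow(tq), nrow(ta))
  keep <- nchar(ta$seq) >= params$min_read_length_after_trim
  lf <- ta[keep, , drop = FALSE]
  log_stage("length_filter", nrow(ta), nrow(lf))
  flags <- NULL
  out <- lf
  if (!is.null(index)) {
    sb <- subtract(lf, index)
    flags <- sb$flags
    out <- sb$reads
    log_stage("subtraction", nrow(lf), nrow(out))
  }
  list(reads = out, report = report, subtraction_flags = flags)
}
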