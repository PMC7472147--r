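# Translated homology classification: six-frame translation, seeded ungapped
# search with Karlin-Altschul E-values, candidate selection against the viral
# database, best-hit virus/non-virus arbitration, and the virome report.

#' Scoring model for the translated search
#'
#' Ungapped BLOSUM62 scoring with the standard ungapped Karlin-Altschul
#' parameters; E = K * m * n * exp(-lambda * S) with m the translated query
#' length and n the total database residue count (no length correction).
#'
#' @param lambda Nats per raw-score unit (ungapped BLOSUM62 default 0.3176).
#' @param K Karlin-Altschul K (ungapped BLOSUM62 default 0.134).
#' @param matrix Substitution matrix; defaults to BLOSUM62 from Biostrings.
#' @return A `vs_scoring_model` list (includes a 128x128 char-indexed
#'   integer lookup for the C++ extension).
#' @export
scoring_model <- function(lambda = 0.3176, K = 0.134, matrix = NULL) {
  stopifnot(lambda > 0, K > 0)
  if (is.null(matrix)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  lut <- matrix(-4L, 128, 128)
  rn <- rownames(matrix)
  ci <- utf8ToInt(paste(rn, collapse = "")) + 1L  # 1-based char codes
  for (i in seq_along(rn)) lut[ci[i], ci] <- as.integer(matrix[i, ])
  structure(list(lambda = lambda, K = K, matrix = matrix, lut = lut),
            class = "vs_scoring_model")
}

#' Classification parameters
#'
#' @param candidate_evalue_cutoff Queries whose best viral-database hit has
#'   an E-value below this are candidates (default 0.01).
#' @param report_evalue_cutoff Taxa whose best E-value is below this are
#'   flagged as mammalian-virus detections (default 1e-10).
#' @param seed_word_length Exact peptide word length for seeding.
#' @param xdrop X-drop threshold (matrix units) for ungapped extension.
#' @param rank_evalue_cutoff Hits above this E-value are ignored when
#'   ranking arbitration hits (default 10).
#' @return A `vs_classify_params` list.
#' @export
classify_params <- function(candidate_evalue_cutoff = 0.01,
                            report_evalue_cutoff = 1e-10,
                            seed_word_length = 4L, xdrop = 15L,
                            rank_evalue_cutoff = 10) {
  structure(list(candidate_evalue_cutoff = candidate_evalue_cutoff,
                 report_evalue_cutoff = report_evalue_cutoff,
                 seed_word_length = as.integer(seed_word_length),
                 xdrop = as.integer(xdrop),
                 rank_evalue_cutoff = rank_evalue_cutoff),
            class = "vs_classify_params")
}

.codon_cache <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(.codon_cache$tab))
    .codon_cache$tab <- Biostrings::GENETIC_CODE  # includes stops as '*'
  .codon_cache$tab
}

translate_frame <- function(seq, offset) {
  n <- nchar(seq)
  usable <- n - offset
  n_cod <- usable %/% 3
  if (n_cod < 1) return("")
  starts <- offset + 1 + 3 * (seq_len(n_cod) - 1)
  cods <- substring(seq, starts, starts + 2)
  tab <- codon_table()
  aa <- tab[cods]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Six-frame translation
#'
#' Frames +1..+3 read the forward strand at offsets 0..2; frames -1..-3
#' read the reverse complement likewise.  Standard genetic code, stop
#' codons emitted as `*`, trailing partial codons dropped, codons with
#' ambiguous bases emitted as `X`.
#'
#' @param seq A nucleotide string.
#' @return Named character vector of six peptides (`+1`,`+2`,`+3`,
#'   `-1`,`-2`,`-3`).
#' @export
six_frame_translate <- function(seq) {
  rc <- revcomp(seq)
  out <- c(vapply(0:2, function(o) translate_frame(seq, o), character(1)),
           vapply(0:2, function(o) translate_frame(rc, o), character(1)))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Read a labeled protein database from FASTA
#'
#' Description lines carry `label=virus|nonvirus` and `taxon=<name>` fields
#' (spaces in taxa written as underscores).
#'
#' @param path FASTA path.
#' @return data.frame: `id`, `seq`, `label`, `taxon`.
#' @export
read_protein_db <- function(path) {
  db <- read_protein_fasta(path)
  stopifnot(all(c("label", "taxon") %in% names(db)))
  db$taxon <- gsub("_", " ", db$taxon)
  db
}

#' Write a labeled protein database as FASTA
#'
#' @param db data.frame with `id`, `seq`, `label`, `taxon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_db <- function(db, path) {
  write_fasta(db[, c("id", "seq")], path,
              desc = sprintf("label=%s taxon=%s", db$label,
                             gsub(" ", "_", db$taxon)),
              protein = TRUE)
  invisible(path)
}

#' Translated seeded search of nucleotide queries against a protein database
#'
#' All six reading frames are seeded with exact `seed_word_length`-residue
#' words and extended without gaps under an X-drop rule; stop codons
#' terminate extension.  Raw scores convert to bit scores as
#' `(lambda*S - ln K) / ln 2` and E-values as `K*m*n*exp(-lambda*S)` with
#' `m` the frame peptide length and `n` the database residue count.
#'
#' @param queries Character vector of nucleotide sequences (named, or a
#'   data.frame with `id`, `seq`).
#' @param db Protein database data.frame (`id`, `seq`, `label`, `taxon`).
#' @param model A [scoring_model()].
#' @param params A [classify_params()].
#' @param max_evalue Keep hits with E-value below this (defaults to the
#'   candidate cutoff).
#' @return data.frame of hits sorted by E-value: `query_id`, `frame`,
#'   `query_start`, `query_end` (0-based half-open forward-strand
#'   nucleotide coordinates), `subject_id`, `subject_start`, `subject_end`
#'   (0-based half-open residue coordinates), `raw_score`, `bit_score`,
#'   `evalue`, `percent_identity`, `align_length`, `label`, `taxon`.
#' @export
translated_search <- function(queries, db, model = scoring_model(),
                              params = classify_params(),
                              max_evalue = params$candidate_evalue_cutoff) {
  if (is.data.frame(queries)) {
    qids <- queries$id
    qseqs <- queries$seq
  } else {
    qids <- if (!is.null(names(queries))) names(queries)
            else sprintf("query%04d", seq_along(queries))
    qseqs <- unname(queries)
  }
  empty <- data.frame(query_id = character(0), frame = character(0),
                      query_start = integer(0), query_end = integer(0),
                      subject_id = character(0), subject_start = integer(0),
                      subject_end = integer(0), raw_score = integer(0),
                      bit_score = numeric(0), evalue = numeric(0),
                      percent_identity = numeric(0), align_length = integer(0),
                      label = character(0), taxon = character(0))
  if (length(qseqs) == 0 || nrow(db) == 0) return(empty)
  # flatten frames
  frames <- lapply(qseqs, six_frame_translate)
  qpep <- unlist(frames, use.names = FALSE)
  pep_query <- rep(seq_along(qseqs), each = 6)
  pep_frame <- rep(c("+1", "+2", "+3", "-1", "-2", "-3"), length(qseqs))
  keep <- nchar(qpep) >= params$seed_word_length
  if (!any(keep)) return(empty)
  hits <- seed_extend_cpp(qpep[keep], db$seq, model$lut,
                          params$seed_word_length, params$xdrop)
  if (nrow(hits) == 0) return(empty)
  n_db <- sum(nchar(db$seq))
  qmap <- which(keep)
  pidx <- qmap[hits$qidx]
  m <- nchar(qpep)[pidx]
  S <- hits$score
  evalue <- model$K * m * n_db * exp(-model$lambda * S)
  bit <- (model$lambda * S - log(model$K)) / log(2)
  sel <- evalue < max_evalue
  if (!any(sel)) return(empty)
  hits <- hits[sel, , drop = FALSE]
  pidx <- pidx[sel]
  evalue <- evalue[sel]
  bit <- bit[sel]
  qi <- pep_query[pidx]
  fr <- pep_frame[pidx]
  qlen_nt <- nchar(qseqs)[qi]
  off <- as.integer(substr(fr, 2, 2)) - 1L
  # peptide residue interval -> nucleotide interval (0-based half-open)
  nt_s <- off + 3L * hits$qs
  nt_e <- off + 3L * (hits$qe + 1L)
  minus <- substr(fr, 1, 1) == "-"
  qs_fwd <- ifelse(minus, qlen_nt - nt_e, nt_s)
  qe_fwd <- ifelse(minus, qlen_nt - nt_s, nt_e)
  # percent identity over aligned columns
  alen <- hits$qe - hits$qs + 1L
  ident <- vapply(seq_len(nrow(hits)), function(r) {
    a <- substr(qpep[pidx[r]], hits$qs[r] + 1L, hits$qe[r] + 1L)
    b <- substr(db$seq[hits$sidx[r]], hits$ss[r] + 1L, hits$se[r] + 1L)
    100 * (1 - str_mismatches(a, b) / nchar(a))
  }, numeric(1))
  out <- data.frame(
    query_id = qids[qi], frame = fr,
    query_start = as.integer(qs_fwd), query_end = as.integer(qe_fwd),
    subject_id = db$id[hits$sidx],
    subject_start = hits$ss, subject_end = hits$se + 1L,
    raw_score = hits$score, bit_score = bit, evalue = evalue,
    percent_identity = ident, align_length = alen,
    label = db$label[hits$sidx], taxon = db$taxon[hits$sidx],
    stringsAsFactors = FALSE)
  out[order(out$evalue, -out$raw_score, out$subject_id), , drop = FALSE]
}

#' Select viral candidates
#'
#' A query is a candidate iff its best hit against the viral database has
#' an E-value below the candidate cutoff.
#'
#' @param queries Named character vector or data.frame of nucleotide
#'   queries.
#' @param viral_db Protein database restricted to `label == "virus"`.
#' @param model,params See [translated_search()].
#' @return data.frame, one row per candidate: `query_id` and its best viral
#'   hit columns.
#' @export
viral_candidates <- function(queries, viral_db, model = scoring_model(),
                             params = classify_params()) {
  viral_db <- viral_db[viral_db$label == "virus", , drop = FALSE]
  hits <- translated_search(queries, viral_db, model, params,
                            max_evalue = params$candidate_evalue_cutoff)
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Best-hit virus/non-virus arbitration
#'
#' Each candidate is re-searched against the combined (virus + non-virus)
#' database; its hits are ranked by E-value ascending, ties by raw score
#' descending, residual ties with non-virus preferred (conservative), then
#' by record id.  The candidate is retained iff the top-ranked hit is
#' labeled virus.
#'
#' @param candidates Result of [viral_candidates()].
#' @param queries The query sequences (same objects searched before).
#' @param combined_db Full labeled database.
#' @param model,params See [translated_search()].
#' @return List: `retained` (data.frame of retained calls with their best
#'   combined hit), `removed_ids`, `all_hits`.
#' @export
nr_filter <- function(candidates, queries, combined_db,
                      model = scoring_model(), params = classify_params()) {
  if (is.data.frame(queries)) {
    qtab <- queries
  } else {
    qtab <- data.frame(id = names(queries), seq = unname(queries),
                       stringsAsFactors = FALSE)
  }
  qtab <- qtab[qtab$id %in% candidates$query_id, , drop = FALSE]
  hits <- translated_search(qtab, combined_db, model, params,
                            max_evalue = params$rank_evalue_cutoff)
  if (nrow(hits) == 0)
    return(list(retained = hits, removed_ids = candidates$query_id,
                all_hits = hits))
  o <- order(hits$query_id, hits$evalue, -hits$raw_score,
             hits$label != "nonvirus",  # nonvirus first on residual ties
             hits$subject_id)
  hits <- hits[o, , drop = FALSE]
  top <- hits[!duplicated(hits$query_id), , drop = FALSE]
  retained <- top[top$label == "virus", , drop = FALSE]
  removed <- setdiff(candidates$query_id, retained$query_id)
  list(retained = retained, removed_ids = removed, all_hits = hits)
}

#' Summarize retained viral calls into a virome report
#'
#' Groups retained calls by database taxon; a taxon is flagged as a
#' mammalian-virus detection iff its best E-value is below the report
#' cutoff (default 1e-10).
#'
#' @param retained Retained calls from [nr_filter()] (their best hits).
#' @param params A [classify_params()].
#' @param query_type Optional named character vector mapping query ids to
#'   `"contig"` or `"read"`.
#' @return data.frame ordered by best E-value: `taxon`, `n_queries`,
#'   `n_contigs`, `n_reads`, `total_aligned_bases`, `best_evalue`,
#'   `detection`.
#' @export
summarize_virome <- function(retained, params = classify_params(),
                             query_type = NULL) {
  if (nrow(retained) == 0)
    return(data.frame(taxon = character(0), n_queries = integer(0),
                      n_contigs = integer(0), n_reads = integer(0),
                      total_aligned_bases = integer(0),
                      best_evalue = numeric(0), detection = logical(0)))
  type <- if (is.null(query_type)) rep("contig", nrow(retained))
          else unname(query_type[retained$query_id])
  agg <- lapply(split(seq_len(nrow(retained)), retained$taxon), function(ix) {
    data.frame(taxon = retained$taxon[ix[1]], n_queries = length(ix),
               n_contigs = sum(type[ix] == "contig"),
               n_reads = sum(type[ix] == "read"),
               total_aligned_bases = sum(retained$query_end[ix] -
                                           retained$query_start[ix]),
               best_evalue = min(retained$evalue[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out$detection <- out$best_evalue < params$report_evalue_cutoff
  out <- out[order(out$best_evalue, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write hits in BLAST-style 12-column tabular form (plus label columns)
#'
#' @param hits Hits data.frame from [translated_search()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  tab <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = sprintf("%.2f", hits$percent_identity),
    length = hits$align_length,
    mismatch = round(hits$align_length * (1 - hits$percent_identity / 100)),
    gapopen = 0L,
    qstart = hits$query_start + 1L, qend = hits$query_end,
    sstart = hits$subject_start + 1L, send = hits$subject_end,
    evalue = format(hits$evalue, digits = 3),
    bitscore = sprintf("%.1f", hits$bit_score),
    frame = hits$frame, label = hits$label, taxon = hits$taxon)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
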