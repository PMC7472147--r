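# Synthetic metagenome generator: seeded genomes with planted ORFs and
# hallmark motifs, community specs, and paired-end read simulation with the
# library artefacts (duplicates, quality decay, adaptor run-through) that the
# preprocessing stage is designed to remove.

#' Describe a synthetic genome
#'
#' A genome spec fixes the label, length, topology, GC content, the ORF
#' layout, and the hallmark motif instances planted inside each ORF.
#' ORF coordinates are 1-based and inclusive; on a circular genome `end`
#' may exceed `length`, meaning the ORF wraps the origin.  Each ORF span
#' must be a multiple of 3 and includes its stop codon, so an ORF of
#' `3 * (n + 1)` bases encodes an `n`-residue peptide.
#'
#' @param label Genome label (also its FASTA id).
#' @param length Genome length in bases.
#' @param topology `"linear"` or `"circular"`.
#' @param orfs `NULL`, or a data.frame with columns `name`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`).
#' @param motifs `NULL`, or a data.frame with columns `orf`, `name`,
#'   `instance` (residue string planted verbatim), `offset` (0-based residue
#'   offset within the ORF peptide).
#' @param gc GC fraction of the non-coding background, in `[0, 1]`.
#' @return A `vs_genome_spec` list.
#' @export
genome_spec <- function(label, length, topology = c("linear", "circular"),
                        orfs = NULL, motifs = NULL, gc = 0.4) {
  topology <- match.arg(topology)
  stopifnot(length > 0, gc >= 0, gc <= 1)
  if (!is.null(orfs)) {
    stopifnot(all(c("name", "start", "end", "strand") %in% names(orfs)))
    span <- orfs$end - orfs$start + 1
    if (any(span %% 3 != 0)) stop("ORF spans must be multiples of 3")
    if (any(span > length)) stop("ORF longer than genome")
    if (topology == "linear" && any(orfs$end > length))
      stop("linear ORFs must fit within the genome")
    n_aa <- span / 3 - 1
    if (!is.null(motifs)) {
      stopifnot(all(c("orf", "name", "instance", "offset") %in% names(motifs)))
      if (!all(motifs$orf %in% orfs$name)) stop("motif assigned to unknown ORF")
      for (i in seq_len(nrow(motifs))) {
        na <- n_aa[match(motifs$orf[i], orfs$name)]
        w <- nchar(motifs$instance[i])
        if (w > na)
          stop("infeasible layout: motif '", motifs$name[i],
               "' longer than ORF '", motifs$orf[i], "'")
        if (motifs$offset[i] < 1 || motifs$offset[i] + w > na)
          stop("motif '", motifs$name[i], "' does not fit inside ORF '",
               motifs$orf[i], "' at offset ", motifs$offset[i])
      }
    }
  } else if (!is.null(motifs) && nrow(motifs) > 0) {
    stop("motifs given without ORFs")
  }
  structure(list(label = label, length = as.integer(length),
                 topology = topology, orfs = orfs, motifs = motifs, gc = gc),
            class = "vs_genome_spec")
}

# uniform random codon for each residue (no stops); vectorised over residues
reverse_translate <- function(residues) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  paste(vapply(residues, function(a) {
    cods <- by_aa[[a]]
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

#' Build a genome sequence and its truth annotation from a spec
#'
#' ORF peptides are drawn at random (always starting with M, never
#' containing a stop), hallmark motif instances are overwritten verbatim at
#' their requested offsets, and the peptides are reverse-translated with
#' uniform codon choice, so every ORF translates without internal stops and
#' contains its motifs exactly.  Non-coding background is random sequence at
#' the requested GC.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; the same (spec, seed) always yields the same
#'   sequence.
#' @return A `vs_genome` list: `id`, `seq`, `topology`, `orfs` (data.frame
#'   with 0-based half-open forward-strand coordinates, `wraps_origin`,
#'   `peptide`), `motifs` (residue offsets of planted instances).
#' @export
make_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "vs_genome_spec"))
  with_seed(seed, {
    L <- spec$length
    chars <- sample(DNA_BASES, L, replace = TRUE,
                    prob = c((1 - spec$gc) / 2, spec$gc / 2,
                             spec$gc / 2, (1 - spec$gc) / 2))
    orf_tab <- NULL
    motif_tab <- NULL
    if (!is.null(spec$orfs) && nrow(spec$orfs) > 0) {
      orfs <- spec$orfs
      peptides <- character(nrow(orfs))
      for (i in seq_len(nrow(orfs))) {
        span <- orfs$end[i] - orfs$start[i] + 1
        n_aa <- span / 3 - 1
        pep <- c("M", sample(AA20, n_aa - 1, replace = TRUE))
        if (!is.null(spec$motifs)) {
          mi <- spec$motifs[spec$motifs$orf == orfs$name[i], , drop = FALSE]
          for (j in seq_len(nrow(mi))) {
            inst <- strsplit(mi$instance[j], "")[[1]]
            pep[mi$offset[j] + seq_along(inst)] <- inst
          }
        }
        peptides[i] <- paste(pep, collapse = "")
        coding <- paste0(reverse_translate(pep),
                         sample(c("TAA", "TAG", "TGA"), 1))
        if (orfs$strand[i] == "-") coding <- revcomp(coding)
        pos <- ((orfs$start[i] - 1 + seq_len(span) - 1) %% L) + 1
        chars[pos] <- strsplit(coding, "")[[1]]
      }
      start0 <- orfs$start - 1L
      end0 <- orfs$end  # 1-based inclusive end == 0-based half-open end
      orf_tab <- data.frame(
        genome_id = spec$label, name = orfs$name,
        start = as.integer(start0), end = as.integer(end0),
        strand = orfs$strand, wraps_origin = orfs$end > L,
        peptide = peptides, stringsAsFactors = FALSE)
      if (!is.null(spec$motifs) && nrow(spec$motifs) > 0) {
        motif_tab <- data.frame(
          genome_id = spec$label, orf = spec$motifs$orf,
          name = spec$motifs$name, instance = spec$motifs$instance,
          offset = as.integer(spec$motifs$offset), stringsAsFactors = FALSE)
      }
    }
    structure(list(id = spec$label, seq = paste(chars, collapse = ""),
                   topology = spec$topology, orfs = orf_tab,
                   motifs = motif_tab, gc = spec$gc),
              class = "vs_genome")
  })
}

#' @export
print.vs_genome <- function(x, ...) {
  cat(sprintf("<vs_genome> %s: %d bases, %s, %d ORFs\n", x$id, nchar(x$seq),
              x$topology, if (is.null(x$orfs)) 0L else nrow(x$orfs)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Canned genome specs used throughout the tests and the demo pipeline
# ---------------------------------------------------------------------------

#' Canned synthetic genome specs
#'
#' `parvovirus_like_spec()` describes a 4,620-base linear genome with the
#' two-ORF organization of a protoparvovirus: a non-structural replication
#' ORF (NS1) carrying Walker A/B and rolling-circle replication motif
#' instances, and a capsid ORF (VP1) with the phospholipase A2 catalytic
#' HD/D residues and YLGPG calcium-binding loop in its N-terminal region.
#' `polyomavirus_like_spec()` describes a 4,800-base circular genome with
#' VP1, VP2, ST and LT ORFs; LT carries the DnaJ HPDKGG box, an LxCxE
#' Rb-binding instance, a Walker A loop and the CxxC/CLVC/CFSC zinc-binding
#' clusters, and ST wraps the origin.  `background_genome_spec()` is an
#' ORF-free random genome standing in for host or bacterial sequence.
#'
#' @param label Genome label.
#' @param length Genome length (background spec only).
#' @param gc Background GC fraction.
#' @return A [genome_spec()].
#' @export
parvovirus_like_spec <- function(label = "parvovirus_like", gc = 0.42) {
  orfs <- data.frame(
    name = c("NS1", "VP1"),
    start = c(201L, 2200L),
    end = c(201L + 1803L - 1L, 2200L + 2103L - 1L),  # 600 aa, 700 aa
    strand = c("+", "+"), stringsAsFactors = FALSE)
  motifs <- data.frame(
    orf = c("NS1", "NS1", "NS1", "NS1", "VP1", "VP1", "VP1"),
    name = c("rcr1", "rcr2", "walker_a", "walker_b",
             "pla2_hd", "pla2_d", "pla2_yxgxg"),
    instance = c("TKLHTHLILG", "VLTYTHKQT", "GPASTGKS", "VIWIEE",
                 "HD", "D", "YLGPG"),
    offset = c(80L, 120L, 250L, 300L, 40L, 80L, 110L),
    stringsAsFactors = FALSE)
  genome_spec(label, 4620L, "linear", orfs, motifs, gc)
}

#' @rdname parvovirus_like_spec
#' @export
polyomavirus_like_spec <- function(label = "polyomavirus_like", gc = 0.40) {
  orfs <- data.frame(
    name = c("VP2", "VP1", "LT", "ST"),
    start = c(400L, 1400L, 2600L, 4600L),
    end = c(400L + 903L - 1L,    # 300 aa
            1400L + 1083L - 1L,  # 360 aa
            2600L + 1983L - 1L,  # 660 aa
            4600L + 543L - 1L),  # 180 aa, wraps the origin (5142 > 4800)
    strand = c("+", "+", "-", "+"), stringsAsFactors = FALSE)
  motifs <- data.frame(
    orf = rep("LT", 6),
    name = c("dnaj_hpdkgg", "lxcxe", "walker_a_lt", "zn_cxxc", "zn_clvc",
             "zn_cfsc"),
    instance = c("HPDKGG", "LFCSE", "GPINSGKT", "CRLC", "CLVC", "CFSC"),
    offset = c(42L, 102L, 420L, 500L, 520L, 540L),
    stringsAsFactors = FALSE)
  genome_spec(label, 4800L, "circular", orfs, motifs, gc)
}

#' @rdname parvovirus_like_spec
#' @export
background_genome_spec <- function(label, length, gc = 0.45) {
  genome_spec(label, length, "linear", NULL, NULL, gc)
}

# ---------------------------------------------------------------------------
# Community + read simulation
# ---------------------------------------------------------------------------

#' Describe a synthetic community
#'
#' @param genomes List of `vs_genome` objects (from [make_genome()]).
#' @param abundance Numeric vector of relative abundances (fraction of read
#'   pairs drawn from each genome); must sum to 1 within 1e-9.
#' @param role Character vector: `"host"`, `"bacterial"` or `"viral"` per
#'   member (used by the truth table and reporting only).
#' @return A `vs_community` list.
#' @export
community_spec <- function(genomes, abundance, role) {
  stopifnot(length(genomes) == length(abundance),
            length(genomes) == length(role),
            all(role %in% c("host", "bacterial", "viral")))
  if (abs(sum(abundance) - 1) > 1e-9)
    stop("abundances must sum to 1 (got ", sum(abundance), ")")
  structure(list(genomes = genomes, abundance = abundance, role = role),
            class = "vs_community")
}

#' Read-simulation parameters
#'
#' Qualities start at `q_start` and decline linearly to `q_floor` across the
#' read, with independent per-base integer jitter (sd `q_jitter_sd`), so read
#' tails genuinely fall below the Phred-20 trimming threshold.  When a
#' sampled insert is shorter than the read length, the read runs through
#' into the adaptor followed by random sequence, emulating adaptor
#' read-through.
#'
#' @param n_pairs Number of read pairs to emit.
#' @param read_length Read length in bases (>= 56 so the positional
#'   deduplication key exists).
#' @param substitution_rate Per-base substitution error probability.
#' @param q_start,q_floor,q_jitter_sd Quality model (Phred).
#' @param duplicate_fraction Fraction of emitted pairs that are re-emissions
#'   of an earlier pair (identical bases; fresh quality jitter).
#' @param adaptor Adaptor base string appended on run-through.
#' @param insert_mean,insert_sd Insert size distribution (bases).
#' @param seed Integer seed.
#' @return A `vs_readsim_params` list.
#' @export
read_sim_params <- function(n_pairs, read_length = 250L,
                            substitution_rate = 0.002,
                            q_start = 37L, q_floor = 17L, q_jitter_sd = 2,
                            duplicate_fraction = 0.1,
                            adaptor = "CTGTCTCTTATACACATCTCCGAGCCCACGAGA",
                            insert_mean = 350, insert_sd = 60, seed = 1L) {
  stopifnot(n_pairs >= 1, read_length >= 56,
            substitution_rate >= 0, substitution_rate <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 substitution_rate = substitution_rate,
                 q_start = q_start, q_floor = q_floor,
                 q_jitter_sd = q_jitter_sd,
                 duplicate_fraction = duplicate_fraction,
                 adaptor = adaptor, insert_mean = insert_mean,
                 insert_sd = insert_sd, seed = as.integer(seed)),
            class = "vs_readsim_params")
}

# substitute bases in a block of equal-length reads held as one big string
apply_substitutions <- function(big, rate) {
  r <- charToRaw(big)
  n_err <- rbinom(1, length(r), rate)
  if (n_err == 0) return(big)
  pos <- sample.int(length(r), n_err)
  repl <- as.raw(sample(utf8ToInt("ACGT"), n_err, replace = TRUE))
  clash <- which(repl == r[pos])
  while (length(clash) > 0) {
    repl[clash] <- as.raw(sample(utf8ToInt("ACGT"), length(clash), replace = TRUE))
    clash <- clash[repl[clash] == r[pos][clash]]
  }
  r[pos] <- repl
  rawToChar(r)
}

#' Simulate paired-end reads from a community
#'
#' Emits exactly `n_pairs` pairs.  A planted fraction of pairs are
#' byte-identical re-emissions of an earlier pair (duplicates; qualities are
#' re-jittered), reads from circular genomes may span the origin, and every
#' read is recorded in a truth table (source genome, forward-strand source
#' coordinates, duplicate status).
#'
#' @param community A [community_spec()].
#' @param params A [read_sim_params()].
#' @return List with `r1`, `r2` (reads tables: `id`, `seq`, `qual`),
#'   `truth` (data.frame: `pair_id`, `genome`, `role`, `start`, `end`
#'   1-based inclusive source span, `wraps_origin`, `is_duplicate`,
#'   `duplicate_of`), and `params`.
#' @export
simulate_reads <- function(community, params) {
  stopifnot(inherits(community, "vs_community"),
            inherits(params, "vs_readsim_params"))
  with_seed(params$seed, {
    rl <- params$read_length
    glens <- vapply(community$genomes, function(g) nchar(g$seq), integer(1))
    circ <- vapply(community$genomes, function(g) g$topology == "circular",
                   logical(1))
    usable <- glens >= ceiling(0.4 * rl)
    if (any(!usable)) {
      warning("skipping genomes shorter than the minimum insert: ",
              paste(vapply(community$genomes[!usable], `[[`, "", "id"),
                    collapse = ", "))
    }
    ab <- community$abundance
    ab[!usable] <- 0
    ab <- ab / sum(ab)

    n_dup <- round(params$duplicate_fraction * params$n_pairs)
    n_orig <- params$n_pairs - n_dup
    src <- sample.int(length(glens), n_orig, replace = TRUE, prob = ab)
    insert <- pmax(ceiling(0.4 * rl),
                   round(rnorm(n_orig, params$insert_mean, params$insert_sd)))
    insert <- pmin(insert, glens[src])  # genome shorter than insert: clamp
    start <- integer(n_orig)
    lin <- !circ[src]
    start[lin] <- floor(runif(sum(lin)) * (glens[src][lin] - insert[lin] + 1)) + 1L
    start[!lin] <- floor(runif(sum(!lin)) * glens[src][!lin]) + 1L

    # fragments, per source genome (doubled string for circular wrap)
    frag <- character(n_orig)
    for (gi in unique(src)) {
      sel <- src == gi
      gseq <- community$genomes[[gi]]$seq
      if (circ[gi]) gseq <- paste0(gseq, gseq)
      frag[sel] <- substring(gseq, start[sel], start[sel] + insert[sel] - 1)
    }
    # R1 from fragment 5' end, R2 from the reverse complement
    fill_read <- function(fr) {
      short <- nchar(fr) < rl
      out <- substring(fr, 1, rl)
      if (any(short)) {
        need <- rl - nchar(fr[short])
        tails <- paste0(params$adaptor,
                        vapply(pmax(0, need - nchar(params$adaptor)) + 1L,
                               function(n) random_dna(n), character(1)))
        out[short] <- substring(paste0(fr[short], tails), 1, rl)
      }
      out
    }
    r1 <- fill_read(frag)
    r2 <- fill_read(revcomp(frag))
    resplit <- function(big) {
      substring(big, (seq_len(n_orig) - 1) * rl + 1, seq_len(n_orig) * rl)
    }
    r1 <- resplit(apply_substitutions(paste(r1, collapse = ""),
                                      params$substitution_rate))
    r2 <- resplit(apply_substitutions(paste(r2, collapse = ""),
                                      params$substitution_rate))

    # duplicates: re-emit already-generated pairs (identical bases)
    dup_of <- if (n_dup > 0) sample.int(n_orig, n_dup, replace = TRUE) else integer(0)
    ord <- sample.int(params$n_pairs)  # interleave duplicates into the pool
    src_all <- c(src, src[dup_of])[ord]
    r1_all <- c(r1, r1[dup_of])[ord]
    r2_all <- c(r2, r2[dup_of])[ord]
    start_all <- c(start, start[dup_of])[ord]
    insert_all <- c(insert, insert[dup_of])[ord]
    is_dup <- c(rep(FALSE, n_orig), rep(TRUE, n_dup))[ord]
    orig_idx <- c(seq_len(n_orig), dup_of)[ord]
    pair_id <- sprintf("read%07d", seq_len(params$n_pairs))
    dup_of_id <- ifelse(is_dup, pair_id[match(orig_idx, orig_idx)], NA)

    # qualities: linear decay template + integer jitter, independent per read
    qtpl <- round(seq(params$q_start, params$q_floor, length.out = rl))
    make_quals <- function(n) {
      q <- rep(qtpl, n) + round(rnorm(n * rl, 0, params$q_jitter_sd))
      q <- pmin(pmax(q, 2L), 41L)
      big <- rawToChar(as.raw(q + 33L))
      substring(big, (seq_len(n) - 1) * rl + 1, seq_len(n) * rl)
    }
    q1 <- make_quals(params$n_pairs)
    q2 <- make_quals(params$n_pairs)

    glabels <- vapply(community$genomes, `[[`, "", "id")
    end_all <- start_all + insert_all - 1L
    truth <- data.frame(
      pair_id = pair_id, genome = glabels[src_all],
      role = community$role[src_all],
      start = start_all, end = end_all,
      wraps_origin = circ[src_all] & end_all > glens[src_all],
      is_duplicate = is_dup, duplicate_of = dup_of_id,
      stringsAsFactors = FALSE)
    list(r1 = data.frame(id = paste0(pair_id, "/1"), seq = r1_all, qual = q1,
                         stringsAsFactors = FALSE),
         r2 = data.frame(id = paste0(pair_id, "/2"), seq = r2_all, qual = q2,
                         stringsAsFactors = FALSE),
         truth = truth, params = params)
  })
}

#' Write a simulation truth table as TSV
#'
#' @param truth Truth table from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write community genomes as FASTA with topology in the description line
#'
#' @param genomes List of `vs_genome` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genomes_fasta <- function(genomes, path) {
  ss <- vapply(genomes, `[[`, "", "seq")
  names(ss) <- vapply(genomes, `[[`, "", "id")
  write_fasta(ss, path,
              desc = paste0("topology=", vapply(genomes, `[[`, "", "topology")))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Labeled protein database derived from the community
# ---------------------------------------------------------------------------

mutate_peptide <- function(pep, identity) {
  aa <- strsplit(pep, "")[[1]]
  n_mut <- round((1 - identity) * length(aa))
  if (n_mut > 0) {
    pos <- sample.int(length(aa), n_mut)
    repl <- sample(AA20, n_mut, replace = TRUE)
    clash <- which(repl == aa[pos])
    while (length(clash) > 0) {
      repl[clash] <- sample(AA20, length(clash), replace = TRUE)
      clash <- clash[repl[clash] == aa[pos][clash]]
    }
    aa[pos] <- repl
  }
  paste(aa, collapse = "")
}

#' Build a labeled virus/non-virus protein database for a community
#'
#' Viral ORF peptides enter the database as diverged homologs (point
#' mutations to a target identity), labeled `virus` under a per-genome
#' taxon.  Host ORF peptides (found by [find_orfs()]) enter verbatim as
#' `nonvirus` cellular records, and random decoy peptides pad both labels so
#' the best-hit arbitration has genuine competition.
#'
#' @param community A [community_spec()].
#' @param homolog_identity Target identity of the viral homologs (fraction).
#' @param n_host_proteins Maximum number of host ORF records.
#' @param n_decoys Random decoy peptides per label.
#' @param decoy_length Decoy peptide length (residues).
#' @param seed Integer seed.
#' @return data.frame with columns `id`, `seq`, `label` (`virus`/`nonvirus`),
#'   `taxon`, `protein`.
#' @export
make_protein_db <- function(community, homolog_identity = 0.7,
                            n_host_proteins = 10, n_decoys = 10,
                            decoy_length = 250, seed = 1L) {
  stopifnot(inherits(community, "vs_community"))
  with_seed(seed, {
    rows <- list()
    for (i in seq_along(community$genomes)) {
      g <- community$genomes[[i]]
      if (community$role[i] == "viral" && !is.null(g$orfs)) {
        taxon <- paste0(g$id, "_relative")
        for (j in seq_len(nrow(g$orfs))) {
          rows[[length(rows) + 1]] <- data.frame(
            id = paste0(taxon, "_", g$orfs$name[j]),
            seq = mutate_peptide(g$orfs$peptide[j], homolog_identity),
            label = "virus", taxon = taxon, protein = g$orfs$name[j],
            stringsAsFactors = FALSE)
        }
      }
    }
    hosts <- which(community$role == "host")
    if (length(hosts) > 0 && n_host_proteins > 0) {
      ho <- find_orfs(community$genomes[[hosts[1]]]$seq, circular = FALSE,
                      min_orf_length = 100)
      if (nrow(ho) > 0) {
        ho <- ho[order(-nchar(ho$peptide)), , drop = FALSE]
        ho <- head(ho, n_host_proteins)
        for (j in seq_len(nrow(ho))) {
          rows[[length(rows) + 1]] <- data.frame(
            id = sprintf("host_protein_%02d", j), seq = ho$peptide[j],
            label = "nonvirus", taxon = "cellular organism",
            protein = sprintf("hypothetical_%02d", j),
            stringsAsFactors = FALSE)
        }
      }
    }
    for (j in seq_len(n_decoys)) {
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("decoy_virus_%02d", j),
        seq = paste(sample(AA20, decoy_length, replace = TRUE), collapse = ""),
        label = "virus", taxon = "unrelated virus",
        protein = sprintf("decoy_%02d", j), stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("decoy_cell_%02d", j),
        seq = paste(sample(AA20, decoy_length, replace = TRUE), collapse = ""),
        label = "nonvirus", taxon = "cellular organism",
        protein = sprintf("decoy_%02d", j), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Truth-based contig evaluation
#'
#' Aligns each contig (both strands, local alignment) to a truth genome and
#' summarises how much of the genome the contig set covers and at what
#' identity.  Circular genomes are aligned against their doubled sequence so
#' a contig crossing the origin is scored correctly.
#'
#' @param contig_seqs Character vector of contig sequences.
#' @param genome A `vs_genome` (or a list with `seq` and `topology`).
#' @param min_identity Contig/genome alignments below this identity
#'   (percent) are ignored.
#' @return List: `coverage` (fraction of genome covered), `identity`
#'   (length-weighted mean percent identity of used alignments), `per_contig`
#'   data.frame.
#' @export
contig_truth_stats <- function(contig_seqs, genome, min_identity = 90) {
  glen <- nchar(genome$seq)
  subject <- if (genome$topology == "circular")
    paste0(genome$seq, genome$seq) else genome$seq
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  res <- lapply(contig_seqs, function(cs) {
    best <- NULL
    for (s in c(cs, revcomp(cs))) {
      a <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(s), Biostrings::DNAString(subject),
        type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      if (is.null(best) || Biostrings::score(a) > Biostrings::score(best))
        best <- a
    }
    sr <- Biostrings::subject(best)
    data.frame(start = Biostrings::start(sr), end = Biostrings::end(sr),
               identity = Biostrings::pid(best, type = "PID2"))
  })
  per <- do.call(rbind, res)
  used <- per[per$identity >= min_identity, , drop = FALSE]
  cov_mask <- logical(glen)
  if (nrow(used) > 0) {
    for (i in seq_len(nrow(used))) {
      pos <- seq(used$start[i], used$end[i])
      cov_mask[((pos - 1) %% glen) + 1] <- TRUE
    }
  }
  wid <- if (nrow(used)) used$end - used$start + 1 else numeric(0)
  list(coverage = mean(cov_mask),
       identity = if (length(wid)) sum(used$identity * wid) / sum(wid) else NA_real_,
       per_contig = per)
}
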