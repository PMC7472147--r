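# Orchestration: synthetic community (or FASTQ input) -> preprocessing ->
# ensemble assembly -> translated classification -> annotation -> comparison,
# as one seeded, logged, resumable run.

#' Default demo run configuration
#'
#' A synthetic community with a 200 kb host genome, a 100 kb bacterial
#' genome, and the two viral genomes (linear parvovirus-like, circular
#' polyomavirus-like) spiked at 30x coverage among the read pairs, plus a
#' labeled protein database holding diverged homologs of the viral
#' proteins and exact host proteins.
#'
#' @param n_pairs Total read pairs.
#' @param viral_coverage Per-virus fold coverage (pre-deduplication).
#' @param host_length,bacterial_length Background genome lengths.
#' @param seed Global seed.
#' @param outdir Output directory.
#' @return A `vs_run_config` list accepted by [run_pipeline()].
#' @export
demo_config <- function(n_pairs = 50000L, viral_coverage = 30,
                        host_length = 200000L, bacterial_length = 100000L,
                        seed = 1L, outdir = tempfile("viroscout_run_")) {
  list(seed = as.integer(seed), outdir = outdir,
       community = list(n_pairs = as.integer(n_pairs),
                        viral_coverage = viral_coverage,
                        host_length = as.integer(host_length),
                        bacterial_length = as.integer(bacterial_length)),
       read_sim = list(), preprocess = list(), subtraction = list(),
       assembly = list(), classify = list(), demarcation = list(),
       subtract_background = TRUE)
}

#' Validate and normalize a run configuration
#'
#' Accepts a config list or a YAML/JSON path.  Either a `community` block
#' (synthetic run) or `fastq` paths plus `references`/`protein_db` paths
#' must be present.  Returns the normalized config or stops with the full
#' list of problems.
#'
#' @param config List, or path to a YAML/JSON file.
#' @return Normalized `vs_run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  errs <- character(0)
  if (is.null(config$seed)) errs <- c(errs, "missing seed")
  if (is.null(config$outdir)) config$outdir <- tempfile("viroscout_run_")
  synthetic <- !is.null(config$community)
  if (!synthetic) {
    for (f in c("fastq_r1", "fastq_r2", "references", "protein_db")) {
      if (is.null(config[[f]])) errs <- c(errs, paste("missing", f))
      else if (!file.exists(config[[f]]))
        errs <- c(errs, paste0(f, " path does not exist: ", config[[f]]))
    }
  }
  for (block in c("read_sim", "preprocess", "subtraction", "assembly",
                  "classify", "demarcation"))
    if (is.null(config[[block]])) config[[block]] <- list()
  if (is.null(config$subtract_background)) config$subtract_background <- TRUE
  if (length(errs) > 0)
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "))
  config$synthetic <- synthetic
  class(config) <- c("vs_run_config", "list")
  config
}

build_demo_inputs <- function(config) {
  cs <- config$community
  seed <- config$seed
  host <- make_genome(background_genome_spec("host", cs$host_length, gc = 0.41),
                      derive_seed(seed, 1))
  bact <- make_genome(background_genome_spec("bacterium", cs$bacterial_length,
                                             gc = 0.5),
                      derive_seed(seed, 2))
  parvo <- make_genome(parvovirus_like_spec(), derive_seed(seed, 3))
  polyo <- make_genome(polyomavirus_like_spec(), derive_seed(seed, 4))
  rs_args <- config$read_sim
  rs_args$n_pairs <- cs$n_pairs
  rs_args$seed <- derive_seed(seed, 5)
  params <- do.call(read_sim_params, rs_args)
  pair_bases <- 2 * params$read_length
  ab_parvo <- cs$viral_coverage * nchar(parvo$seq) / pair_bases / cs$n_pairs
  ab_polyo <- cs$viral_coverage * nchar(polyo$seq) / pair_bases / cs$n_pairs
  ab_bg <- 1 - ab_parvo - ab_polyo
  lens <- c(nchar(host$seq), nchar(bact$seq))
  community <- community_spec(
    genomes = list(host, bact, parvo, polyo),
    abundance = c(ab_bg * lens / sum(lens), ab_parvo, ab_polyo),
    role = c("host", "bacterial", "viral", "viral"))
  db <- make_protein_db(community, seed = derive_seed(seed, 6))
  list(community = community, read_sim = params, db = db,
       references = setNames(c(host$seq, bact$seq), c(host$id, bact$id)))
}

#' Run the discovery pipeline end to end
#'
#' Stages execute in fixed order (simulate/load, preprocess, assemble,
#' classify, annotate, compare); any failure halts with the manifest
#' recording the failure point, and re-running with the same config and
#' seed reproduces identical reports.  An empty read set after subtraction
#' yields a report with zero viruses, not an error.
#'
#' @param config A config list or path (see [validate_config()];
#'   [demo_config()] builds a synthetic run).
#' @return A `vs_run` list: `manifest`, `contigs`, `hits`, `report`
#'   (virome report), `annotation`, `comparison`, `truth` (synthetic runs),
#'   with artifact files under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  t_all <- proc.time()[["elapsed"]]
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(),
                   params = config[setdiff(names(config), "synthetic")])
  stage_time <- function(t0) round(proc.time()[["elapsed"]] - t0, 2)
  log_msg <- function(...) message(sprintf(...))

  # --- stage 1: obtain reads -------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  truth <- NULL
  if (config$synthetic) {
    inputs <- build_demo_inputs(config)
    sim <- simulate_reads(inputs$community, inputs$read_sim)
    reads <- rbind(sim$r1, sim$r2)
    truth <- sim$truth
    db <- inputs$db
    refs <- inputs$references
    write_fastq(sim$r1, file.path(config$outdir, "reads_R1.fastq"))
    write_fastq(sim$r2, file.path(config$outdir, "reads_R2.fastq"))
    write_truth_tsv(truth, file.path(config$outdir, "truth.tsv"))
    write_genomes_fasta(inputs$community$genomes,
                        file.path(config$outdir, "genomes.fasta"))
    write_protein_db(db, file.path(config$outdir, "protein_db.fasta"))
  } else {
    reads <- rbind(read_fastq(config$fastq_r1), read_fastq(config$fastq_r2))
    db <- read_protein_db(config$protein_db)
    rtab <- read_fasta(config$references)
    refs <- setNames(rtab$seq, rtab$id)
  }
  manifest$stages$input <- list(n_reads = nrow(reads), seconds = stage_time(t0))
  log_msg("input: %d reads", nrow(reads))

  # --- stage 2: preprocess ---------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  pp_params <- do.call(preprocess_params, config$preprocess)
  sub_params <- do.call(subtraction_params, config$subtraction)
  index <- if (config$subtract_background)
    build_subtraction_index(refs, sub_params) else NULL
  pp <- preprocess(reads, pp_params, index, seed = derive_seed(config$seed, 7))
  write.table(pp$report, file.path(config$outdir, "stage_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$preprocess <- list(
    report = pp$report, n_out = nrow(pp$reads), seconds = stage_time(t0))
  log_msg("preprocess: %d reads survive", nrow(pp$reads))

  # --- stage 3: assemble -----------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  asm_params <- do.call(assembly_params, config$assembly)
  asm <- assemble_reads(pp$reads, asm_params, seed = derive_seed(config$seed, 8))
  contigs <- asm$contigs
  write_contigs_fasta(contigs, file.path(config$outdir, "contigs.fasta"))
  manifest$stages$assemble <- list(
    n_contigs = nrow(contigs), n_singlets = length(asm$singlets),
    seconds = stage_time(t0))
  log_msg("assemble: %d contigs, %d singlets", nrow(contigs),
          length(asm$singlets))

  # --- stage 4: classify -----------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  cls_params <- do.call(classify_params, config$classify)
  model <- scoring_model()
  queries <- data.frame(
    id = c(contigs$id, pp$reads$id[asm$singlets]),
    seq = c(contigs$seq, pp$reads$seq[asm$singlets]),
    stringsAsFactors = FALSE)
  qtype <- setNames(c(rep("contig", nrow(contigs)),
                      rep("read", length(asm$singlets))), queries$id)
  cand <- viral_candidates(queries, db, model, cls_params)
  arb <- nr_filter(cand, queries, db, model, cls_params)
  report <- summarize_virome(arb$retained, cls_params, qtype)
  write_hits_tsv(arb$all_hits, file.path(config$outdir, "hits.tsv"))
  jsonlite::write_json(report, file.path(config$outdir, "virome_report.json"),
                       dataframe = "rows", pretty = TRUE)
  write.table(report, file.path(config$outdir, "virome_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$classify <- list(
    n_queries = nrow(queries), n_candidates = nrow(cand),
    n_retained = nrow(arb$retained), n_taxa = nrow(report),
    n_detections = sum(report$detection), seconds = stage_time(t0))
  log_msg("classify: %d candidates, %d retained, %d taxa flagged",
          nrow(cand), nrow(arb$retained), sum(report$detection))

  # --- stage 5: annotate retained viral contigs ------------------------------
  t0 <- proc.time()[["elapsed"]]
  annotation <- list()
  viral_contig_ids <- intersect(arb$retained$query_id, contigs$id)
  for (cid in viral_contig_ids) {
    crow <- contigs[contigs$id == cid, ]
    orfs <- find_orfs(crow$seq, circular = crow$circular)
    if (nrow(orfs) == 0) next
    orfs$name <- sprintf("%s_orf%02d", cid, seq_len(nrow(orfs)))
    hm <- hallmark_report(orfs)
    gff <- file.path(config$outdir, paste0(cid, "_annotation.gff3"))
    write_orfs_gff3(orfs, cid, nchar(crow$seq), gff,
                    motif_hits = hm$hits[hm$hits$n_hits > 0, , drop = FALSE])
    annotation[[cid]] <- list(orfs = orfs, hallmarks = hm)
  }
  manifest$stages$annotate <- list(
    n_contigs_annotated = length(annotation), seconds = stage_time(t0))

  # --- stage 6: compare (demarcation + NJ tree on NS1-like proteins) ---------
  t0 <- proc.time()[["elapsed"]]
  comparison <- NULL
  dem_params <- do.call(demarcation_params, config$demarcation)
  ns1_like <- db[db$label == "virus" & grepl("NS1|LT", db$id), , drop = FALSE]
  # candidate NS1: panel-complete ORFs, preferring ones not also matching
  # other panels (degenerate panels can co-fire on long random peptides),
  # then the longest peptide
  ns1_cand <- list()
  for (cid in names(annotation)) {
    vd <- annotation[[cid]]$hallmarks$verdicts
    orfs <- annotation[[cid]]$orfs
    for (orf_id in unique(vd$orf[vd$complete & vd$panel == "parvovirus_NS1"])) {
      n_other <- sum(vd$complete & vd$orf == orf_id &
                       vd$panel != "parvovirus_NS1")
      pep <- orfs$peptide[match(orf_id, orfs$name)]
      ns1_cand[[length(ns1_cand) + 1]] <-
        list(pep = pep, n_other = n_other, len = nchar(pep))
    }
  }
  query_ns1 <- NULL
  if (length(ns1_cand) > 0) {
    sc <- vapply(ns1_cand, function(x) x$n_other * 1e6 - x$len, numeric(1))
    query_ns1 <- ns1_cand[[which.min(sc)]]$pep
  }
  if (!is.null(query_ns1) && nrow(ns1_like) > 0) {
    refs_ns1 <- setNames(ns1_like$seq, ns1_like$id)
    dem <- species_demarcation(query_ns1, refs_ns1, dem_params)
    seqs <- c(setNames(query_ns1, "query_NS1"), refs_ns1)
    im <- identity_matrix(seqs, mode = "global")
    tree <- nj_tree(im$distance)
    write_newick(tree, file.path(config$outdir, "ns1_nj.nwk"))
    write.table(round(im$identity, 2),
                file.path(config$outdir, "ns1_identity.tsv"),
                sep = "\t", quote = FALSE)
    comparison <- list(demarcation = dem, identity = im$identity, tree = tree)
  }
  manifest$stages$compare <- list(
    ran = !is.null(comparison), seconds = stage_time(t0))

  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 2)
  jsonlite::write_json(
    manifest[c("seed", "total_seconds")],
    file.path(config$outdir, "manifest.json"), auto_unbox = TRUE)
  structure(list(manifest = manifest, contigs = contigs, hits = arb$all_hits,
                 retained = arb$retained, report = report,
                 annotation = annotation, comparison = comparison,
                 truth = truth, reads = pp$reads, config = config),
            class = "vs_run")
}

#' @export
print.vs_run <- function(x, ...) {
  cat("<vs_run>\n")
  cat(sprintf("  contigs: %d  taxa: %d  detections: %d\n",
              nrow(x$contigs), nrow(x$report), sum(x$report$detection)))
  invisible(x)
}
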