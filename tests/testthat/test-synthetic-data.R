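# Synthetic genome and read-pool generator.

test_that("planted ORFs translate cleanly and carry their motifs verbatim", {
  g <- make_genome(parvovirus_like_spec(), seed = 11)
  expect_equal(nchar(g$seq), 4620)
  expect_false(any(grepl("\\*", g$orfs$peptide)))
  for (i in seq_len(nrow(g$motifs))) {
    pep <- g$orfs$peptide[match(g$motifs$orf[i], g$orfs$name)]
    expect_equal(substr(pep, g$motifs$offset[i] + 1,
                        g$motifs$offset[i] + nchar(g$motifs$instance[i])),
                 g$motifs$instance[i])
  }
  # the genome itself encodes the peptides (cross-check with Biostrings)
  ns1 <- g$orfs[g$orfs$name == "NS1", ]
  coding <- substr(g$seq, ns1$start + 1, ns1$end - 3)  # strip stop codon
  expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(coding))),
               ns1$peptide)
})

test_that("ORF-free specs give plain random sequence with empty truth", {
  g <- make_genome(genome_spec("bg", 1000, "linear"), seed = 3)
  expect_equal(nchar(g$seq), 1000)
  expect_null(g$orfs)
  expect_null(g$motifs)
})

test_that("genome construction is deterministic in (spec, seed)", {
  s <- polyomavirus_like_spec()
  expect_identical(make_genome(s, 5)$seq, make_genome(s, 5)$seq)
  expect_false(make_genome(s, 5)$seq == make_genome(s, 6)$seq)
})

test_that("infeasible motif layouts are rejected with a message", {
  orfs <- data.frame(name = "tiny", start = 1, end = 33, strand = "+")
  motifs <- data.frame(orf = "tiny", name = "m", offset = 1,
                       instance = "WWWWWWWWWWWWWWWW")  # 16 aa > 10 aa ORF
  expect_error(genome_spec("g", 100, "linear", orfs, motifs),
               "infeasible|longer than ORF")
})

test_that("minus-strand and origin-wrapping ORFs are encoded faithfully", {
  g <- make_genome(polyomavirus_like_spec(), seed = 21)
  lt <- g$orfs[g$orfs$name == "LT", ]
  coding <- revcomp(substr(g$seq, lt$start + 1, lt$end))
  coding <- substr(coding, 1, nchar(coding) - 3)
  expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(coding))),
               lt$peptide)
  st <- g$orfs[g$orfs$name == "ST", ]
  expect_true(st$wraps_origin)
  doubled <- paste0(g$seq, g$seq)
  coding <- substr(doubled, st$start + 1, st$end - 3)
  expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(coding))),
               st$peptide)
})

make_test_community <- function(host_len = 8000) {
  host <- make_genome(background_genome_spec("host", host_len), 1)
  polyo <- make_genome(polyomavirus_like_spec(), 3)
  community_spec(list(host, polyo), c(0.7, 0.3), c("host", "viral"))
}

test_that("the planted duplicate count is exact and flagged in the truth table", {
  comm <- make_test_community()
  sim <- simulate_reads(comm, read_sim_params(n_pairs = 10000,
                                              duplicate_fraction = 0.10,
                                              seed = 7))
  expect_equal(sum(sim$truth$is_duplicate), 1000)
  expect_equal(nrow(sim$truth), 10000)
  # completeness: every pair id appears exactly once
  expect_equal(anyDuplicated(sim$truth$pair_id), 0)
  expect_equal(sim$r1$id, paste0(sim$truth$pair_id, "/1"))
  # duplicates are byte-identical re-emissions of their originals
  d <- which(sim$truth$is_duplicate)[1]
  o <- match(sim$truth$duplicate_of[d], sim$truth$pair_id)
  expect_identical(sim$r1$seq[d], sim$r1$seq[o])
  expect_identical(sim$r2$seq[d], sim$r2$seq[o])
})

test_that("error-free reads are exact substrings of their source genome", {
  comm <- make_test_community()
  params <- read_sim_params(n_pairs = 300, substitution_rate = 0,
                            duplicate_fraction = 0, insert_mean = 350,
                            insert_sd = 0, seed = 13)
  sim <- simulate_reads(comm, params)
  genomes <- setNames(
    lapply(comm$genomes, function(g)
      if (g$topology == "circular") paste0(g$seq, g$seq) else g$seq),
    vapply(comm$genomes, `[[`, "", "id"))
  for (i in seq_len(50)) {
    src <- genomes[[sim$truth$genome[i]]]
    frag <- substr(src, sim$truth$start[i], sim$truth$end[i])
    expect_identical(sim$r1$seq[i], substr(frag, 1, 250))
    expect_identical(sim$r2$seq[i], substr(rc_str(frag), 1, 250))
  }
})

test_that("circular genomes yield origin-wrapping reads", {
  polyo <- make_genome(polyomavirus_like_spec(), 3)
  comm <- community_spec(list(polyo), 1, "viral")
  sim <- simulate_reads(comm, read_sim_params(n_pairs = 300, seed = 5))
  expect_gt(sum(sim$truth$wraps_origin), 0)
})

test_that("read simulation is deterministic and composition follows abundances", {
  comm <- make_test_community()
  p <- read_sim_params(n_pairs = 4000, seed = 17)
  s1 <- simulate_reads(comm, p)
  s2 <- simulate_reads(comm, p)
  expect_identical(s1$r1$seq, s2$r1$seq)
  expect_identical(s1$r2$qual, s2$r2$qual)
  # realized fractions within 3 multinomial standard deviations
  frac <- mean(s1$truth$genome[!s1$truth$is_duplicate] == "host")
  n <- sum(!s1$truth$is_duplicate)
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("FASTQ round-trips through the reads table", {
  comm <- make_test_community()
  sim <- simulate_reads(comm, read_sim_params(n_pairs = 50, seed = 2))
  f <- tempfile(fileext = ".fastq")
  write_fastq(sim$r1, f)
  back <- read_fastq(f)
  expect_equal(back$seq, sim$r1$seq)
  expect_equal(back$qual, sim$r1$qual)
  unlink(f)
})

test_that("quality tails decay below the trimming threshold", {
  comm <- make_test_community()
  sim <- simulate_reads(comm, read_sim_params(n_pairs = 200, seed = 4))
  q <- utf8ToInt(sim$r1$qual[1]) - 33L
  expect_gt(mean(head(q, 30)), 30)
  expect_lt(mean(tail(q, 10)), 20)
})
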