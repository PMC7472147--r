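# Deduplication, trimming, adaptor clipping, background subtraction.

test_that("reads identical over the key interval collapse to one survivor", {
  set.seed(1)
  base <- random_dna_str(250)
  r2 <- paste0(substr(base, 1, 60), random_dna_str(190))  # same positions 5-55
  reads <- make_reads(c(base, r2))
  out <- dedup(reads)
  expect_equal(nrow(out$reads), 1)
  expect_equal(out$removed, 1)
  # a single read survives trivially
  out1 <- dedup(make_reads(base))
  expect_equal(nrow(out1$reads), 1)
})

test_that("dedup equals the all-pairs oracle on planted duplicates", {
  set.seed(42)
  uniq <- vapply(1:800, function(i) random_dna_str(250), character(1))
  dup_src <- sample(uniq, 100)
  dups <- vapply(dup_src, function(s)
    paste0(substr(s, 1, 100), random_dna_str(150)), character(1))
  seqs <- unname(sample(c(uniq, dups)))  # 900 reads: 800 unique keys + 100 repeats
  reads <- make_reads(seqs)
  out <- dedup(reads)
  oracle <- oracle_dedup_first(seqs)
  expect_equal(nrow(out$reads), 800)
  expect_identical(out$reads$seq, seqs[oracle])
  # idempotence
  again <- dedup(out$reads)
  expect_identical(again$reads, out$reads)
  expect_equal(again$removed, 0)
  # random-survivor mode keeps exactly one per group
  rnd <- dedup(reads, seed = 9, keep = "random")
  expect_equal(nrow(rnd$reads), 800)
})

test_that("short reads are keyed on their full sequence", {
  reads <- make_reads(c("ACGTACGT", "ACGTACGT", "ACGTACGA"))
  out <- dedup(reads)
  expect_equal(nrow(out$reads), 2)
})

test_that("quality trimming removes the contiguous low-quality tail only", {
  r <- make_reads("ACGTT", quals = qual_string(c(30, 30, 30, 10, 10)))
  expect_equal(nchar(trim_quality(r, 20)$seq), 3)
  r <- make_reads("ACG", quals = qual_string(c(10, 30, 10)))
  expect_equal(trim_quality(r, 20)$seq, "AC")  # internal low base retained
  r <- make_reads("ACGTA", quals = qual_string(rep(30, 5)))
  expect_equal(trim_quality(r, 20)$seq, "ACGTA")
  r <- make_reads("ACGTA", quals = qual_string(rep(5, 5)))
  out <- trim_quality(r, 20)
  expect_equal(nchar(out$seq), 0)  # all-bad read flagged by zero length
  expect_equal(nchar(out$qual), 0)
})

test_that("adaptor clipping needs eight exact prefix bases or a near-full match", {
  set.seed(3)
  ad <- "CTGTCTCTTATACACATCTCCGAGCCCACGAGA"
  body <- random_dna_str(150)
  # full adaptor at the read end
  r <- make_reads(paste0(body, ad))
  expect_equal(trim_adaptor(r, ad)$seq, body)
  # 12-base adaptor prefix at the end (run-through truncated by read end)
  r <- make_reads(paste0(body, substr(ad, 1, 12)))
  expect_equal(trim_adaptor(r, ad)$seq, body)
  # 7-base prefix: below the evidence threshold
  r <- make_reads(paste0(body, substr(ad, 1, 7)))
  expect_equal(trim_adaptor(r, ad)$seq, paste0(body, substr(ad, 1, 7)))
  # full adaptor with one mismatch, mid-read: clipped from there
  ad1 <- ad
  substr(ad1, 16, 16) <- "A"
  if (ad1 == ad) substr(ad1, 16, 16) <- "C"
  r <- make_reads(paste0(body, ad1, random_dna_str(40)))
  expect_equal(trim_adaptor(r, ad)$seq, body)
  # clean read untouched
  r <- make_reads(body)
  expect_equal(trim_adaptor(r, ad)$seq, body)
})

test_that("background detection obeys the 60-base / 2-mismatch contract", {
  set.seed(7)
  ref <- random_dna_str(10000)
  idx <- build_subtraction_index(c(ref = ref))
  # verbatim copy: background
  r <- substr(ref, 501, 750)
  expect_true(is_background(r, idx)$background)
  # reverse complement: background
  expect_true(is_background(rc_str(r), idx)$background)
  # mismatches every 20 bases: every 60-base window has >= 3
  v <- strsplit(r, "")[[1]]
  for (p in seq(1, 250, by = 20)) v[p] <- setdiff(c("A","C","G","T"), v[p])[1]
  spoiled <- paste(v, collapse = "")
  expect_false(is_background(spoiled, idx)$background)
  expect_false(oracle_background(spoiled, ref))
  # random read against an unrelated reference
  rnd <- random_dna_str(250)
  expect_false(is_background(rnd, idx)$background)
  expect_false(oracle_background(rnd, ref))
  # too short to ever qualify
  expect_false(is_background("ACGTACGT", idx)$background)
})

test_that("seed-and-extend subtraction matches the exhaustive window oracle", {
  set.seed(11)
  ref <- random_dna_str(2000)
  idx <- build_subtraction_index(c(ref = ref))
  n <- 60
  reads <- character(n)
  for (i in seq_len(n)) {
    kind <- i %% 3
    if (kind == 0) {
      reads[i] <- random_dna_str(250)  # unrelated
    } else {
      s <- sample(1750, 1)
      r <- substr(ref, s, s + 249)
      v <- strsplit(r, "")[[1]]
      n_mut <- sample(0:12, 1)
      if (n_mut > 0) {
        pos <- sample(250, n_mut)
        for (p in pos) v[p] <- sample(setdiff(c("A","C","G","T"), v[p]), 1)
      }
      r <- paste(v, collapse = "")
      reads[i] <- if (kind == 1) r else rc_str(r)
    }
  }
  got <- is_background(reads, idx)$background
  want <- vapply(reads, oracle_background, logical(1), refs = ref)
  expect_identical(unname(got), unname(want))
})

test_that("the preprocessing pipeline is monotone and accounts for every read", {
  host <- make_genome(background_genome_spec("host", 10000), 1)
  polyo <- make_genome(polyomavirus_like_spec(), 3)
  comm <- community_spec(list(host, polyo), c(0.7, 0.3), c("host", "viral"))
  sim <- simulate_reads(comm, read_sim_params(n_pairs = 800, seed = 9))
  reads <- rbind(sim$r1, sim$r2)
  idx <- build_subtraction_index(setNames(host$seq, "host"))
  pp <- preprocess(reads, preprocess_params(), idx)
  rpt <- pp$report
  expect_true(all(diff(c(rpt$n_in[1], rpt$n_out)) <= 0))
  expect_equal(rpt$n_in[-1], rpt$n_out[-nrow(rpt)])
  expect_equal(rpt$n_in[1] - sum(rpt$removed), nrow(pp$reads))
  # surviving reads are viral
  pid <- sub("/[12]$", "", pp$reads$id)
  roles <- sim$truth$role[match(pid, sim$truth$pair_id)]
  expect_true(all(roles == "viral"))
  # no error-free background read survives subtraction
  flags <- pp$subtraction_flags
  expect_gt(sum(flags$background), 0)
})
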