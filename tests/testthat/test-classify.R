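# Six-frame translation, translated seeded search, E-value statistics,
# virus/non-virus arbitration, virome report.

back_translate_exact <- function(pep) {
  # deterministic codon choice (first codon per residue)
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  paste(vapply(strsplit(pep, "")[[1]], function(a) sort(by_aa[[a]])[1],
               character(1)), collapse = "")
}

db_frame <- function(seqs, label = "virus", taxon = "taxon A") {
  data.frame(id = sprintf("p%03d", seq_along(seqs)), seq = seqs,
             label = label, taxon = taxon, stringsAsFactors = FALSE)
}

test_that("six-frame translation follows the standard code and frame symmetry", {
  expect_equal(unname(six_frame_translate("ATGAAA")[["+1"]]), "MK")
  set.seed(41)
  s <- random_dna_str(60)
  fr <- six_frame_translate(s)
  # oracle: Biostrings translation of each frame
  rc <- rc_str(s)
  for (o in 0:2) {
    sub <- substr(s, o + 1, o + 1 + 3 * ((60 - o) %/% 3) - 1)
    expect_equal(unname(fr[[paste0("+", o + 1)]]),
                 as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                                    no.init.codon = TRUE)))
    sub <- substr(rc, o + 1, o + 1 + 3 * ((60 - o) %/% 3) - 1)
    expect_equal(unname(fr[[paste0("-", o + 1)]]),
                 as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                                    no.init.codon = TRUE)))
  }
  # reverse-complementing the input swaps the +i and -i frame sets
  fr_rc <- six_frame_translate(rc)
  expect_equal(unname(fr_rc[c("+1", "+2", "+3")]),
               unname(fr[c("-1", "-2", "-3")]))
})

test_that("an exact CDS fragment finds its protein with a tiny E-value", {
  set.seed(42)
  peps <- vapply(rep(200, 20), random_protein, character(1))
  db <- db_frame(peps)
  cds <- back_translate_exact(substr(peps[7], 51, 100))  # 150 nt
  query <- paste0(random_dna_str(30), cds, random_dna_str(30))
  hits <- translated_search(c(q1 = query), db)
  expect_gt(nrow(hits), 0)
  expect_equal(hits$subject_id[1], "p007")
  expect_lt(hits$evalue[1], 1e-10)
  expect_equal(hits$percent_identity[1], 100)
})

test_that("self-comparison raw score equals the BLOSUM62 diagonal sum", {
  set.seed(43)
  pep <- random_protein(80)
  db <- db_frame(pep)
  query <- back_translate_exact(pep)
  hits <- translated_search(c(q = query), db)
  b62 <- scoring_model()$matrix
  aa <- strsplit(pep, "")[[1]]
  want <- sum(vapply(aa, function(a) b62[a, a], numeric(1)))
  expect_equal(hits$raw_score[1], want)
  expect_equal(hits$align_length[1], 80)
})

test_that("random queries rarely reach the candidate cutoff", {
  set.seed(44)
  db <- db_frame(vapply(rep(300, 50), random_protein, character(1)))
  n_hit <- 0
  for (i in 1:40) {
    q <- random_dna_str(300)
    h <- translated_search(c(q = q), db)
    if (nrow(h) > 0) n_hit <- n_hit + 1
  }
  expect_lte(n_hit / 40, 0.05)
})

test_that("E-values decrease in score and scale with database size", {
  set.seed(45)
  pep <- random_protein(120)
  db1 <- db_frame(pep)
  q <- back_translate_exact(pep)
  h1 <- translated_search(c(q = q), db1, max_evalue = Inf)
  # doubling the database residue count doubles every E-value
  db2 <- rbind(db1, db_frame(random_protein(120))[1, ])
  db2$id <- c("a", "b")
  h2 <- translated_search(c(q = q), db2, max_evalue = Inf)
  top2 <- h2[h2$subject_id == "a", ][1, ]
  expect_equal(top2$evalue / h1$evalue[1], 2, tolerance = 1e-9)
  # E strictly decreasing in raw score at fixed m, n
  m <- scoring_model()
  S <- 1:100
  E <- m$K * 100 * 1000 * exp(-m$lambda * S)
  expect_true(all(diff(E) < 0))
  # bit score identity
  expect_equal(h1$bit_score[1],
               (m$lambda * h1$raw_score[1] - log(m$K)) / log(2))
})

test_that("the top hit matches the brute-force best-diagonal-segment oracle", {
  set.seed(46)
  lut <- scoring_model()$lut
  for (i in 1:10) {
    common <- random_protein(35)
    qpep <- paste0(random_protein(25), common, random_protein(25))
    spep <- paste0(random_protein(40), common, random_protein(15))
    db <- db_frame(spep)
    q <- back_translate_exact(qpep)
    hits <- translated_search(c(q = q), db)
    ora <- oracle_best_segment(qpep, spep, lut)
    expect_equal(hits$raw_score[1], ora$score)
    top <- hits[1, ]
    pep_start <- (top$query_start - (as.integer(substr(top$frame, 2, 2)) - 1)) / 3
    expect_equal(pep_start, ora$qs)
  }
})

test_that("arbitration removes candidates whose best hit is non-viral", {
  set.seed(47)
  vir <- random_protein(150)
  host <- random_protein(150)
  db <- rbind(db_frame(vir, "virus", "virus X"),
              data.frame(id = "h1", seq = host, label = "nonvirus",
                         taxon = "cellular"))
  # query = exact host CDS, but sharing enough with the viral record to be a
  # candidate: build a chimera closer to host
  chim <- paste0(substr(vir, 1, 40), host)
  q <- c(contig1 = back_translate_exact(chim))
  cand <- viral_candidates(q, db)
  expect_equal(nrow(cand), 1)
  arb <- nr_filter(cand, q, db)
  expect_equal(nrow(arb$retained), 0)  # best combined hit is the host protein
  expect_equal(arb$removed_ids, "contig1")
  # a purely viral query is retained
  q2 <- c(contig2 = back_translate_exact(vir))
  cand2 <- viral_candidates(q2, db)
  arb2 <- nr_filter(cand2, q2, db)
  expect_equal(arb2$retained$query_id, "contig2")
  expect_equal(arb2$retained$label, "virus")
})

test_that("exact virus/non-virus ties resolve conservatively to removal", {
  set.seed(48)
  pep <- random_protein(150)
  db <- rbind(
    data.frame(id = "v1", seq = pep, label = "virus", taxon = "virus X"),
    data.frame(id = "n1", seq = pep, label = "nonvirus", taxon = "cellular"))
  q <- c(contig1 = back_translate_exact(pep))
  cand <- viral_candidates(q, db)
  expect_equal(nrow(cand), 1)
  arb <- nr_filter(cand, q, db)
  expect_equal(nrow(arb$retained), 0)
})

test_that("the virome report groups by taxon and applies the detection cutoff", {
  retained <- data.frame(
    query_id = c("c1", "c2", "r1"),
    taxon = c("virus A", "virus B", "virus A"),
    evalue = c(1e-40, 1e-5, 1e-20),
    query_start = c(0L, 0L, 0L), query_end = c(900L, 300L, 150L),
    stringsAsFactors = FALSE)
  rep <- summarize_virome(retained,
                          query_type = c(c1 = "contig", c2 = "contig",
                                         r1 = "read"))
  expect_equal(rep$taxon, c("virus A", "virus B"))
  expect_true(rep$detection[rep$taxon == "virus A"])
  expect_false(rep$detection[rep$taxon == "virus B"])  # 1e-5 is not a detection
  expect_equal(rep$n_reads[rep$taxon == "virus A"], 1)
  # empty input gives an empty report
  expect_equal(nrow(summarize_virome(retained[0, ])), 0)
})
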