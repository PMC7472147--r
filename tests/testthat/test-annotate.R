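# Motif grammar, ORF finding, hallmark panels, species demarcation.

test_that("the motif grammar compiles to the expected token structure", {
  p <- compile_motif("GxxxxGKT/S")
  expect_length(p$tokens, 8)
  expect_equal(p$tokens[[1]], list(type = "EXACT", residues = "G"))
  expect_equal(p$tokens[[2]]$type, "ANY")
  expect_equal(p$tokens[[8]]$residues, c("T", "S"))
  p2 <- compile_motif("uuuuD/ED/E")
  expect_length(p2$tokens, 6)
  expect_equal(p2$tokens[[5]]$residues, c("D", "E"))
  expect_equal(p2$tokens[[6]]$residues, c("D", "E"))
  p3 <- compile_motif("uxxYux-Kxx")
  expect_length(p3$tokens, 10)
  expect_equal(p3$tokens[[7]]$type, "OPTIONAL_ANY")
  # uppercase X is a wildcard position
  p4 <- compile_motif("LXCXE")
  expect_equal(vapply(p4$tokens, `[[`, "", "type"),
               c("EXACT", "ANY", "EXACT", "ANY", "EXACT"))
  # G/A alternative binds to the position before the slash
  p5 <- compile_motif("G/AxxxxGKT/S")
  expect_length(p5$tokens, 8)
  expect_equal(p5$tokens[[1]]$residues, c("G", "A"))
})

test_that("degenerate notations reject dangling slashes and empty patterns", {
  expect_error(compile_motif("GKT/"), "dangling")
  expect_error(compile_motif("/S"), "dangling")
  expect_error(compile_motif("-"), "no mandatory")
})

test_that("all printed hallmark instances match their patterns", {
  expect_equal(nrow(scan_motifs("GPASTGKS", compile_motif("GxxxxGKT/S"))), 1)
  expect_equal(nrow(scan_motifs("VIWIEE", compile_motif("uuuuD/ED/E"))), 1)
  m <- scan_motifs("VLTYTHKQT", compile_motif("uxxYux-Kxx"))
  expect_equal(nrow(m), 1)
  expect_false(m$used_optional)  # the optional position consumes nothing
  expect_equal(nrow(scan_motifs("GPINSGKT", compile_motif("G/AxxxxGKT/S"))), 1)
  expect_equal(nrow(scan_motifs("YLGPG", compile_motif("YLGPG"))), 1)
  expect_equal(nrow(scan_motifs("HPDKGG", compile_motif("HPDKGG"))), 1)
})

test_that("the rolling-circle motif matches offset 1 of TKLHTHLILG, not the bare 9-mer", {
  rcr1 <- compile_motif("xuHuHuuux")
  expect_equal(nrow(scan_motifs("TKLHTHLIL", rcr1)), 0)
  m <- scan_motifs("TKLHTHLILG", rcr1)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1)
  expect_equal(m$window, "KLHTHLILG")
})

test_that("empty proteins and optional-both-ways windows behave", {
  expect_equal(nrow(scan_motifs("", compile_motif("YLGPG"))), 0)
  # a window matching with and without the optional residue reports both
  p <- compile_motif("Kx-K")
  m <- scan_motifs("KAKK", p)
  expect_true(any(m$used_optional) && any(!m$used_optional))
})

test_that("the scanner agrees with per-offset regex evaluation on random proteins", {
  set.seed(51)
  panels <- hallmark_panels()
  pats <- unlist(lapply(panels, `[[`, "patterns"), recursive = FALSE)
  for (i in 1:25) {
    prot <- random_protein(120)
    for (pat in pats) {
      got <- scan_motifs(prot, pat)
      want <- oracle_scan(prot, pat)
      expect_equal(nrow(got), nrow(want),
                   info = sprintf("pattern %s on protein %d", pat$name, i))
      if (nrow(got) > 0) {
        key <- function(d) sort(paste(d$start, d$window, d$used_optional))
        expect_equal(key(got), key(want))
      }
    }
  }
})

test_that("ORF finding reports ATG-initiated stop-terminated frames", {
  o <- find_orfs("ATGAAATAA", min_orf_length = 1)
  expect_equal(nrow(o), 1)
  expect_equal(o$peptide, "MK")
  expect_equal(o$start, 0)
  expect_equal(o$end, 9)
  # threshold excludes short ORFs
  expect_equal(nrow(find_orfs("ATGAAATAA", min_orf_length = 100)), 0)
})

test_that("ORFs mirror coordinates under reverse complement", {
  g <- make_genome(parvovirus_like_spec(), seed = 61)
  o_f <- find_orfs(g$seq, min_orf_length = 150)
  o_r <- find_orfs(rc_str(g$seq), min_orf_length = 150)
  L <- nchar(g$seq)
  expect_setequal(o_f$peptide, o_r$peptide)
  mirrored <- data.frame(start = L - o_r$end, end = L - o_r$start)
  expect_setequal(paste(o_f$start, o_f$end),
                  paste(mirrored$start, mirrored$end))
  # the planted ORFs are recovered verbatim
  expect_true(all(g$orfs$peptide %in% o_f$peptide))
})

test_that("origin-wrapping ORFs are found once and rotation leaves them invariant", {
  g <- make_genome(polyomavirus_like_spec(), seed = 62)
  o <- find_orfs(g$seq, circular = TRUE, min_orf_length = 150)
  expect_true(all(g$orfs$peptide %in% o$peptide))
  st <- g$orfs[g$orfs$name == "ST", ]
  hit <- o[o$peptide == st$peptide, ]
  expect_true(hit$wraps_origin)
  # rotate the circle: same peptide set
  rot <- paste0(substr(g$seq, 1001, nchar(g$seq)), substr(g$seq, 1, 1000))
  o2 <- find_orfs(rot, circular = TRUE, min_orf_length = 150)
  expect_setequal(o$peptide, o2$peptide)
})

test_that("hallmark panels complete on the planted ORFs and fail without YLGPG", {
  g <- make_genome(parvovirus_like_spec(), seed = 63)
  hm <- hallmark_report(g$orfs)
  v <- hm$verdicts
  expect_true(v$complete[v$orf == "NS1" & v$panel == "parvovirus_NS1"])
  expect_true(v$complete[v$orf == "VP1" & v$panel == "parvovirus_VP1"])
  expect_equal(v$verdict[v$orf == "NS1" & v$panel == "parvovirus_NS1"],
               "consistent with parvovirus NS1")
  # remove the calcium loop: VP1 panel incomplete, verdict withheld
  s <- parvovirus_like_spec()
  s$motifs <- s$motifs[s$motifs$name != "pla2_yxgxg", , drop = FALSE]
  g2 <- make_genome(s, seed = 63)
  # guard against an accidental YLGPG in the random fill
  if (!grepl("YLGPG", g2$orfs$peptide[g2$orfs$name == "VP1"])) {
    v2 <- hallmark_report(g2$orfs)$verdicts
    expect_false(v2$complete[v2$orf == "VP1" & v2$panel == "parvovirus_VP1"])
  }
  # the LT panel completes on the polyomavirus LT ORF
  gp <- make_genome(polyomavirus_like_spec(), seed = 64)
  vl <- hallmark_report(gp$orfs)$verdicts
  expect_true(vl$complete[vl$orf == "LT" & vl$panel == "polyomavirus_LT"])
  expect_equal(vl$verdict[vl$orf == "LT" & vl$panel == "polyomavirus_LT"],
               "consistent with polyomavirus LT")
})

test_that("species demarcation applies the strict 85% boundary", {
  set.seed(52)
  ref <- random_protein(1000)
  q449 <- mutate_positions(ref, 551)  # 44.9% identity
  d <- species_demarcation(q449, c(refA = ref))
  expect_lt(d$max_identity, 85)
  expect_true(d$is_new_species_candidate)
  # exactly 85.0%: NOT a candidate (strict inequality)
  q850 <- mutate_positions(ref, 150)
  d850 <- species_demarcation(q850, c(refA = ref))
  expect_equal(d850$max_identity, 85)
  expect_false(d850$is_new_species_candidate)
  # 84.9%: candidate
  q849 <- mutate_positions(ref, 151)
  d849 <- species_demarcation(q849, c(refA = ref))
  expect_equal(d849$max_identity, 84.9)
  expect_true(d849$is_new_species_candidate)
  # identical query: 100%, not a candidate
  d100 <- species_demarcation(ref, c(refA = ref, refB = q449))
  expect_equal(d100$max_identity, 100)
  expect_equal(d100$closest_reference, "refA")
  expect_false(d100$is_new_species_candidate)
})

test_that("GFF3 export writes wrap-around ORFs as two segments", {
  g <- make_genome(polyomavirus_like_spec(), seed = 65)
  f <- tempfile(fileext = ".gff3")
  orfs <- g$orfs
  write_orfs_gff3(orfs, g$id, nchar(g$seq), f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  st_lines <- grep("ID=ST", lines, value = TRUE)
  expect_length(st_lines, 2)  # wrapped ORF split at the origin
  unlink(f)
})
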