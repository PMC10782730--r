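test_that("terminal classification covers all four classes and Met-loss starts", {
  expect_equal(classify_terminal_fragment(1, 20, 400), "N_TERMINAL")
  expect_equal(classify_terminal_fragment(2, 16, 400), "N_TERMINAL")
  expect_equal(classify_terminal_fragment(54, 78, 78), "C_TERMINAL")
  expect_equal(classify_terminal_fragment(1, 78, 78), "FULL_LENGTH")
  expect_equal(classify_terminal_fragment(10, 30, 400), "INTERNAL")
  expect_equal(classify_terminal_fragment(3, 30, 400,
                                          met_loss_window = 2), "INTERNAL")
  expect_error(classify_terminal_fragment(5, 100, 78), "exceeds")
})

test_that("terminal classes partition any peptide set", {
  set.seed(20)
  start <- sample(1:50, 200, replace = TRUE)
  end <- start + sample(6:20, 200, replace = TRUE)
  plen <- pmax(end, 60)
  classes <- classify_terminal_fragment(start, end, plen)
  expect_equal(sum(table(classes)), 200)
  expect_true(all(classes %in% c("N_TERMINAL", "C_TERMINAL",
                                 "FULL_LENGTH", "INTERNAL")))
})

test_that("the N-terminal/acetyl cross-table counts fragments and modifications", {
  precursors <- c(P1 = strrep("M", 100), P2 = strrep("A", 50))
  rec <- data.frame(
    peptide_id = c("a", "b", "c", "d"),
    sequence = c(strrep("M", 10), strrep("M", 8), strrep("A", 10),
                 strrep("A", 9)),
    accession = c("P1", "P1", "P2", "P2"),
    start = c(1, 2, 20, 42), end = c(10, 9, 29, 50),
    modifications = c("1:Acetyl", "", "1:acetyl", ""),
    stringsAsFactors = FALSE)
  res <- summarize_terminal_and_acetyl(rec, precursors)
  expect_equal(res$n_terminal, 2)           # a and b
  expect_equal(res$n_acetylated_nterm, 1)   # a only
  expect_equal(unname(res$counts["acetyl", "all"]), 2)
  expect_equal(unname(res$percent["acetyl", "N_terminal"]), 50)
  # empty input: all-zero table
  empty <- summarize_terminal_and_acetyl(rec[0, ], precursors)
  expect_equal(sum(empty$counts), 0)
})

test_that("cleavage contexts index the precursor correctly and pad at termini", {
  precursors <- c(X = "MAAKRGGGGW")
  rec <- data.frame(peptide_id = "p1", sequence = "GGGG", accession = "X",
                    start = 6, end = 9, stringsAsFactors = FALSE)
  ctx <- extract_cleavage_contexts(rec, precursors)
  expect_equal(nrow(ctx), 2)
  n_side <- ctx$context[ctx$side == "N"]
  c_side <- ctx$context[ctx$side == "C"]
  # N-side: P4..P1 = AAKR (positions 2-5), P1'..P4' = GGGG
  expect_equal(n_side, "AAKRGGGG")
  expect_equal(substr(n_side, 4, 4), "R")        # P1
  # C-side: P4..P1 = GGGG (6-9), P1' = W (10), then gaps
  expect_equal(c_side, "GGGGW---")
  expect_equal(substr(c_side, 5, 5), "W")        # P1'
})

test_that("contexts at protein termini carry gaps, never invented residues", {
  precursors <- c(X = "MKRAAAAGGG")
  rec <- data.frame(peptide_id = c("nt", "ct"),
                    sequence = c("MKRAAAA", "AAAAGGG"),
                    accession = "X", start = c(1, 4), end = c(7, 10),
                    stringsAsFactors = FALSE)
  ctx <- extract_cleavage_contexts(rec, precursors)
  expect_equal(ctx$context[ctx$peptide_id == "nt" & ctx$side == "N"],
               "----MKRA")
  expect_equal(ctx$context[ctx$peptide_id == "ct" & ctx$side == "C"],
               "AGGG----")
  # exactly 2 contexts per valid peptide
  expect_equal(nrow(ctx), 4)
})

test_that("mismatched peptides are skipped from context extraction with a warning", {
  precursors <- c(X = "MAAAAAAAAA")
  rec <- data.frame(peptide_id = c("ok", "bad"),
                    sequence = c("AAAA", "GGGG"), accession = "X",
                    start = c(2, 2), end = c(5, 5), stringsAsFactors = FALSE)
  expect_warning(ctx <- extract_cleavage_contexts(rec, precursors), "skipped")
  expect_setequal(unique(ctx$peptide_id), "ok")
})

test_that("residue frequency columns sum to one with gaps excluded", {
  ctx <- data.frame(peptide_id = c("a", "b"), side = "N",
                    context = c("AAKRGGGG", "---KWGGG"),
                    stringsAsFactors = FALSE)
  fm <- residue_frequency_matrix(ctx, side = "N")
  expect_equal(unname(colSums(fm)), rep(1, 8))
  # single context with K at P1
  fm1 <- residue_frequency_matrix(ctx[2, ], side = "N")
  expect_equal(unname(fm1["K", "P1"]), 1)
  expect_error(residue_frequency_matrix(ctx[0, ]), "no cleavage contexts")
})

test_that("a 70% K/R P1 bias is recovered from a large synthetic peptidome", {
  cfg <- synth_config(seed = 21, n_peptides = 5000, n_precursors = 200,
                      p1_basic_prob = 0.7)
  precursors <- generate_precursors(cfg)
  rec <- simulate_peptidome(cfg, precursors)
  ctx <- extract_cleavage_contexts(rec, precursors)
  internal <- rec$start > 2
  # restrict to internal peptides: N-terminal fragments have no upstream P1
  ctxN <- ctx[ctx$side == "N" & ctx$peptide_id %in% rec$peptide_id[internal], ]
  fmN <- residue_frequency_matrix(ctxN, side = "N")
  expect_equal(unname(fmN["K", "P1"] + fmN["R", "P1"]), 0.70,
               tolerance = 0.03 / 0.70)
})

test_that("p1_basic_prob = 1 forces K or R before every internal peptide", {
  cfg <- synth_config(seed = 22, n_peptides = 300, n_precursors = 50,
                      p1_basic_prob = 1)
  precursors <- generate_precursors(cfg)
  rec <- simulate_peptidome(cfg, precursors)
  internal <- rec[rec$start > 2, ]
  p1 <- substr(precursors[internal$accession], internal$start - 1,
               internal$start - 1)
  expect_true(all(p1 %in% c("K", "R")))
})

test_that("domain overlap classes follow interval arithmetic", {
  domains <- data.frame(accession = "S1", domain_name = "secretoneurin",
                        start = 184, end = 216)
  rec <- data.frame(
    peptide_id = c("in", "part", "out", "othr"),
    sequence = c(strrep("A", 12), strrep("A", 11), strrep("A", 11),
                 strrep("A", 12)),
    accession = c("S1", "S1", "S1", "S2"),
    start = c(184, 180, 10, 184), end = c(195, 190, 20, 195),
    stringsAsFactors = FALSE)
  ov <- map_known_domain_overlaps(rec, domains)
  get <- function(id) ov$overlap[ov$peptide_id == id]
  expect_equal(get("in"), "CONTAINED")
  expect_equal(get("part"), "PARTIAL")
  expect_equal(get("out"), "NONE")
  expect_equal(length(get("othr")), 0)   # different precursor: no comparison
  # translation invariance
  rec2 <- rec; rec2$start <- rec$start + 7; rec2$end <- rec$end + 7
  dom2 <- domains; dom2$start <- dom2$start + 7; dom2$end <- dom2$end + 7
  expect_equal(map_known_domain_overlaps(rec2, dom2)$overlap, ov$overlap)
})

test_that("dibasic flanks require K/R pairs on both sides", {
  # positions 175-176 KR and 200-201 KR flank a 177-199 peptide
  seq <- paste0(strrep("A", 174), "KR", strrep("G", 23), "KR", strrep("A", 20))
  precursors <- c(PENK = seq)
  rec <- data.frame(
    peptide_id = c("hit", "ka", "nterm"),
    sequence = c(strrep("G", 23), strrep("G", 23), substr(seq, 1, 10)),
    accession = "PENK",
    start = c(177, 177, 1), end = c(199, 199, 10),
    stringsAsFactors = FALSE)
  res <- flanked_by_dibasic(rec, precursors)
  expect_true(res$dibasic_flanked[1])
  expect_equal(res$upstream_pair[1], "KR")
  expect_equal(res$downstream_pair[1], "KR")
  # upstream pair "KA" -> false
  seq2 <- paste0(strrep("A", 173), "KA", strrep("G", 24), "KR", strrep("A", 20))
  res2 <- flanked_by_dibasic(rec[1, ], c(PENK = seq2))
  expect_false(res2$dibasic_flanked[1])
  # start at 1: no upstream pair exists
  expect_false(res$dibasic_flanked[3])
  expect_true(is.na(res$upstream_pair[3]))
})

test_that("length summaries report mean, median and range", {
  res <- length_distribution(c(7L))
  expect_equal(res$mean, 7)
  rec <- data.frame(peptide_id = c("a", "b"),
                    sequence = c("AAAAAAA", "AAAAAAAAAAA"),
                    accession = "X", start = c(1, 1), end = c(7, 11))
  res2 <- length_distribution(rec)
  expect_equal(res2$mean, 9)
  expect_equal(res2$range, c(7, 11))
})
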