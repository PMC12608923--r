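test_that("the degenerate motif grammar compiles literals, wildcards and alternations", {
  m <- compile_motif("MGNxxxx[K/R]", anchored = TRUE)
  expect_length(m$positions, 8L)
  expect_setequal(m$positions[[8]], c("K", "R"))
  expect_equal(m$positions[[1]], "M")
  expect_length(m$positions[[4]], 20L)

  m2 <- compile_motif("MATL[M/T/A]A[F/T]")
  expect_length(m2$positions, 7L)
  expect_setequal(m2$positions[[5]], c("M", "T", "A"))

  expect_length(compile_motif("x")$positions[[1]], 20L)

  expect_error(compile_motif("MGN[K/R"), "offset 4")
  expect_error(compile_motif("A[/]B"), "empty alternation")
  expect_error(compile_motif("mGN"), "offset 1")
  expect_error(compile_motif("A[B/1]"), "alternation")
})

test_that("motif scanning matches a brute-force substring oracle", {
  patterns <- c("MGNxxxx[K/R]", "MGNxxxxK", "FxxxW", "MATL[M/T/A]A[F/T]",
                "IxI", "VxV", "RRx[A/G]", "RRxS")
  set.seed(31)
  seqs <- c(
    replicate(25, random_protein(sample(5:50, 1))),
    replicate(10, random_protein(sample(8:50, 1),
                                 alphabet = c("M", "G", "N", "K", "R", "A",
                                              "S", "F", "W", "I", "V", "T", "L"))),
    "MGNAAATKFAQLW", "RRGSRRASRRVS", "MATLMAFT"
  )
  for (p in patterns) {
    motif <- compile_motif(p)
    for (s in seqs) {
      got <- find_motif(s, motif)$start
      expect_identical(got, brute_motif_starts(s, p),
                       label = paste(p, "on", s))
    }
  }
})

test_that("anchoring, wildcard semantics and X behave as specified", {
  anchored_k <- compile_motif("MGNxxxxK", anchored = TRUE)
  anchored_kr <- compile_motif("MGNxxxx[K/R]", anchored = TRUE)
  hit <- find_motif("MGNAAATK", anchored_k)
  expect_equal(c(hit$start, hit$end), c(1L, 8L))
  expect_equal(find_motif("AFAAAWA", "FxxxW")$start, 2L)
  # K-only motif misses R; the alternation catches it
  expect_equal(nrow(find_motif("MGNAAATR", anchored_k)), 0L)
  expect_equal(nrow(find_motif("MGNAAATR", anchored_kr)), 1L)
  # anchored motifs never match away from residue 1
  expect_equal(nrow(find_motif("AMGNAAATK", anchored_k)), 0L)
  # X never satisfies a literal nor the wildcard
  expect_equal(nrow(find_motif("MGNAXATK", anchored_k)), 0L)
  expect_equal(nrow(find_motif("MGXAAATK", anchored_k)), 0L)
})

test_that("any sequence matching anchored MGNxxxxK also matches MGNxxxx[K/R]", {
  set.seed(13)
  anchored_k <- compile_motif("MGNxxxxK", anchored = TRUE)
  anchored_kr <- compile_motif("MGNxxxx[K/R]", anchored = TRUE)
  for (i in 1:200) {
    s <- paste0("MGN", random_protein(4), sample(c("K", "R", "A"), 1),
                random_protein(5))
    if (nrow(find_motif(s, anchored_k)) > 0) {
      expect_gt(nrow(find_motif(s, anchored_kr)), 0)
    }
  }
})

test_that("autoinhibitory-site typing distinguishes RI, RII, ambiguous and none", {
  expect_equal(classify_ai_site("EIRRVSV")$class, "RII")
  expect_equal(classify_ai_site("ETRRRGA")$class, "RI")
  expect_equal(classify_ai_site("KAQSA")$class, "none")
  both <- classify_ai_site("AARRAGAARRTSAA")
  expect_equal(both$class, "ambiguous")
  expect_true(nrow(both$ri_hits) > 0 && nrow(both$rii_hits) > 0)
})

test_that("the autoinhibitory scan is restricted to the annotated linker", {
  set.seed(77)
  # RRxS inside the cAMP-binding domain must not be seen
  seq <- paste0(random_protein(10), "RRGA", random_protein(36),
                "AARRSSAA", random_protein(42))
  seq <- sub("^..", "MS", seq)
  rec <- make_records(r = seq)
  ann <- make_domains("r", c("DD", "cAMP_binding"), c(2, 51), c(8, 100))
  res <- classify_ai_site(rec, annotations = ann)
  expect_equal(res$region, c(9L, 50L))
  expect_equal(res$class, "RI")
  # without annotations the whole sequence is scanned (with a warning if
  # annotations lack a cAMP domain)
  expect_equal(classify_ai_site(seq)$class, "ambiguous")
})

test_that("consensus emits residues, alternations, wildcards and gaps per the thresholds", {
  aln <- c(a = "G", b = "G", c = "G", d = "G")
  expect_equal(as.character(consensus(aln)), "G")

  # 10 K + 10 R in one column -> [K/R]
  rows <- setNames(c(rep("K", 10), rep("R", 10)), paste0("r", 1:20))
  expect_equal(as.character(consensus(rows)), "[K/R]")

  # 20 distinct residues -> x
  rows <- setNames(AA20_TEST, paste0("r", 1:20))
  expect_equal(as.character(consensus(rows)), "x")

  # gap-majority column -> '-'
  rows <- setNames(c("A", "-", "-", "-"), paste0("r", 1:4))
  expect_equal(as.character(consensus(rows)), "-")

  expect_error(consensus(character(0)), "empty")
})

test_that("consensus is invariant to row order and ties break alphabetically", {
  set.seed(3)
  mat <- replicate(12, sample(c("A", "C", "D", "-"), 8, replace = TRUE))
  rows <- setNames(apply(mat, 2, paste, collapse = ""), paste0("r", 1:12))
  shuffled <- rows[sample(seq_along(rows))]
  expect_equal(as.character(consensus(rows)), as.character(consensus(shuffled)))
  # equal-frequency pair: alphabetically first named first
  rows <- setNames(c(rep("R", 5), rep("K", 5)), paste0("r", 1:10))
  expect_equal(as.character(consensus(rows)), "[K/R]")
})

test_that("glycine-rich detection counts correctly and respects the span", {
  tract <- "GGSGGGAGGGSGGGAGGGSGGGAGG"  # 25 aa, 19 G
  expect_equal(sum(strsplit(tract, "")[[1]] == "G"), 19L)
  regions <- glycine_rich_regions(tract, window = 25, min_frac = 0.4)
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$gly_fraction, 19 / 25)

  expect_equal(nrow(glycine_rich_regions(strrep("A", 40))), 0L)

  expect_warning(
    empty <- glycine_rich_regions(random_protein(10), window = 25),
    "shorter")
  expect_equal(nrow(empty), 0L)
})

test_that("lowering the glycine threshold never removes reported coverage", {
  set.seed(21)
  for (i in 1:20) {
    s <- paste(sample(c("G", "A", "S"), 120, replace = TRUE,
                      prob = c(0.45, 0.3, 0.25)), collapse = "")
    strict <- glycine_rich_regions(s, window = 25, min_frac = 0.5)
    loose <- glycine_rich_regions(s, window = 25, min_frac = 0.35)
    if (nrow(strict) > 0) {
      covered_strict <- unlist(Map(seq, strict$start, strict$end))
      covered_loose <- unlist(Map(seq, loose$start, loose$end))
      expect_true(all(covered_strict %in% covered_loose))
    }
  }
})

test_that("the N-terminal region ends just before the first core domain", {
  rec <- make_records(n1 = random_protein(400))
  ann <- make_domains("n1", "kinase", 120, 370)
  expect_equal(unname(nterm_region(rec, ann)), c(1L, 119L))

  ann2 <- make_domains("n1", "kinase", 1, 250)
  r2 <- nterm_region(rec, ann2)
  expect_true(isTRUE(attr(r2, "empty")))

  ann3 <- make_domains("n1", c("cAMP_binding", "cAMP_binding"),
                       c(150, 280), c(260, 390))
  expect_equal(unname(nterm_region(rec, ann3)), c(1L, 149L))

  expect_error(nterm_region(rec, make_domains("n1", "DD", 5, 50)),
               "kinase or cAMP")
})

test_that("the standard motif report finds planted features and stays silent otherwise", {
  s <- paste0("MGNAAATKFAQLWGG", random_protein(30, c("A", "C", "D", "E")))
  rep1 <- motif_report(s)
  get <- function(chk) rep1[rep1$check == chk, ]
  expect_true(get("G2")$present)
  expect_equal(get("MGNxxxxK")$start, 1L)
  expect_equal(get("FxxxW")$start, 9L)

  rep2 <- motif_report(strrep("A", 40))
  expect_false(any(rep2$present))

  # chordate-style start with arginine accepted by the alternation only
  rep3 <- motif_report("MGNAAAARKFAQLW")
  expect_true(rep3$present[rep3$check == "MGNxxxx[K/R]"])
  expect_false(rep3$present[rep3$check == "MGNxxxxK"])
})
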