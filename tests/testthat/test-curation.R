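test_that("reference filter applies the e-value, identity and domain thresholds", {
  # enumerate the full threshold grid; oracle is the direct inequality
  evalues <- c(1e-60, 1e-70, 1e-80)
  idents <- c(55, 60, 75)
  n_doms <- c(0L, 1L, 2L)
  grid <- expand.grid(e = evalues, p = idents, d = n_doms)
  ids <- sprintf("s%02d", seq_len(nrow(grid)))
  hits <- make_hits(ids, grid$e, grid$p)
  domains <- do.call(rbind, lapply(which(grid$d > 0L), function(i) {
    make_domains(rep(ids[i], grid$d[i]), "cAMP_binding",
                 start = seq(1, by = 150, length.out = grid$d[i]),
                 end = seq(120, by = 150, length.out = grid$d[i]))
  }))
  qc <- filter_reference_hits(hits, domains, filter_config())
  expected_keep <- grid$e <= 1e-70 & grid$p > 60 & grid$d >= 1L
  expect_setequal(qc$kept, ids[expected_keep])
  # partition property
  expect_setequal(c(qc$kept, qc$rejected$id), ids)
  expect_length(intersect(qc$kept, qc$rejected$id), 0L)
  # boundary semantics: e-value inclusive, identity strict
  expect_true(ids[grid$e == 1e-70 & grid$p == 75 & grid$d == 1L] %in% qc$kept)
  expect_true(ids[grid$e == 1e-80 & grid$p == 60 & grid$d == 1L] %in%
                qc$rejected$id[qc$rejected$reason == "identity"])
  # subject with hits but no annotation row at all
  unannotated_good <- ids[grid$e <= 1e-70 & grid$p > 60 & grid$d == 0L]
  details <- qc$rejected$detail[match(unannotated_good, qc$rejected$id)]
  expect_true(all(details == "no annotations"))
})

test_that("reference filter rejects a good hit whose e-value is too large", {
  hits <- make_hits("s1", 1e-60, 75)
  domains <- make_domains("s1", "kinase", 10, 200)
  qc <- filter_reference_hits(hits, domains)
  expect_equal(qc$rejected$reason, "evalue")
  qc2 <- filter_reference_hits(make_hits("s1", 1e-80, 75), domains)
  expect_equal(qc2$kept, "s1")
})

test_that("transcriptome filter keeps hits at or below 1e-120 only", {
  hits <- make_hits(c("a", "b", "c"), c(1e-150, 1e-119, 1e-120))
  qc <- filter_crustome_hits(hits)
  expect_setequal(qc$kept, c("a", "c"))  # the bound is inclusive
  expect_equal(qc$rejected$id, "b")
})

test_that("domain-completeness filter counts only complete domains", {
  recs <- make_records(r1 = random_protein(400), r2 = random_protein(400),
                       r3 = random_protein(400))
  domains <- rbind(
    make_domains("r1", "cAMP_binding", 100, 220),                 # 1 complete
    make_domains("r2", c("cAMP_binding", "cAMP_binding"),
                 c(100, 250), c(220, 380)),                       # 2 complete
    make_domains("r3", c("cAMP_binding", "cAMP_binding"),
                 c(100, 250), c(220, 380), complete = c(TRUE, FALSE))
  )
  qc <- filter_domain_completeness(recs, domains, 2L)
  expect_equal(qc$kept, "r2")
  expect_setequal(qc$rejected$id, c("r1", "r3"))
  expect_setequal(filter_domain_completeness(recs, domains, 0L)$kept,
                  recs$id)
})

test_that("filters are idempotent and monotone in their thresholds", {
  set.seed(11)
  recs <- do.call(make_records,
                  as.list(setNames(replicate(30, random_protein(100)),
                                   sprintf("m%02d", 1:30))))
  gh <- generate_hit_table(recs, keep = rep(c(TRUE, FALSE), 15),
                           decoy_count = 5, seed = 4)
  qc <- filter_crustome_hits(gh$hits)
  # idempotence: filtering the kept set changes nothing
  again <- filter_crustome_hits(gh$hits[gh$hits$subject_id %in% qc$kept, ])
  expect_setequal(again$kept, qc$kept)
  expect_equal(nrow(again$rejected), 0L)
  # monotonicity: relaxing the threshold never shrinks the kept set
  relaxed <- filter_crustome_hits(gh$hits, filter_config(crustome_max_evalue = 1e-100))
  expect_true(all(qc$kept %in% relaxed$kept))
  # partition at every configuration
  for (ce in c(1e-180, 1e-120, 1e-80)) {
    q <- filter_crustome_hits(gh$hits, filter_config(crustome_max_evalue = ce))
    expect_setequal(c(q$kept, q$rejected$id), unique(gh$hits$subject_id))
  }
})

test_that("long-branch flagging needs a real outlier, not just spread", {
  # star-like tree with equal terminal branches: nothing to flag
  tr <- ape::rcoal(12)
  pend <- tr$edge[, 2] <= 12
  tr$edge.length[pend] <- 0.3
  expect_equal(nrow(flag_long_branches(tr)), 0L)

  # one 100x terminal branch on a 20-tip tree: exactly that tip flagged
  tr <- ape::rcoal(20)
  pend <- which(tr$edge[, 2] <= 20)
  tr$edge.length[pend] <- 0.1
  victim <- tr$tip.label[tr$edge[pend[7], 2]]
  tr$edge.length[pend[7]] <- 10
  fl <- flag_long_branches(tr, k = 5)
  expect_equal(fl$tip_id, victim)
  # direct inequality oracle
  lens <- tr$edge.length[pend]
  expect_true(10 > 5 * median(lens))

  # k = Inf disables flagging entirely
  expect_equal(nrow(flag_long_branches(tr, k = Inf)), 0L)
  # too few tips for a null spread
  expect_error(flag_long_branches(ape::rcoal(5)), "review")
})

test_that("taxon-inconsistency flags match a brute-force patristic check", {
  skip_if_not_installed("igraph")
  set.seed(5)
  tr <- ape::rcoal(6)
  taxa <- setNames(c("Arthropoda", "Arthropoda", "Arthropoda",
                     "Nematoda", "Nematoda", "Nematoda"), tr$tip.label)
  d_oracle <- brute_patristic(tr)
  m <- 3L
  oracle_flags <- character(0)
  for (tip in tr$tip.label) {
    others <- setdiff(tr$tip.label, tip)
    nb <- others[order(d_oracle[tip, others], others)][seq_len(m)]
    if (sum(taxa[nb] == taxa[tip]) < 2L) oracle_flags <- c(oracle_flags, tip)
  }
  got <- flag_taxon_inconsistency(tr, taxa, m = m)
  expect_setequal(got$tip_id, oracle_flags)
})

test_that("a foreign tip inside a clean clade is flagged with its neighbors' phylum", {
  sim <- generate_contaminated_tree(30, n_long = 0, n_mislabeled = 1, seed = 9)
  got <- flag_taxon_inconsistency(sim$tree, sim$taxa, m = 5)
  expect_equal(got$tip_id, sim$mislabeled_tips)
  neighbor <- unique(strsplit(got$neighbor_phyla, ",")[[1]])
  expect_false(got$own_phylum %in% neighbor)

  # clean two-clade tree: no flags at all
  clean <- generate_contaminated_tree(30, n_long = 0, n_mislabeled = 0, seed = 9)
  expect_equal(nrow(flag_taxon_inconsistency(clean$tree, clean$taxa)), 0L)
})

test_that("degenerate m = 1 always flags and missing taxa are reported by tip", {
  set.seed(2)
  tr <- ape::rcoal(8)
  taxa <- setNames(rep("Arthropoda", 8), tr$tip.label)
  # with m = 1 no tip can reach 2 matching neighbors
  expect_equal(nrow(flag_taxon_inconsistency(tr, taxa, m = 1L)), 8L)
  expect_error(flag_taxon_inconsistency(tr, taxa[-1], m = 3L),
               tr$tip.label[1])
})

test_that("gap-heavy alignment columns are trimmed", {
  aln <- c(r1 = "AC-DE", r2 = "AC-DF", r3 = "A--DE", r4 = "ACWD-")
  trimmed <- trim_alignment_gaps(aln, max_gap_frac = 0.5)
  expect_equal(unname(trimmed), c("ACDE", "ACDF", "A-DE", "ACD-"))
})
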