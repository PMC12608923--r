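rec_with <- function(id, residues) {
  seq_records(id, residues, species = "testsp", phylum = "Arthropoda",
              source = "synthetic")
}

test_that("domain architecture resolves the PKA/PKC families in rule order", {
  set.seed(41)
  filler <- function(n) random_protein(n)

  cpkc <- rec_with("c1", filler(650))
  ann <- make_domains("c1", c("C1", "C2", "kinase"),
                      c(40, 120, 350), c(90, 210, 600))
  expect_equal(classify_family(cpkc, ann)$family, "cPKC")

  pkn <- rec_with("p1", filler(900))
  ann <- make_domains("p1", c("HR1", "HR1", "HR1", "C2", "kinase"),
                      c(10, 100, 190, 300, 600), c(80, 170, 260, 400, 850))
  expect_equal(classify_family(pkn, ann)$family, "PKN")

  apkc <- rec_with("a1", filler(600))
  ann <- make_domains("a1", c("PB1", "C1", "kinase"),
                      c(20, 130, 330), c(100, 180, 570))
  expect_equal(classify_family(apkc, ann)$family, "aPKC")

  pkar <- rec_with("r1", filler(400))
  ann <- make_domains("r1", c("DD", "cAMP_binding", "cAMP_binding"),
                      c(5, 100, 250), c(50, 220, 380))
  res <- classify_family(pkar, ann)
  expect_equal(res$family, "PKA-R")

  pkac <- rec_with("k1", paste0("MGNAAATK", filler(52), filler(260)))
  ann <- make_domains("k1", "kinase", 60, 310)
  res <- classify_family(pkac, ann)
  expect_equal(res$family, "PKA-C")
  expect_equal(res$confidence, "architecture+motif")

  # kinase-only without motif evidence stays unknown without a panel
  bare <- rec_with("b1", strrep("A", 320))
  ann <- make_domains("b1", "kinase", 60, 310)
  expect_equal(classify_family(bare, ann)$family, "unknown")
})

test_that("novel PKCs (C2 before C1) are split delta/epsilon by nearest reference", {
  classes <- default_sim_classes()
  panel <- template_panel(classes)
  d0 <- generate_dataset(sim_spec(classes, n_species = 1, n_per_class = 1,
                                  mu = 0.05, indel_rate = 0, seed = 6))
  for (lbl in c("nPKC-delta-like", "nPKC-epsilon-like")) {
    id <- d0$truth$id[d0$truth$class == lbl]
    rec <- d0$records[d0$records$id == id, ]
    res <- classify_family(rec, d0$domains, panel = panel)
    expect_equal(res$family, lbl)
  }
  # without a panel the call stays at the architecture level
  id <- d0$truth$id[d0$truth$class == "nPKC-delta-like"]
  rec <- d0$records[d0$records$id == id, ]
  expect_equal(classify_family(rec, d0$domains)$family, "nPKC")
})

test_that("contradictory overlapping annotations are an error and row order is irrelevant", {
  rec <- rec_with("x1", strrep("A", 700))
  bad <- make_domains("x1", c("C1", "C2", "kinase"),
                      c(40, 60, 350), c(120, 130, 600))
  expect_error(classify_family(rec, bad), "contradictory")

  set.seed(43)
  ann <- make_domains("x1", c("C1", "C2", "kinase"),
                      c(40, 120, 350), c(90, 210, 600))
  shuffled <- ann[sample(nrow(ann)), ]
  expect_equal(classify_family(rec, ann)$family,
               classify_family(rec, shuffled)$family)
})

test_that("PKA-C subtypes follow the GLY > D1 > ancestral priority", {
  set.seed(47)
  core <- random_protein(260)
  kin_ann <- function(id, nterm_len) {
    make_domains(id, "kinase", nterm_len + 10, nterm_len + 250)
  }

  c1 <- rec_with("c_1", paste0("MGNAAATK", random_protein(52), core))
  expect_equal(classify_pka_c_isoform(c1, kin_ann("c_1", 60)), "C_1")

  gly_nterm <- paste0("MS", strrep("GGGGA", 6), random_protein(28))
  cg <- rec_with("c_g", paste0(gly_nterm, core))
  expect_equal(classify_pka_c_isoform(cg, kin_ann("c_g", 60)), "C_GLY")

  cd <- rec_with("c_d", paste0("MS", random_protein(27), "MATLMAF",
                               random_protein(24), core))
  expect_equal(classify_pka_c_isoform(cd, kin_ann("c_d", 60)), "C_D1")

  # both GLY tract and MATL motif: the tract wins
  both <- rec_with("c_b", paste0("MS", strrep("GGGGA", 6), "MATLMAF",
                                 random_protein(21), core))
  expect_equal(classify_pka_c_isoform(both, kin_ann("c_b", 60)), "C_GLY")

  plain <- rec_with("c_p", paste0("MS", random_protein(58), core))
  expect_equal(classify_pka_c_isoform(plain, kin_ann("c_p", 60)),
               "other-arthropod")
})

test_that("PKA-R subtyping combines AI site, glycine tract and D/D evidence", {
  set.seed(53)
  camp <- random_protein(280)
  r_ann <- function(id, nterm_len, dd = TRUE) {
    d <- make_domains(id, c("cAMP_binding", "cAMP_binding"),
                      nterm_len + c(1, 151), nterm_len + c(120, 270))
    if (dd) d <- rbind(make_domains(id, "DD", 6, 50), d)
    d
  }
  clean <- function(n) gsub("R", "A", random_protein(n))

  # RII + glycine-rich N-terminal -> RII_GLY
  nt <- paste0("MS", clean(3), strrep("G", 30), clean(15), "EIRRVSV",
               clean(23))  # 80 aa
  rg <- rec_with("r_g", paste0(nt, camp))
  res <- classify_pka_r(rg, r_ann("r_g", 80))
  expect_equal(res$subtype, "RII_GLY")

  # RI pseudosubstrate
  nt <- paste0("MS", clean(58), "EIRRAGV", clean(13))  # 80 aa
  ri <- rec_with("r_i", paste0(nt, camp))
  res <- classify_pka_r(ri, r_ann("r_i", 80))
  expect_equal(res$subtype, "RI")

  # truncated subunit without a D/D keeps its type, evidence notes it
  res2 <- classify_pka_r(ri, r_ann("r_i", 80, dd = FALSE))
  expect_equal(res2$subtype, "RI")
  expect_true(any(grepl("no identifiable dimerization",
                        res2$evidence$outcome)))

  # both motifs present in the linker -> unresolved, both positions recorded
  nt <- paste0("MS", clean(48), "RRAGA", clean(5), "RRTS", clean(16))  # 80 aa
  amb <- rec_with("r_a", paste0(nt, camp))
  res3 <- classify_pka_r(amb, r_ann("r_a", 80))
  expect_equal(res3$subtype, "R-unresolved")
})

test_that("sequences typed RI carry no RRxS in their linker unless flagged ambiguous", {
  d <- generate_dataset(sim_spec(n_species = 4, n_per_class = 2,
                                 mu = 0.05, seed = 8))
  r_ids <- d$truth$id[d$truth$family == "PKA-R"]
  for (id in r_ids) {
    rec <- d$records[d$records$id == id, ]
    res <- classify_pka_r(rec, d$domains)
    if (res$subtype == "RI") {
      expect_equal(nrow(res$ai$rii_hits), 0L)
    }
  }
})

test_that("nearest reference recovers labels, breaks ties lexicographically", {
  set.seed(59)
  ex1 <- random_protein(120)
  ex2 <- random_protein(120)
  panel <- reference_panel(
    make_records(zeta = ex1, alpha = ex1, beta = ex2),
    c("L1", "L1", "L2"))

  rec <- make_records(q = ex2)
  nr <- nearest_reference(rec, panel)
  expect_equal(nr$label, "L2")
  expect_equal(c(nr$identity, nr$similarity), c(100, 100))

  # exact tie between two exemplars: smaller id wins and the tie is flagged
  rec2 <- make_records(q = ex1)
  nr2 <- nearest_reference(rec2, panel)
  expect_equal(nr2$exemplar_id, "alpha")
  expect_true(nr2$tie)

  # 5% mutated copy of one exemplar is pulled back to its label
  chars <- strsplit(ex1, "")[[1]]
  mut <- sample(120, 6)
  for (i in mut) chars[i] <- sample(setdiff(AA20_TEST, chars[i]), 1)
  rec3 <- make_records(q = paste(chars, collapse = ""))
  expect_equal(nearest_reference(rec3, panel)$label, "L1")

  expect_error(nearest_reference(rec, panel[0, ]), "empty")
})

test_that("decapod names are issued per species series in characterization order", {
  reg <- create_registry()
  expect_equal(assign_decapod_name("cPKC", species = "spA", registry = reg),
               "cPKC_D1")
  expect_equal(assign_decapod_name("PKN", species = "spA", registry = reg),
               "PKN_D1")
  expect_equal(assign_decapod_name("PKN", species = "spA", registry = reg),
               "PKN_D2")
  expect_equal(assign_decapod_name("PKN", species = "spA", registry = reg),
               "PKN_D3")
  # another species starts its own series
  expect_equal(assign_decapod_name("PKN", species = "spB", registry = reg),
               "PKN_D1")
  expect_equal(assign_decapod_name("PKA-C", "C_GLY", "spA", reg),
               "PKA-C_GLY1")
  expect_equal(assign_decapod_name("PKA-C", "C_GLY", "spA", reg),
               "PKA-C_GLY2")
  expect_equal(assign_decapod_name("PKA-C", "C_1", "spA", reg), "PKA-C_1")
  expect_equal(assign_decapod_name("nPKC-delta-like", species = "spA",
                                   registry = reg), "nPKC_D1\u03b4")
  expect_equal(assign_decapod_name("nPKC-epsilon-like", species = "spA",
                                   registry = reg), "nPKC_D1\u03b5")
  expect_equal(assign_decapod_name("PKA-R", "RII_GLY", "spA", reg),
               "PKA-RII_GLY")
  expect_error(assign_decapod_name("unknown", species = "spA", registry = reg),
               "unknown")
})

test_that("a classified dataset never repeats a name within a species", {
  d <- generate_dataset(sim_spec(n_species = 3, n_per_class = 2, mu = 0.02,
                                 seed = 14))
  cl <- suppressWarnings(
    classify_dataset(d$records, d$domains, panel = template_panel()))
  named <- cl[!is.na(cl$decapod_name), ]
  combos <- paste(named$species, named$decapod_name)
  expect_equal(anyDuplicated(combos), 0L)
})

test_that("isoforms of one species share an identical catalytic core and family", {
  d <- generate_dataset(sim_spec(n_species = 2, n_per_class = 1, mu = 0.05,
                                 seed = 16))
  cl <- suppressWarnings(
    classify_dataset(d$records, d$domains, panel = template_panel(),
                     name_isoforms = FALSE))
  for (sp in unique(d$truth$species)) {
    ids <- d$truth$id[d$truth$species == sp & d$truth$family == "PKA-C"]
    cores <- vapply(ids, function(id) {
      rec <- d$records[d$records$id == id, ]
      kin <- d$domains[d$domains$seq_id == id &
                         d$domains$domain_name == "kinase", ]
      # from the beginning of the catalytic domain to the C-terminus
      substring(rec$residues, kin$start)
    }, character(1))
    expect_equal(length(unique(cores)), 1L)
    expect_setequal(unique(cl$family[cl$seq_id %in% ids]), "PKA-C")
  }
})
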