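#' Synthetic PKA/PKC dataset specification
#'
#' Bundles the generator settings: the class templates, how many species
#' and how many sequences per class per species to emit, the per-residue
#' substitution rate, the single-residue indel rate, and the seed.
#'
#' @param classes class templates, see [default_sim_classes()].
#' @param n_species number of synthetic decapod species.
#' @param n_per_class sequences per class per species.
#' @param mu per-residue substitution rate, in `[0, 0.3]`.
#' @param indel_rate per-residue single-position indel rate.
#' @param seed integer seed recorded in the output metadata.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(classes = default_sim_classes(), n_species = 10L,
                     n_per_class = 2L, mu = 0.05, indel_rate = 0.005,
                     seed = 1L) {
  if (mu < 0 || mu > 0.3) {
    stop("substitution rate mu = ", mu, " outside [0, 0.3]; rates that ",
         "high cannot preserve planted motif positions - lower mu")
  }
  stopifnot(indel_rate >= 0, indel_rate <= 0.05, n_species >= 1L,
            n_per_class >= 1L)
  structure(list(classes = classes, n_species = as.integer(n_species),
                 n_per_class = as.integer(n_per_class), mu = mu,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "sim_spec")
}

# deterministic filler sequence from the background composition
random_residues <- function(n) {
  if (n == 0L) return(character(0))
  sample(AA20, n, replace = TRUE, prob = AA_BACKGROUND)
}

# remove RR dipeptides from a stretch of template filler so planted
# autoinhibitory sites stay the only RRx? signal in a linker
screen_rr <- function(chars, keep = integer(0)) {
  repeat {
    first <- which(chars[-length(chars)] == "R" & chars[-1L] == "R")
    # replace whichever member of the RR pair is not a planted literal
    targets <- unique(unlist(lapply(first, function(i) {
      cand <- setdiff(c(i + 1L, i), keep)
      if (length(cand) > 0L) cand[1L] else integer(0)
    })))
    if (length(targets) == 0L) break
    for (i in targets) chars[i] <- sample(setdiff(AA20, "R"), 1L)
  }
  chars
}

plant <- function(chars, at, literal) {
  lit <- strsplit(literal, "")[[1L]]
  chars[at:(at + length(lit) - 1L)] <- lit
  chars
}

#' Default synthetic class templates
#'
#' Ten classes mirroring the decapod PKA/PKC repertoire. Template
#' proportions follow the to-scale domain schematics of the real
#' families (a PKA catalytic subunit of ~350 aa with the kinase domain in
#' its C-terminal 60%, a ~900 aa PKN with three N-terminal HR1 repeats,
#' and so on). Each class has an N-terminal template with planted,
#' mutation-protected motif literals (anchored MGNxxxxK for the ancestral
#' catalytic subunit; a glycine tract plus conserved FxxxW for the GLY
#' isoforms; MATLMAF for the decapod-specific type; RRGA/RRVS
#' autoinhibitory sites for the regulatory subunits), and a catalytic
#' core shared across all isoform classes of the same family, so that
#' isoforms of one species are identical from the core onward. Templates
#' are generated from a fixed internal seed and are therefore stable
#' constants.
#'
#' @return named list of class templates with a `cores` attribute.
#' @export
default_sim_classes <- function() {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20251030L)

  cores <- list()
  # shared PKA catalytic core: kinase domain, nothing else
  core <- random_residues(240L)
  cores[["PKA-C"]] <- list(
    seq = core,
    domains = data.frame(domain_name = "kinase", start = 11L, end = 230L,
                         stringsAsFactors = FALSE)
  )
  # shared PKA regulatory core: two cAMP-binding domains
  core <- random_residues(280L)
  cores[["PKA-R"]] <- list(
    seq = core,
    domains = data.frame(domain_name = c("cAMP_binding", "cAMP_binding"),
                         start = c(1L, 151L), end = c(120L, 270L),
                         stringsAsFactors = FALSE)
  )
  pkc_core <- function(len, domains) {
    list(seq = random_residues(len), domains = domains)
  }
  cores[["cPKC"]] <- pkc_core(640L, data.frame(
    domain_name = c("C1", "C2", "kinase"),
    start = c(41L, 121L, 351L), end = c(90L, 210L, 600L),
    stringsAsFactors = FALSE))
  cores[["nPKC-delta-like"]] <- pkc_core(700L, data.frame(
    domain_name = c("C2", "C1", "kinase"),
    start = c(21L, 161L, 381L), end = c(120L, 210L, 640L),
    stringsAsFactors = FALSE))
  cores[["nPKC-epsilon-like"]] <- pkc_core(720L, data.frame(
    domain_name = c("C2", "C1", "kinase"),
    start = c(31L, 181L, 421L), end = c(130L, 230L, 680L),
    stringsAsFactors = FALSE))
  cores[["aPKC"]] <- pkc_core(590L, data.frame(
    domain_name = c("PB1", "C1", "kinase"),
    start = c(21L, 131L, 331L), end = c(100L, 180L, 570L),
    stringsAsFactors = FALSE))
  cores[["PKN"]] <- pkc_core(900L, data.frame(
    domain_name = c("HR1", "HR1", "HR1", "C2", "kinase"),
    start = c(11L, 101L, 191L, 301L, 601L),
    end = c(80L, 170L, 260L, 400L, 850L),
    stringsAsFactors = FALSE))

  no_dom <- data.frame(domain_name = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  classes <- list()

  # ancestral catalytic subunit: anchored MGNxxxxK, FxxxW, G2
  nt <- random_residues(60L)
  nt <- plant(nt, 1L, "MGNAAATK")
  nt <- plant(nt, 15L, "FAQLW")
  classes[["PKA-C_1"]] <- list(
    label = "PKA-C_1", family = "PKA-C", subtype = "C_1",
    core_group = "PKA-C", nterm = nt,
    protect = c(1L, 2L, 3L, 8L, 15L, 19L),
    motifs = list(MGNxxxxK = c(1L, 8L), FxxxW = c(15L, 19L)),
    nterm_domains = no_dom, gly = FALSE, ai = "none"
  )

  # glycine-rich catalytic subunit: elongated N-terminal with a G tract
  nt <- random_residues(100L)
  nt[1:2] <- c("M", "S")
  tract <- ifelse(runif(36L) < 0.8, "G", random_residues(36L))
  nt[10:45] <- tract
  nt <- plant(nt, 60L, "FSDLW")
  classes[["PKA-C_GLY"]] <- list(
    label = "PKA-C_GLY", family = "PKA-C", subtype = "C_GLY",
    core_group = "PKA-C", nterm = nt,
    protect = c(1L, 60L, 64L),
    motifs = list(FxxxW = c(60L, 64L)),
    nterm_domains = no_dom, gly = TRUE, ai = "none"
  )

  # decapod-specific catalytic subunit: MATL motif
  nt <- random_residues(70L)
  nt[1:2] <- c("M", "S")
  nt <- plant(nt, 10L, "FSELW")
  nt <- plant(nt, 30L, "MATLMAF")
  classes[["PKA-C_D1"]] <- list(
    label = "PKA-C_D1", family = "PKA-C", subtype = "C_D1",
    core_group = "PKA-C", nterm = nt,
    protect = c(10L, 14L, 30:36),
    motifs = list(`MATL[M/T/A]A[F/T]` = c(30L, 36L), FxxxW = c(10L, 14L)),
    nterm_domains = no_dom, gly = FALSE, ai = "none"
  )

  # type I regulatory subunit: D/D domain, RRGA pseudosubstrate
  nt <- random_residues(95L)
  nt[1:2] <- c("M", "S")
  nt <- plant(nt, 71L, "RRGA")
  nt[51:95] <- screen_rr(nt[51:95], keep = (71:74) - 50L)
  classes[["PKA-RI"]] <- list(
    label = "PKA-RI", family = "PKA-R", subtype = "RI",
    core_group = "PKA-R", nterm = nt,
    protect = c(1L, 71L, 72L, 74L),
    motifs = list(`RRx[A/G]` = c(71L, 74L)),
    nterm_domains = data.frame(domain_name = "DD", start = 6L, end = 50L,
                               stringsAsFactors = FALSE),
    gly = FALSE, ai = "RI"
  )

  # glycine-rich type II regulatory subunit: D/D, G tract, RRVS substrate
  nt <- random_residues(130L)
  nt[1:2] <- c("M", "S")
  tract <- ifelse(runif(40L) < 0.8, "G", random_residues(40L))
  nt[56:95] <- tract
  nt <- plant(nt, 110L, "RRVS")
  nt[51:130] <- screen_rr(nt[51:130], keep = (110:113) - 50L)
  classes[["PKA-RII_GLY"]] <- list(
    label = "PKA-RII_GLY", family = "PKA-R", subtype = "RII_GLY",
    core_group = "PKA-R", nterm = nt,
    protect = c(1L, 110L, 111L, 113L),
    motifs = list(RRxS = c(110L, 113L)),
    nterm_domains = data.frame(domain_name = "DD", start = 6L, end = 50L,
                               stringsAsFactors = FALSE),
    gly = TRUE, ai = "RII"
  )

  for (pkc in c("cPKC", "nPKC-delta-like", "nPKC-epsilon-like", "aPKC",
                "PKN")) {
    classes[[pkc]] <- list(
      label = pkc, family = pkc, subtype = NA_character_,
      core_group = pkc, nterm = character(0), protect = integer(0),
      motifs = list(), nterm_domains = no_dom, gly = FALSE, ai = "none"
    )
  }

  attr(classes, "cores") <- cores
  classes
}

# substitute one residue with a background-frequency-weighted proposal
# that excludes the original
substitute_residue <- function(orig) {
  others <- setdiff(AA20, orig)
  sample(others, 1L, prob = AA_BACKGROUND[others])
}

# positions within +/- pad of any interval boundary (or inside a motif)
indel_excluded <- function(n, protect, motifs, domains, pad = 3L) {
  excl <- protect
  for (m in motifs) {
    excl <- c(excl, (m[1L] - 1L):(m[2L] + 1L))
  }
  if (nrow(domains) > 0L) {
    for (i in seq_len(nrow(domains))) {
      excl <- c(excl, (domains$start[i] - pad):(domains$start[i] + pad),
                (domains$end[i] - pad):(domains$end[i] + pad))
    }
  }
  unique(excl[excl >= 1L & excl <= n])
}

# mutate one sequence part: substitutions on unprotected positions, then
# single-residue indels away from motifs and domain boundaries; motif
# spans and domain coordinates are shifted consistently
mutate_part <- function(chars, protect, motifs, domains, mu, indel_rate) {
  n <- length(chars)
  if (n == 0L) {
    return(list(chars = chars, motifs = motifs, domains = domains))
  }
  eligible <- setdiff(seq_len(n), protect)
  hit <- eligible[runif(length(eligible)) < mu]
  for (i in hit) chars[i] <- substitute_residue(chars[i])
  if (indel_rate > 0) {
    excl <- indel_excluded(n, protect, motifs, domains)
    sites <- setdiff(seq_len(n), excl)
    sites <- sites[runif(length(sites)) < indel_rate]
    is_insert <- runif(length(sites)) < 0.5
    ord <- order(sites, decreasing = TRUE)
    for (k in ord) {
      p <- sites[k]
      if (is_insert[k]) {
        chars <- append(chars, random_residues(1L), after = p)
        motifs <- lapply(motifs, function(m) m + (m > p))
        if (nrow(domains) > 0L) {
          inside <- domains$start <= p & p < domains$end
          domains$start <- domains$start + (domains$start > p)
          domains$end <- domains$end + (domains$end > p | inside)
        }
      } else {
        chars <- chars[-p]
        motifs <- lapply(motifs, function(m) m - (m > p))
        if (nrow(domains) > 0L) {
          domains$start <- domains$start - (domains$start > p)
          domains$end <- domains$end - (domains$end >= p)
        }
      }
    }
  }
  list(chars = chars, motifs = motifs, domains = domains)
}

#' Generate a synthetic PKA/PKC dataset with planted ground truth
#'
#' Each sequence is a mutated copy of its class template: substitutions
#' never touch planted motif literals, indels never fall inside planted
#' motifs or within 3 residues of a domain boundary, and domain-table
#' coordinates are shifted consistently with indels. The catalytic core
#' is mutated once per species and shared by all isoform classes of the
#' same family, so isoforms within one species are identical from the
#' core onward (as real decapod isoforms are). Output is deterministic
#' given the seed.
#'
#' @param spec a [sim_spec()].
#' @return list with `records` (sequence table, `source = "synthetic"`),
#'   `domains` (annotation table), and `truth` (data.frame `id`,
#'   `class`, `family`, `subtype`, `species`, `gly`, `ai`).
#' @export
generate_dataset <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  classes <- spec$classes
  cores <- attr(classes, "cores")
  rec_rows <- list()
  dom_rows <- list()
  truth_rows <- list()
  for (s in seq_len(spec$n_species)) {
    species <- sprintf("species%02d", s)
    # one mutated core per family group, shared by its isoform classes
    species_cores <- lapply(cores, function(core) {
      mutate_part(core$seq, integer(0), list(), core$domains,
                  spec$mu, spec$indel_rate)
    })
    for (cls_name in names(classes)) {
      cls <- classes[[cls_name]]
      core <- species_cores[[cls$core_group]]
      for (k in seq_len(spec$n_per_class)) {
        id <- sprintf("%s_%s_%d", species, gsub("[^A-Za-z0-9]", "", cls$label), k)
        nt <- mutate_part(cls$nterm, cls$protect, cls$motifs,
                          cls$nterm_domains, spec$mu, spec$indel_rate)
        offset <- length(nt$chars)
        residues <- paste(c(nt$chars, core$chars), collapse = "")
        dom <- rbind(
          nt$domains,
          within(core$domains, {
            start <- start + offset
            end <- end + offset
          })
        )
        if (nrow(dom) > 0L) {
          dom_rows[[id]] <- data.frame(
            seq_id = id, domain_name = dom$domain_name,
            start = dom$start, end = dom$end, complete = TRUE,
            evalue = 1e-90, stringsAsFactors = FALSE
          )
        }
        rec_rows[[id]] <- data.frame(
          id = id, species = species, phylum = "Arthropoda",
          residues = residues, source = "synthetic",
          stringsAsFactors = FALSE
        )
        truth_rows[[id]] <- data.frame(
          id = id, class = cls$label, family = cls$family,
          subtype = cls$subtype, species = species, gly = cls$gly,
          ai = cls$ai,
          motifs = paste(vapply(names(nt$motifs), function(m) {
            sprintf("%s@%d-%d", m, nt$motifs[[m]][1L], nt$motifs[[m]][2L])
          }, character(1)), collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  records <- do.call(rbind, rec_rows)
  rownames(records) <- NULL
  domains <- do.call(rbind, dom_rows)
  rownames(domains) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  validate_records(records)
  validate_domains(domains, records)
  list(records = records, domains = domains, truth = truth,
       seed = spec$seed)
}

#' Reference panel of unmutated class templates
#'
#' Builds a [reference_panel()] from the pristine class templates of a
#' simulation, labeled by family. Used to resolve novel-PKC
#' delta-like/epsilon-like calls on synthetic data.
#'
#' @param classes class templates (default [default_sim_classes()]).
#' @return a [reference_panel()].
#' @export
template_panel <- function(classes = default_sim_classes()) {
  cores <- attr(classes, "cores")
  recs <- do.call(rbind, lapply(names(classes), function(cn) {
    cls <- classes[[cn]]
    data.frame(
      id = paste0("template_", gsub("[^A-Za-z0-9]", "", cn)),
      species = "template", phylum = "unknown",
      residues = paste(c(cls$nterm, cores[[cls$core_group]]$seq),
                       collapse = ""),
      source = "synthetic", stringsAsFactors = FALSE
    )
  }))
  labels <- vapply(classes, function(cls) cls$family, character(1))
  reference_panel(recs, unname(labels))
}

#' Generate a homology-hit table with planted keep/reject labels
#'
#' True homologs flagged `keep` draw e-values log-uniformly from the
#' passing range `[1e-180, 1e-121]`, rejects from the failing range
#' `[1e-119, 1e-60]` (relative to the transcriptome threshold of
#' 1e-120); decoys draw from `[1e-50, 1e-5]`. Percent identity is
#' consistent with the substitution rate used to build the records.
#'
#' @param records a sequence-record table (the hit subjects).
#' @param keep logical vector (recycled) flagging which records should
#'   pass the transcriptome e-value filter; default all `TRUE`.
#' @param decoy_count number of decoy subjects to append.
#' @param mu substitution rate used for the identity field.
#' @param seed integer seed.
#' @param query_id query sequence name used for every row.
#' @return list with `hits` (12-column hit table) and `truth`
#'   (data.frame `subject_id`, `keep`).
#' @export
generate_hit_table <- function(records, keep = TRUE, decoy_count = 0L,
                               mu = 0.05, seed = 1L, query_id = "query1") {
  set.seed(seed)
  keep <- rep_len(keep, nrow(records))
  lens <- nchar(records$residues)
  log_e <- ifelse(keep, runif(nrow(records), -180, -121),
                  runif(nrow(records), -119, -60))
  pident <- pmin(100, pmax(0, 100 * (1 - mu) + stats::rnorm(nrow(records), 0, 1)))
  hits <- data.frame(
    query_id = query_id, subject_id = records$id,
    percent_identity = round(pident, 1), alignment_length = lens,
    mismatches = as.integer(round(lens * mu)), gap_opens = 0L,
    qstart = 1L, qend = lens, sstart = 1L, send = lens,
    evalue = 10^log_e, bitscore = round(lens * 2, 1),
    stringsAsFactors = FALSE
  )
  if (decoy_count > 0L) {
    decoys <- data.frame(
      query_id = query_id,
      subject_id = sprintf("decoy_%03d", seq_len(decoy_count)),
      percent_identity = round(runif(decoy_count, 20, 40), 1),
      alignment_length = 150L, mismatches = 90L, gap_opens = 5L,
      qstart = 1L, qend = 150L, sstart = 1L, send = 150L,
      evalue = 10^runif(decoy_count, -50, -5),
      bitscore = round(runif(decoy_count, 40, 80), 1),
      stringsAsFactors = FALSE
    )
    hits <- rbind(hits, decoys)
  }
  list(hits = hits,
       truth = data.frame(subject_id = records$id, keep = keep,
                          stringsAsFactors = FALSE))
}

# tip labels of the subtree under `node`
tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  out <- character(0)
  stack <- node
  while (length(stack) > 0L) {
    nd <- stack[1L]
    stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    out <- c(out, tree$tip.label[kids[kids <= n_tip]])
    stack <- c(stack, kids[kids > n_tip])
  }
  out
}

#' Generate a phylogeny with planted contaminant tips
#'
#' Builds a coalescent-topology tree whose terminal branches are
#' clock-like (lognormal lengths with moderate spread, the null expected
#' of a curated single-protein tree), splits the tips into two clean
#' phylum clades at the root, then plants contamination: `n_long` tips
#' get their terminal branch inflated by a factor drawn from
#' `inflation`, and `n_mislabeled` tips are relabeled with the phylum of
#' the opposite clade. Trees whose root split would leave a clade with
#' fewer than 5 tips are redrawn (same RNG stream, still deterministic
#' given the seed).
#'
#' @param n_tips total number of tips (>= 20 recommended).
#' @param n_long number of long-branch contaminants to plant.
#' @param n_mislabeled number of taxon-mislabeled contaminants to plant.
#' @param seed integer seed.
#' @param inflation `c(min, max)` multiplicative branch inflation.
#' @param phyla the two phylum labels for the clean clades.
#' @return list with `tree` (`phylo`), `taxa` (named character vector),
#'   `long_tips`, `mislabeled_tips` (planted truth).
#' @export
generate_contaminated_tree <- function(n_tips, n_long = 2L,
                                       n_mislabeled = 1L, seed = 1L,
                                       inflation = c(10, 100),
                                       phyla = c("Arthropoda", "Nematoda")) {
  if (n_long + n_mislabeled >= n_tips / 2) {
    stop("too many planted contaminants for ", n_tips, " tips")
  }
  set.seed(seed)
  labels <- sprintf("t%03d", seq_len(n_tips))
  repeat {
    tree <- ape::rcoal(n_tips, tip.label = labels)
    root <- n_tips + 1L
    kids <- tree$edge[tree$edge[, 1L] == root, 2L]
    sides <- lapply(kids, function(k) tips_under(tree, k))
    if (min(lengths(sides)) >= 5L) break
  }
  pend <- tree$edge[, 2L] <= n_tips
  tree$edge.length[pend] <- stats::rlnorm(n_tips, meanlog = log(0.2),
                                          sdlog = 0.35)
  taxa <- setNames(rep(phyla[1L], n_tips), labels)
  taxa[sides[[2L]]] <- phyla[2L]

  long_tips <- sort(sample(labels, n_long))
  for (tip in long_tips) {
    e <- which(tree$edge[, 2L] == match(tip, tree$tip.label))
    tree$edge.length[e] <- tree$edge.length[e] *
      runif(1L, inflation[1L], inflation[2L])
  }
  mislabeled <- sort(sample(setdiff(labels, long_tips), n_mislabeled))
  for (tip in mislabeled) {
    taxa[tip] <- if (taxa[tip] == phyla[1L]) phyla[2L] else phyla[1L]
  }
  list(tree = tree, taxa = taxa, long_tips = long_tips,
       mislabeled_tips = mislabeled)
}
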