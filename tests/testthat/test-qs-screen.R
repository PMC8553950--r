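test_that("best-KO rule classifies by strict score dominance", {
  hits <- hit_table(
    hit_row("orf1", 80, ko = "K13060"), hit_row("orf1", 70, ko = "K00001"),
    hit_row("orf2", 80, ko = "K13060"), hit_row("orf2", 85, ko = "K00001"),
    hit_row("orf3", 50, ko = "K07782"))
  cand <- classify_qs_orfs(hits)
  expect_equal(cand$orf_id, c("orf1", "orf3"))
  expect_equal(cand$role[cand$orf_id == "orf1"], "synthase")
  expect_equal(cand$best_qs_score[cand$orf_id == "orf1"], 80)
  expect_equal(cand$best_other_score[cand$orf_id == "orf1"], 70)
  expect_equal(cand$role[cand$orf_id == "orf3"], "receptor")
  expect_true(is.na(cand$best_other_score[cand$orf_id == "orf3"]))
})

test_that("QS/non-QS score ties are rejected and logged", {
  hits <- hit_table(hit_row("orfT", 80, ko = "K13060"),
                    hit_row("orfT", 80, ko = "K00001"))
  cand <- classify_qs_orfs(hits)
  expect_equal(nrow(cand), 0L)
  expect_equal(attr(cand, "rejected_ties"), "orfT")
})

test_that("classification is invariant under row permutation and duplication", {
  set.seed(31)
  for (rep in 1:20) {
    n_orfs <- sample(3:8, 1)
    rows <- list()
    for (i in seq_len(n_orfs)) {
      for (j in seq_len(sample(1:4, 1))) {
        ko <- sample(c("K13060", "K07782", "K00001", "K02335", NA), 1)
        rows[[length(rows) + 1]] <- hit_row(paste0("o", i),
                                            round(runif(1, 30, 120), 1), ko = ko)
      }
    }
    hits <- do.call(rbind, rows)
    base <- classify_qs_orfs(hits)
    perm <- classify_qs_orfs(hits[sample(nrow(hits)), , drop = FALSE])
    dup <- classify_qs_orfs(rbind(hits, hits[sample(nrow(hits), 2), ,
                                             drop = FALSE]))
    expect_equal(perm, base, ignore_attr = TRUE)
    expect_equal(dup, base, ignore_attr = TRUE)
    # re-check the strict-inequality rule against the raw table
    qs <- c(qs_ko_sets()$synthase_kos, qs_ko_sets()$receptor_kos)
    for (k in seq_len(nrow(base))) {
      sub <- hits[hits$orf_id == base$orf_id[k], ]
      in_qs <- !is.na(sub$ko_id) & sub$ko_id %in% qs
      expect_equal(max(sub$bitscore[in_qs]), base$best_qs_score[k])
      if (any(!in_qs)) {
        expect_true(base$best_qs_score[k] > max(sub$bitscore[!in_qs]))
      }
    }
  }
})

test_that("domain validation needs Pfam00765 for luxI and both receptor domains", {
  cand <- classify_qs_orfs(hit_table(hit_row("s1", 80, ko = "K13060"),
                                     hit_row("r1", 70, ko = "K07782")))
  dom <- data.frame(orf_id = c("s1", "r1"),
                    domain_id = c("Pfam00765", "Pfam03472"),
                    score = c(100, 90), evalue = c(1e-20, 1e-20),
                    stringsAsFactors = FALSE)
  v <- validate_domains(cand, dom)
  expect_equal(v$domain_validated[v$orf_id == "s1"], "true")
  expect_equal(v$domain_validated[v$orf_id == "r1"], "false")  # GerE missing

  dom2 <- rbind(dom, data.frame(orf_id = "r1", domain_id = "PF00196",
                                score = 50, evalue = 1e-8,
                                stringsAsFactors = FALSE))
  v2 <- validate_domains(cand, dom2)
  expect_equal(v2$domain_validated[v2$orf_id == "r1"], "true")

  v3 <- validate_domains(cand, dom[0, ])
  expect_true(all(v3$domain_validated == "untested"))

  weak <- dom; weak$evalue <- c(1e-2, 1e-20)   # above the 1e-5 cutoff
  v4 <- validate_domains(cand, weak)
  expect_equal(v4$domain_validated[v4$orf_id == "s1"], "false")

  stray <- rbind(dom, data.frame(orf_id = "ghost", domain_id = "PF00765",
                                 score = 10, evalue = 1e-9,
                                 stringsAsFactors = FALSE))
  expect_warning(validate_domains(cand, stray), "ghost")
})

test_that("global alignment produces the expected reference-position maps", {
  a <- align_global("MKW", "MKW")
  expect_equal(unname(a$ref_map), c("M", "K", "W"))
  expect_false(grepl("-", a$aligned_query))

  b <- align_global("MW", "MKW")
  expect_equal(unname(b$ref_map), c("M", "-", "W"))

  expect_error(align_global("MXW", "MKW"), "residue")
  expect_error(align_global("", "MKW"), "empty")
})

test_that("alignment scores match a brute-force affine-gap enumeration", {
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  submat <- get("BLOSUM62", envir = environment())
  ident <- align_global("MKWDE", "MKWDE")
  expect_equal(ident$score,
               sum(diag(submat[c("M", "K", "W", "D", "E"),
                               c("M", "K", "W", "D", "E")])))
  set.seed(17)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    q <- paste(sample(aa, sample(2:4, 1), replace = TRUE), collapse = "")
    r <- paste(sample(aa, sample(2:4, 1), replace = TRUE), collapse = "")
    expect_equal(align_global(q, r)$score, oracle_align_score(q, r),
                 info = paste(q, r))
  }
})

test_that("conserved-residue audit flags exactly the planted substitutions", {
  ref <- luxr_reference()
  expect_equal(check_luxr_conservation(ref$sequence)$missense_acyl, 0L)
  expect_equal(check_luxr_conservation(ref$sequence)$missense_dna, 0L)

  q <- ref$sequence
  substr(q, 79, 79) <- "A"                      # D79A
  rep1 <- check_luxr_conservation(q)
  expect_equal(rep1$missense_acyl, 1L)
  expect_false(rep1$acyl$conserved[rep1$acyl$position == 79])
  expect_equal(rep1$missense_dna, 0L)

  q2 <- ref$sequence
  substr(q2, 187, 187) <- "K"; substr(q2, 191, 191) <- "V"
  rep2 <- check_luxr_conservation(q2)
  expect_equal(rep2$missense_dna, 2L)
  expect_equal(rep2$missense_acyl, 0L)
})

test_that("deleted regions count as gaps, not missense", {
  ref <- luxr_reference()
  # remove residues 75-85 (spans D79/P80)
  q <- paste0(substr(ref$sequence, 1, 74), substr(ref$sequence, 86, 210))
  rep <- check_luxr_conservation(q)
  expect_gte(rep$gaps_acyl, 2L)
  expect_equal(rep$missense_acyl + rep$gaps_acyl +
                 sum(rep$acyl$conserved), 5L)
})

test_that("a mis-annotated reference is a configuration error", {
  bad <- luxr_reference()$sequence
  substr(bad, 66, 66) <- "A"
  expect_error(luxr_reference(bad), "annotated position")
})

test_that("cognate pairing is greedy nearest-first within a contig", {
  ctg <- setNames(strrep("A", 10000), "c1")
  orfs <- rbind(orf_row("r1", "c1", 1000, 1500, "-"),
                orf_row("s1", "c1", 1800, 2600, "+"),
                orf_row("x1", "c1", 2700, 3000, "+"),
                orf_row("r2", "c1", 3100, 3600, "+"))
  cand <- data.frame(orf_id = c("s1", "r1", "r2"),
                     role = c("synthase", "receptor", "receptor"),
                     stringsAsFactors = FALSE)
  pairing <- pair_lux_genes(cand, orfs)
  expect_equal(nrow(pairing$pairs), 1L)
  expect_equal(pairing$pairs$receptor, "r1")     # distance 0 beats distance 1
  expect_equal(pairing$pairs$intervening, 0L)
  expect_equal(pairing$pairs$orientation, "divergent")
  expect_equal(pairing$solo_receptors, "r2")
})

test_that("pairing respects contig boundaries and max_intervening", {
  orfs <- rbind(orf_row("s1", "c1", 100, 400, "+"),
                orf_row("r1", "c2", 100, 400, "+"))
  cand <- data.frame(orf_id = c("s1", "r1"), role = c("synthase", "receptor"),
                     stringsAsFactors = FALSE)
  p <- pair_lux_genes(cand, orfs)
  expect_equal(nrow(p$pairs), 0L)
  expect_equal(p$solo_receptors, "r1")
  expect_equal(p$unpaired_synthases, "s1")

  orfs2 <- rbind(orf_row("s1", "c1", 100, 400, "+"),
                 orf_row("b1", "c1", 500, 700, "+"),
                 orf_row("b2", "c1", 800, 1000, "+"),
                 orf_row("r1", "c1", 1100, 1400, "+"))
  cand2 <- cand
  expect_equal(nrow(pair_lux_genes(cand2, orfs2, max_intervening = 1L)$pairs), 0L)
  expect_equal(nrow(pair_lux_genes(cand2, orfs2, max_intervening = 2L)$pairs), 1L)
  # tandem orientation on the same strand
  expect_equal(pair_lux_genes(cand2, orfs2, max_intervening = 3L)$pairs$orientation,
               "tandem")
})
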