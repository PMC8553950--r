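test_that("best-score window keeps hits within 0.95 of the best bitscore", {
  h <- hit_table(hit_row("o", 100), hit_row("o", 96), hit_row("o", 94))
  expect_equal(sort(best_score_window(h)$bitscore), c(96, 100))
  expect_equal(best_score_window(hit_table(hit_row("o", 42)))$bitscore, 42)
  # boundary hit exactly at 0.95 * Sbest is kept by default, dropped if strict
  hb <- hit_table(hit_row("o", 100), hit_row("o", 95))
  expect_equal(sort(best_score_window(hb)$bitscore), c(95, 100))
  expect_equal(best_score_window(hb, window_params(strict = TRUE))$bitscore, 100)
})

test_that("window selection is an upper set of bitscores", {
  set.seed(9)
  for (i in 1:25) {
    h <- do.call(rbind, lapply(seq_len(sample(2:10, 1)), function(j)
      hit_row("o", round(runif(1, 10, 200), 2))))
    win <- best_score_window(h)
    kept_min <- min(win$bitscore)
    expect_true(all(h$bitscore[h$bitscore >= kept_min] %in% win$bitscore))
    expect_true(max(h$bitscore) %in% win$bitscore)
  }
})

test_that("majority-rule consensus needs a strict majority", {
  w <- function(labels) {
    do.call(rbind, lapply(labels, function(l) hit_row("o", 100, fun = l)))
  }
  expect_equal(consensus_function(w(c("A", "A", "B"))), "A")
  expect_equal(consensus_function(w(c("A", "B"))), "ambiguous")
  expect_equal(consensus_function(w(c("A", "A", "A", "A"))), "A")
  expect_equal(consensus_function(w(c(NA, NA))), "ambiguous")
  expect_equal(consensus_function(w(c("A", NA))), "A")  # unlabelled excluded
})

test_that("LCA matches the quoted prefix examples", {
  h <- hit_table(
    hit_row("o", 100, tax = "superkingdom:Bacteria;phylum:Proteobacteria;class:Alpha"),
    hit_row("o", 99, tax = "superkingdom:Bacteria;phylum:Proteobacteria;class:Beta"))
  expect_equal(lca_taxon(h),
               c("superkingdom:Bacteria", "phylum:Proteobacteria"))
  single <- hit_table(hit_row("o", 50, tax = "superkingdom:Bacteria;phylum:Nitrospirae"))
  expect_equal(lca_taxon(single),
               c("superkingdom:Bacteria", "phylum:Nitrospirae"))
  expect_equal(lca_taxon(hit_table(hit_row("o", 10))), character(0))
  # divergence at the root
  h2 <- hit_table(hit_row("o", 10, tax = "superkingdom:Bacteria"),
                  hit_row("o", 10, tax = "superkingdom:Archaea"))
  expect_equal(lca_taxon(h2), character(0))
})

test_that("LCA and consensus match brute-force oracles on random windows", {
  set.seed(23)
  ranks <- c("superkingdom", "phylum", "class", "order", "genus")
  for (i in 1:200) {
    n <- sample(1:6, 1)
    paths <- lapply(seq_len(n), function(j) {
      depth <- sample(1:5, 1)
      paste0(ranks[1:depth], ":", sample(c("X", "Y"), depth, replace = TRUE))
    })
    labels <- sample(c("f1", "f2", NA), n, replace = TRUE)
    win <- do.call(rbind, lapply(seq_len(n), function(j)
      hit_row("o", 100, fun = labels[j],
              tax = paste(paths[[j]], collapse = ";"))))
    expect_equal(lca_taxon(win), oracle_lca(paths))
    expect_equal(consensus_function(win), oracle_majority(labels))
  }
})

test_that("per-ORF assignment is independent across ORFs and handles no hits", {
  hits <- hit_table(
    hit_row("o1", 100, fun = "fa", tax = "superkingdom:Bacteria;genus:Nitrospira"),
    hit_row("o1", 99, fun = "fa", tax = "superkingdom:Bacteria;genus:Nitrospira"),
    hit_row("o2", 60, fun = "fb", tax = "superkingdom:Bacteria;genus:Pseudomonas"))
  a <- assign_orf_taxonomy(hits, orf_ids = c("o1", "o2", "o3"))
  expect_equal(nrow(a), 3L)
  expect_equal(a$consensus_function[a$orf_id == "o1"], "fa")
  expect_equal(a$window_size[a$orf_id == "o3"], 0L)
  expect_true(is.na(a$lca_path[a$orf_id == "o3"]))
  # permutation of input rows leaves the result unchanged
  a2 <- assign_orf_taxonomy(hits[c(3, 1, 2), ], orf_ids = c("o1", "o2", "o3"))
  expect_equal(a2, a)
})

test_that("tiered contig calls reproduce the quoted worked examples", {
  mk <- function(n, t) {
    lca <- c(rep("superkingdom:Bacteria;genus:Nitrospira", t),
             rep("superkingdom:Bacteria;genus:Pseudomonas", n - t))
    data.frame(orf_id = sprintf("o%d", seq_len(n)), window_size = 1L,
               consensus_function = "f", lca_path = lca,
               stringsAsFactors = FALSE)
  }
  tgt <- "genus:Nitrospira"
  c1 <- classify_contig_taxon(mk(7, 4), tgt)
  expect_true(c1$is_target); expect_equal(c1$tier_applied, "i")
  c2 <- classify_contig_taxon(mk(5, 3), tgt)   # 60.0% is not > 60%
  expect_false(c2$is_target); expect_equal(c2$tier_applied, "ii")
  c3 <- classify_contig_taxon(mk(2, 2), tgt)
  expect_true(c3$is_target); expect_equal(c3$tier_applied, "iii")
  c4 <- classify_contig_taxon(mk(3, 3), tgt)   # gap-filling extension, flagged
  expect_true(c4$is_target); expect_equal(c4$tier_applied, "iii*")
  c0 <- classify_contig_taxon(mk(1, 1)[0, ], tgt)
  expect_false(c0$is_target); expect_equal(c0$tier_applied, "none")
})

test_that("contig calls match the frozen exhaustive truth table", {
  truth <- read.delim(test_path("fixtures", "tier_truth.tsv"))
  for (k in seq_len(nrow(truth))) {
    n <- truth$n_orfs[k]; t <- truth$n_target[k]
    a <- data.frame(orf_id = character(0), window_size = integer(0),
                    consensus_function = character(0), lca_path = character(0),
                    stringsAsFactors = FALSE)
    if (n > 0) {
      lca <- c(rep("superkingdom:Bacteria;genus:Nitrospira", t),
               rep(NA_character_, n - t))
      a <- data.frame(orf_id = sprintf("o%d", seq_len(n)), window_size = 1L,
                      consensus_function = "f", lca_path = lca,
                      stringsAsFactors = FALSE)
    }
    call <- classify_contig_taxon(a, "genus:Nitrospira")
    expect_identical(call$is_target, truth$is_target[k],
                     info = sprintf("n=%d t=%d", n, t))
  }
})

test_that("raising n_target never flips a contig call to negative", {
  for (n in 1:10) {
    calls <- vapply(0:n, function(t) {
      lca <- c(rep("superkingdom:Bacteria;genus:Nitrospira", t),
               rep(NA_character_, n - t))
      a <- data.frame(orf_id = sprintf("o%d", seq_len(n)), window_size = 1L,
                      consensus_function = "f", lca_path = lca,
                      stringsAsFactors = FALSE)
      classify_contig_taxon(a, "genus:Nitrospira")$is_target
    }, logical(1))
    expect_true(all(diff(as.integer(calls)) >= 0))
  }
})

test_that("target membership is prefix-based on the lineage", {
  expect_true(is_target_taxon(
    "superkingdom:Bacteria;genus:Nitrospira;species:Ndefluvii",
    "genus:Nitrospira"))
  expect_false(is_target_taxon("superkingdom:Bacteria", "genus:Nitrospira"))
  expect_false(is_target_taxon(NA_character_, "genus:Nitrospira"))
})
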