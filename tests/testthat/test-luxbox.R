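test_that("upstream extraction follows the strand conventions", {
  set.seed(1)
  ctg <- random_dna_str(1000)
  # + strand ORF far from the edge: positions start-400 .. start-1
  r1 <- extract_upstream(orf_row("o1", "c", 500, 800, "+"), ctg)
  expect_equal(c(r1$genomic_start, r1$genomic_end), c(100L, 499L))
  expect_equal(r1$sequence, substr(ctg, 100, 499))
  expect_false(r1$clipped)
  # + strand ORF near the edge is clipped
  r2 <- extract_upstream(orf_row("o2", "c", 200, 500, "+"), ctg)
  expect_equal(c(r2$genomic_start, r2$genomic_end), c(1L, 199L))
  expect_true(r2$clipped)
  # - strand ORF: revcomp of end+1 .. end+400
  ctg6 <- random_dna_str(600)
  r3 <- extract_upstream(orf_row("o3", "c", 50, 100, "-"), ctg6)
  expect_equal(c(r3$genomic_start, r3$genomic_end), c(101L, 500L))
  expect_equal(r3$sequence, revcomp(substr(ctg6, 101, 500)))
  # ORF at position 1 on + strand has no upstream sequence
  expect_warning(r4 <- extract_upstream(orf_row("o4", "c", 1, 90, "+"), ctg),
                 "no upstream")
  expect_equal(r4$sequence, "")
  expect_true(r4$clipped)
})

test_that("region offsets map back to the exact genomic slice on both strands", {
  set.seed(8)
  ctg <- random_dna_str(2000)
  for (strand in c("+", "-")) {
    orf <- orf_row("o", "c", 900, 1200, strand)
    region <- extract_upstream(orf, ctg)
    for (off in sample(seq_len(nchar(region$sequence) - 19L), 10)) {
      g <- region_to_genomic(region, off, 20L)
      slice <- substr(ctg, g[1], g[2])
      if (strand == "-") slice <- revcomp(slice)
      expect_equal(substr(region$sequence, off, off + 19L), slice)
    }
  }
})

test_that("scanning finds a planted consensus site at the right offset", {
  lib <- generate_motif_library(mutation_rate = 0.05, seed = 1)
  model <- build_motif(as.character(lib))
  set.seed(1)
  seqn <- random_dna_str(400)
  site <- "ACCTGGCGGTTCCGCCAGGT"
  at <- 137L
  seqn <- paste0(substr(seqn, 1, at - 1), site, substr(seqn, at + 20, 400))
  hits <- scan_region(model, seqn)
  strong <- hits[hits$p_value < 1e-8, ]
  expect_equal(strong$offset, at)
  expect_equal(strong$site, site)
  expect_equal(strong$strand, "+")
})

test_that("scanning is strand-symmetric for planted sites", {
  lib <- generate_motif_library(mutation_rate = 0.05, seed = 2)
  model <- build_motif(as.character(lib))
  set.seed(2)
  seqn <- random_dna_str(400)
  site <- "ACCTGGCGGTTCCGCCAGGT"
  at <- 200L
  fwd <- paste0(substr(seqn, 1, at - 1), site, substr(seqn, at + 20, 400))
  rev <- paste0(substr(seqn, 1, at - 1), revcomp(site), substr(seqn, at + 20, 400))
  h_f <- scan_region(model, fwd); h_f <- h_f[h_f$p_value < 1e-8, ]
  h_r <- scan_region(model, rev); h_r <- h_r[h_r$p_value < 1e-8, ]
  expect_equal(h_f$offset, h_r$offset)
  expect_equal(h_f$site, h_r$site)       # matching-strand sequence reported
  expect_equal(h_f$score, h_r$score)
  expect_equal(h_r$strand, "-")
  # reverse-complementing the whole region mirrors the offsets
  h_m <- scan_region(model, revcomp(fwd)); h_m <- h_m[h_m$p_value < 1e-8, ]
  expect_equal(h_m$offset, 400L - (at + 20L) + 2L)
  expect_equal(h_m$site, site)
})

test_that("GC-poor regions yield no hits against a GC-rich motif", {
  model <- build_motif(replicate(8, strrep("GC", 10)))
  expect_equal(nrow(scan_region(model, strrep("A", 400))), 0L)
  expect_warning(out <- scan_region(model, "ACGT"), "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("hit location is intragenic iff the site overlaps any ORF", {
  set.seed(12)
  ctg <- random_dna_str(1500)
  orfs <- rbind(orf_row("up", "c", 100, 400, "+"),
                orf_row("gene", "c", 900, 1200, "+"))
  region <- extract_upstream(orfs[2, ], ctg)  # positions 500..899
  # site wholly between the two ORFs
  loc1 <- classify_hit_location(region, 150L, 20L, orfs)
  expect_equal(loc1$location_class, "intergenic")
  # region position 1 corresponds to genomic 500; a site can't reach ORF "up"
  # here, so test the boundary with an ORF ending at 510
  orfs2 <- rbind(orf_row("up2", "c", 100, 510, "+"), orfs[2, ])
  loc2 <- classify_hit_location(region, 11L, 20L, orfs2)  # genomic 510..529
  expect_equal(loc2$location_class, "intragenic")          # 1 bp overlap
  loc3 <- classify_hit_location(region, 12L, 20L, orfs2)  # genomic 511..530
  expect_equal(loc3$location_class, "intergenic")
})

test_that("promoter element search enforces the 15-19 bp spacer", {
  pad <- strrep("C", 40)
  # -35 ... 17 bp ... -10
  seqn <- paste0(pad, "TTGACA", strrep("C", 17), "TATAAT", strrep("C", 30))
  res <- find_promoter_elements(seqn, site_end = 10L)
  expect_true(res$paired)
  expect_equal(res$spacer, 17L)
  expect_true(res$minus35$found)
  expect_true(res$minus10$found)
  expect_equal(res$minus10$offset - (res$minus35$offset + 6L), 17L)

  # spacer 25 bp: elements found individually but not paired
  seqn2 <- paste0(pad, "TTGACA", strrep("C", 25), "TATAAT", strrep("C", 30))
  res2 <- find_promoter_elements(seqn2, site_end = 10L)
  expect_false(res2$paired)
  expect_true(res2$minus35$found)
  expect_true(res2$minus10$found)

  # one mismatch in the -10 hexamer is tolerated at mismatch_max = 1
  seqn3 <- paste0(pad, "TTGACA", strrep("C", 17), "TATACT", strrep("C", 30))
  res3 <- find_promoter_elements(seqn3, site_end = 10L, mismatch_max = 1L)
  expect_true(res3$minus10$found)
  expect_true(res3$paired)
})

test_that("Shine-Dalgarno search requires 4+ core matches ending 4-14 nt out", {
  base <- strrep("C", 400)
  plant <- function(s, end_gap) {
    at <- 400 - end_gap - nchar(s) + 1
    paste0(substr(base, 1, at - 1), s, substr(base, at + nchar(s), 400))
  }
  r1 <- find_shine_dalgarno(plant("AGGAGG", 7))
  expect_true(r1$found)
  expect_equal(r1$match_length, 6L)
  expect_false(find_shine_dalgarno(base)$found)
  # 4 consecutive core matches (GGAG) at spacing 8
  expect_true(find_shine_dalgarno(plant("GGAG", 8))$found)
  # right motif, too close to the start codon
  expect_false(find_shine_dalgarno(plant("AGGAGG", 2))$found)
  # clipped regions are searched as available
  expect_true(find_shine_dalgarno(substr(plant("AGGAGG", 7), 386, 400))$found)
})

test_that("regulon prediction reports divergently shared boxes and distances", {
  cm <- generate_community(community_config(seed = 19))
  model <- build_motif(as.character(cm$library))
  reg <- predict_regulon(cm$contigs, cm$orfs, model)
  box <- cm$truth$boxes
  planted <- reg[reg$genomic_start == box$genomic_start &
                 reg$contig_id == box$contig_id, ]
  expect_equal(nrow(planted), 2L)
  expect_setequal(planted$orf_id, c(box$synthase, box$receptor))
  expect_equal(planted$shared_bidirectional_with,
               rev(planted$orf_id))
  expect_equal(planted$distance_upstream[planted$orf_id == box$synthase],
               box$distance_synthase)
  expect_equal(planted$distance_upstream[planted$orf_id == box$receptor],
               box$distance_receptor)
  expect_true(all(planted$location_class == "intergenic"))
  expect_true(all(planted$palindrome_mismatches <= 8))
  syn <- planted[planted$orf_id == box$synthase, ]
  expect_true(syn$minus35_found && syn$minus10_found && syn$sd_found)
  # ranked by p-value
  expect_true(!is.unsorted(reg$p_value))
})

test_that("a box degraded to p ~ 1e-3 is no longer predicted", {
  cm <- generate_community(community_config(seed = 19))
  model <- build_motif(as.character(cm$library))
  box <- cm$truth$boxes
  # mutate the planted site until its own p-value crosses the threshold
  set.seed(99)
  site <- box$site
  repeat {
    site <- mutate_dna(site, 1L)
    p <- motif_score_pvalue(model, score_site(model, site))
    if (p > 1e-4) break
  }
  expect_lt(p, 1e-2)
  ctg <- cm$contigs
  ctg[[box$contig_id]] <- paste0(
    substr(ctg[[box$contig_id]], 1, box$genomic_start - 1), site,
    substr(ctg[[box$contig_id]], box$genomic_end + 1,
           nchar(ctg[[box$contig_id]])))
  reg <- predict_regulon(ctg, cm$orfs, model)
  expect_equal(nrow(reg[reg$genomic_start == box$genomic_start &
                        reg$contig_id == box$contig_id, ]), 0L)
})
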