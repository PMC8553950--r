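## Upstream-region extraction, PWM scanning of both strands, palindrome
## filtering, promoter-element annotation, and regulon candidate assembly.

#' Extract the upstream region of an ORF
#'
#' For a + strand ORF starting at `s`, the region covers contig positions
#' `[max(1, s - length), s - 1]` as-is; for a − strand ORF ending at `e` it
#' covers `[e + 1, min(L, e + length)]` reverse-complemented. The returned
#' sequence therefore always reads 5'→3' toward the start codon. Regions
#' shorter than `length` (contig edge) are flagged `clipped`.
#'
#' @param orf one-row ORF data.frame (or list) with `orf_id`, `contig_id`,
#'   `start`, `end`, `strand`.
#' @param contig the contig sequence (character scalar).
#' @param length upstream window size in bp (default 400).
#' @return list of class `"upstream_region"`: `orf_id`, `contig_id`,
#'   `genomic_start`, `genomic_end`, `strand`, `sequence`, `clipped`.
#' @export
extract_upstream <- function(orf, contig, length = 400L) {
  L <- nchar(contig)
  if (orf$start < 1L || orf$end > L) stop("ORF outside contig", call. = FALSE)
  if (orf$strand == "+") {
    gs <- max(1L, orf$start - length)
    ge <- orf$start - 1L
  } else {
    gs <- orf$end + 1L
    ge <- min(L, orf$end + length)
  }
  if (ge < gs) {
    warning("ORF '", orf$orf_id, "' has no upstream sequence on its contig")
    seqn <- ""
    gs <- NA_integer_; ge <- NA_integer_
  } else {
    seqn <- substr(contig, gs, ge)
    if (orf$strand == "-") seqn <- revcomp(seqn)
  }
  structure(list(orf_id = orf$orf_id, contig_id = orf$contig_id,
                 genomic_start = gs, genomic_end = ge, strand = orf$strand,
                 sequence = seqn, clipped = nchar(seqn) < length),
            class = "upstream_region")
}

#' Map a region-relative interval back to genomic coordinates
#'
#' @param region an `"upstream_region"`.
#' @param offset 1-based start of the interval within the region sequence.
#' @param width interval width.
#' @return integer `c(start, end)`, 1-based inclusive genomic positions.
#' @export
region_to_genomic <- function(region, offset, width) {
  if (region$strand == "+") {
    gs <- region$genomic_start + offset - 1L
    c(gs, gs + width - 1L)
  } else {
    ge <- region$genomic_end - offset + 1L
    c(ge - width + 1L, ge)
  }
}

#' Scan an upstream region with a motif model on both strands
#'
#' Every offset is scored in both orientations; at each offset only the
#' better-scoring orientation is kept (ties go to +). Hits with
#' `p_value < p_threshold` are returned with their palindrome mismatch count.
#'
#' @param model a `"motif_model"`.
#' @param region an `"upstream_region"` or a plain DNA string.
#' @param p_threshold report sites with p-value strictly below this.
#' @param granularity DP bins per column for the p-value (see
#'   [motif_score_pvalue()]).
#' @return data.frame with columns `offset` (1-based within the region),
#'   `strand` (orientation of the match within the region), `site` (the
#'   matching strand's sequence), `score`, `p_value`,
#'   `palindrome_mismatches` (`NA` for odd widths or sites containing N).
#' @export
scan_region <- function(model, region, p_threshold = 1e-4, granularity = 1000L) {
  seqn <- if (inherits(region, "upstream_region")) region$sequence else region
  empty <- data.frame(offset = integer(0), strand = character(0),
                      site = character(0), score = numeric(0),
                      p_value = numeric(0), palindrome_mismatches = integer(0),
                      stringsAsFactors = FALSE)
  w <- model$width
  if (nchar(seqn) < w) {
    warning("region shorter than motif width; nothing to scan")
    return(empty)
  }
  pfun <- motif_pvalue_fun(model, granularity)
  n_off <- nchar(seqn) - w + 1L
  rows <- vector("list", n_off)
  for (o in seq_len(n_off)) {
    fwd <- substr(seqn, o, o + w - 1L)
    rcs <- revcomp(fwd)
    s_f <- score_site(model, fwd)
    s_r <- score_site(model, rcs)
    if (s_f >= s_r) { strand <- "+"; site <- fwd; sc <- s_f }
    else { strand <- "-"; site <- rcs; sc <- s_r }
    p <- pfun(sc)
    if (p < p_threshold) {
      pm <- if (w %% 2L == 0L && !grepl("N", site, fixed = TRUE))
        palindrome_mismatches(site) else NA_integer_
      rows[[o]] <- data.frame(offset = o, strand = strand, site = site,
                              score = sc, p_value = p,
                              palindrome_mismatches = pm,
                              stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a motif hit as intergenic or intragenic
#'
#' A hit is intragenic when its genomic interval overlaps any ORF interval on
#' either strand, by even a single base.
#'
#' @param region the `"upstream_region"` the hit was found in.
#' @param offset hit offset within the region.
#' @param width motif width.
#' @param orfs ORF table for the contig set.
#' @return list with `location_class` (`"intergenic"`/`"intragenic"`) and
#'   `genomic_start`, `genomic_end`.
#' @export
classify_hit_location <- function(region, offset, width, orfs) {
  g <- region_to_genomic(region, offset, width)
  same_contig <- orfs[orfs$contig_id == region$contig_id, , drop = FALSE]
  overlaps <- nrow(same_contig) > 0L &&
    any(same_contig$start <= g[2] & same_contig$end >= g[1])
  list(location_class = if (overlaps) "intragenic" else "intergenic",
       genomic_start = g[1], genomic_end = g[2])
}

## mismatch count of `word` against `seqn` at each start offset
mismatch_profile <- function(seqn, word) {
  n <- nchar(seqn) - nchar(word) + 1L
  if (n < 1L) return(integer(0))
  wc <- chars_of(word)
  sc <- chars_of(seqn)
  vapply(seq_len(n), function(o) {
    sum(sc[o:(o + length(wc) - 1L)] != wc)
  }, integer(1))
}

#' Search for sigma-70 −35/−10 promoter elements downstream of a motif site
#'
#' Looks between the site's 3' edge and the start codon for the −35 hexamer
#' (consensus `TTGACA`) and the −10 hexamer (consensus `TATAAT`), each
#' allowing up to `mismatch_max` mismatches, with the spacer between them
#' constrained to 15–19 bp. The compatible pair with the fewest total
#' mismatches wins (ties: most downstream). When no compatible pair exists
#' the elements are still reported individually as unpaired.
#'
#' @param region_seq region sequence oriented toward the start codon.
#' @param site_end 1-based position of the motif site's last base within the
#'   region.
#' @param mismatch_max maximum mismatches per hexamer (default 2).
#' @return list with `minus35` and `minus10` (each `list(found, offset,
#'   mismatches)`, offsets region-relative) and `paired`, `spacer`.
#' @export
find_promoter_elements <- function(region_seq, site_end, mismatch_max = 2L) {
  down <- substr(region_seq, site_end + 1L, nchar(region_seq))
  m35 <- mismatch_profile(down, "TTGACA")
  m10 <- mismatch_profile(down, "TATAAT")
  best_solo <- function(mm) {
    ok <- which(mm <= mismatch_max)
    if (length(ok) == 0L) return(list(found = FALSE, offset = NA_integer_,
                                      mismatches = NA_integer_))
    o <- ok[which.min(mm[ok])]
    list(found = TRUE, offset = site_end + o, mismatches = mm[[o]])
  }
  out <- list(minus35 = best_solo(m35), minus10 = best_solo(m10),
              paired = FALSE, spacer = NA_integer_)
  best <- NULL
  for (o35 in which(m35 <= mismatch_max)) {
    for (o10 in which(m10 <= mismatch_max)) {
      spacer <- o10 - (o35 + 6L)     # gap between end of -35 and start of -10
      if (spacer < 15L || spacer > 19L) next
      total <- m35[[o35]] + m10[[o10]]
      if (is.null(best) || total < best$total ||
          (total == best$total && o10 > best$o10)) {
        best <- list(o35 = o35, o10 = o10, spacer = spacer, total = total)
      }
    }
  }
  if (!is.null(best)) {
    out$minus35 <- list(found = TRUE, offset = site_end + best$o35,
                        mismatches = m35[[best$o35]])
    out$minus10 <- list(found = TRUE, offset = site_end + best$o10,
                        mismatches = m10[[best$o10]])
    out$paired <- TRUE
    out$spacer <- best$spacer
  }
  out
}

#' Search for a Shine–Dalgarno sequence next to the start codon
#'
#' Scans the final 20 bp of the region (which abuts the start codon) for at
#' least `min_match` consecutive matches to the `AGGAGG` core, with the
#' matched stretch ending 4–14 nt before the start codon.
#'
#' @param region_seq region sequence oriented toward the start codon; clipped
#'   regions shorter than 20 bp are searched as available.
#' @param min_match minimum run of consecutive core matches (default 4).
#' @return list with `found`, `offset` (region-relative start of the matched
#'   run) and `match_length`.
#' @export
find_shine_dalgarno <- function(region_seq, min_match = 4L) {
  L <- nchar(region_seq)
  win_start <- max(1L, L - 19L)
  win <- substr(region_seq, win_start, L)
  core <- chars_of("AGGAGG")
  wc <- if (nchar(win) > 0L) chars_of(win) else character(0)
  best <- list(found = FALSE, offset = NA_integer_, match_length = NA_integer_)
  for (o in seq_len(max(0L, length(wc) - 5L))) {
    seg <- wc[o:(o + 5L)]
    match <- seg == core
    run <- 0L; run_end <- 0L; cur <- 0L
    for (k in seq_along(match)) {
      cur <- if (match[[k]]) cur + 1L else 0L
      if (cur > run) { run <- cur; run_end <- k }
    }
    if (run < min_match) next
    end_region <- win_start + o - 1L + run_end - 1L
    dist_to_start <- L - end_region   # nt strictly between run end and ATG
    if (dist_to_start >= 4L && dist_to_start <= 14L) {
      if (!best$found || run > best$match_length) {
        best <- list(found = TRUE,
                     offset = end_region - run + 1L,
                     match_length = run)
      }
    }
  }
  best
}

#' Default configuration for regulon prediction
#'
#' @param upstream_length bp of upstream sequence scanned (default 400).
#' @param p_threshold motif p-value cutoff (default 1e-4, strict `<`).
#' @param palindrome_max maximum palindrome mismatches tolerated in a
#'   reported site (default 8, i.e. at least 6 of 10 complementary pairs).
#' @param background `"region"` (per-region base composition; falls back to
#'   the model's own background for empty regions), `"model"` (use the
#'   model's background as built), or a length-4 frequency vector.
#' @param granularity p-value DP bins per column.
#' @param mismatch_max promoter hexamer mismatch tolerance.
#' @return list of configuration values.
#' @export
regulon_config <- function(upstream_length = 400L, p_threshold = 1e-4,
                           palindrome_max = 8L, background = "region",
                           granularity = 1000L, mismatch_max = 2L) {
  stopifnot(upstream_length > 0, p_threshold > 0, palindrome_max >= 0)
  list(upstream_length = upstream_length, p_threshold = p_threshold,
       palindrome_max = palindrome_max, background = background,
       granularity = granularity, mismatch_max = mismatch_max)
}

#' Predict AHL-regulated promoters (lux boxes) upstream of ORFs
#'
#' For every ORF (optionally restricted to contigs called for the target
#' taxon) the upstream region is extracted, scanned with the lux-box PWM on
#' both strands, and sites passing the p-value threshold and the
#' imperfect-palindrome filter are annotated with their genomic interval,
#' intergenic/intragenic location, distance upstream of the start codon,
#' −35/−10 promoter elements and Shine–Dalgarno sequence. When one genomic
#' site lies in the upstream regions of two divergently transcribed ORFs,
#' both candidates are emitted and cross-referenced via
#' `shared_bidirectional_with`. Candidates are ranked by p-value.
#'
#' `distance_upstream` counts the nucleotides strictly between the site's
#' proximal (3') edge and the first base of the start codon.
#'
#' @param contigs named character vector of contigs.
#' @param orfs ORF table.
#' @param model lux-box `"motif_model"` (default width 20).
#' @param config from [regulon_config()].
#' @param target_calls optional contig-call table from
#'   [classify_all_contigs()]; when given, only `is_target` contigs are
#'   scanned.
#' @return data.frame of regulon candidates, ranked by `p_value`: columns
#'   `orf_id`, `contig_id`, `genomic_start`, `genomic_end`, `site_strand`,
#'   `site`, `score`, `p_value`, `palindrome_mismatches`,
#'   `distance_upstream`, `location_class`, `minus35_found`, `minus10_found`,
#'   `promoter_paired`, `sd_found`, `shared_bidirectional_with`, `clipped`.
#' @export
predict_regulon <- function(contigs, orfs, model, config = regulon_config(),
                            target_calls = NULL) {
  if (!is.null(target_calls)) {
    keep <- target_calls$contig_id[target_calls$is_target]
    orfs <- orfs[orfs$contig_id %in% keep, , drop = FALSE]
  }
  empty <- data.frame(orf_id = character(0), contig_id = character(0),
                      genomic_start = integer(0), genomic_end = integer(0),
                      site_strand = character(0), site = character(0),
                      score = numeric(0), p_value = numeric(0),
                      palindrome_mismatches = integer(0),
                      distance_upstream = integer(0),
                      location_class = character(0),
                      minus35_found = logical(0), minus10_found = logical(0),
                      promoter_paired = logical(0), sd_found = logical(0),
                      shared_bidirectional_with = character(0),
                      clipped = logical(0), stringsAsFactors = FALSE)
  if (nrow(orfs) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, , drop = FALSE]
    region <- extract_upstream(orf, contigs[[orf$contig_id]],
                               config$upstream_length)
    if (nchar(region$sequence) < model$width) next
    m <- model
    if (identical(config$background, "region")) {
      m <- set_motif_background(model, sequence_background(region$sequence))
    } else if (is.numeric(config$background)) {
      m <- set_motif_background(model, config$background)
    }
    hits <- suppressWarnings(
      scan_region(m, region, config$p_threshold, config$granularity))
    if (nrow(hits) == 0L) next
    hits <- hits[!is.na(hits$palindrome_mismatches) &
                 hits$palindrome_mismatches <= config$palindrome_max, ,
                 drop = FALSE]
    for (k in seq_len(nrow(hits))) {
      loc <- classify_hit_location(region, hits$offset[[k]], model$width, orfs)
      prom <- find_promoter_elements(region$sequence,
                                     hits$offset[[k]] + model$width - 1L,
                                     config$mismatch_max)
      sd <- find_shine_dalgarno(region$sequence)
      rows[[length(rows) + 1L]] <- data.frame(
        orf_id = orf$orf_id, contig_id = orf$contig_id,
        genomic_start = loc$genomic_start, genomic_end = loc$genomic_end,
        site_strand = hits$strand[[k]], site = hits$site[[k]],
        score = hits$score[[k]], p_value = hits$p_value[[k]],
        palindrome_mismatches = hits$palindrome_mismatches[[k]],
        distance_upstream = nchar(region$sequence) -
          (hits$offset[[k]] + model$width - 1L),
        location_class = loc$location_class,
        minus35_found = prom$minus35$found, minus10_found = prom$minus10$found,
        promoter_paired = prom$paired, sd_found = sd$found,
        shared_bidirectional_with = NA_character_,
        clipped = region$clipped, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  ## cross-reference candidates that share one genomic site (divergent genes)
  key <- paste(out$contig_id, out$genomic_start, out$genomic_end)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 2L && out$orf_id[idx[1]] != out$orf_id[idx[2]]) {
      out$shared_bidirectional_with[idx] <- out$orf_id[rev(idx)]
    }
  }
  out <- out[order(out$p_value, out$orf_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
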