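## Quorum-sensing gene screen: classify ORFs as putative luxI/luxR homologs
## from KO-labelled hits, validate against conserved Pfam domains, and resolve
## cognate luxI/luxR pairs versus luxR solos.

#' KEGG-orthology sets defining the AHL synthase / receptor screen
#'
#' Defaults are the KO groups used to mine AHL machinery from metagenomes:
#' synthases K13060, K13061, K13062 and K18096 (luxI family) and receptors
#' K07782, K18098 and K18099 (luxR family).
#'
#' @param synthase_kos character vector of synthase KO accessions.
#' @param receptor_kos character vector of receptor KO accessions.
#' @return list with elements `synthase_kos` and `receptor_kos`.
#' @export
qs_ko_sets <- function(synthase_kos = c("K13060", "K13061", "K13062", "K18096"),
                       receptor_kos = c("K07782", "K18098", "K18099")) {
  stopifnot(length(synthase_kos) > 0L, length(receptor_kos) > 0L)
  if (length(intersect(synthase_kos, receptor_kos)) > 0L) {
    stop("synthase and receptor KO sets must be disjoint", call. = FALSE)
  }
  ok <- grepl("^K[0-9]{5}$", c(synthase_kos, receptor_kos))
  if (!all(ok)) stop("KO accessions must match K + 5 digits", call. = FALSE)
  list(synthase_kos = synthase_kos, receptor_kos = receptor_kos)
}

#' Classify ORFs as putative luxI/luxR homologs by the best-KO rule
#'
#' An ORF is a candidate iff its best bitscore among QS-KO hits strictly
#' exceeds its best bitscore among all other hits (hits to other KOs, or
#' without a KO label). ORFs whose best QS hit ties the best non-QS hit are
#' rejected and recorded in the `"rejected_ties"` attribute. The result is
#' invariant under permutation and duplication of hit rows.
#'
#' @param hits hit data.frame as from [read_hit_table()].
#' @param ko_sets KO sets from [qs_ko_sets()].
#' @return data.frame of candidates with columns `orf_id`, `role`
#'   (`"synthase"`/`"receptor"`), `best_qs_ko`, `best_qs_score`,
#'   `best_other_score` (`NA` when the ORF has only QS-KO hits) and
#'   `domain_validated` (initialised to `"untested"`).
#' @export
classify_qs_orfs <- function(hits, ko_sets = qs_ko_sets()) {
  qs_kos <- c(ko_sets$synthase_kos, ko_sets$receptor_kos)
  empty <- data.frame(orf_id = character(0), role = character(0),
                      best_qs_ko = character(0), best_qs_score = numeric(0),
                      best_other_score = numeric(0),
                      domain_validated = character(0), stringsAsFactors = FALSE)
  attr(empty, "rejected_ties") <- character(0)
  if (nrow(hits) == 0L) return(empty)

  rows <- lapply(split(hits, hits$orf_id), function(h) {
    is_qs <- !is.na(h$ko_id) & h$ko_id %in% qs_kos
    if (!any(is_qs)) return(NULL)
    qs <- h[is_qs, , drop = FALSE]
    # deterministic winner: highest score, ties broken by KO accession
    qs <- qs[order(-qs$bitscore, qs$ko_id), , drop = FALSE]
    best_qs <- qs$bitscore[[1]]
    best_other <- if (any(!is_qs)) max(h$bitscore[!is_qs]) else NA_real_
    status <- if (is.na(best_other) || best_qs > best_other) "candidate"
              else if (best_qs == best_other) "tie" else "beaten"
    role <- if (qs$ko_id[[1]] %in% ko_sets$synthase_kos) "synthase" else "receptor"
    data.frame(orf_id = h$orf_id[[1]], role = role, best_qs_ko = qs$ko_id[[1]],
               best_qs_score = best_qs, best_other_score = best_other,
               domain_validated = "untested", status = status,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows)) return(empty)
  ties <- rows$orf_id[rows$status == "tie"]
  out <- rows[rows$status == "candidate", setdiff(names(rows), "status"),
              drop = FALSE]
  out <- out[order(out$orf_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected_ties") <- sort(ties)
  out
}

## normalize Pfam accessions so "Pfam00765", "PF00765", "pf00765" all compare
normalize_pfam <- function(x) sub("^PFAM", "PF", toupper(x))

PFAM_SYNTHASE <- "PF00765"                 # autoinducer synthase domain
PFAM_RECEPTOR <- c("PF03472", "PF00196")   # autoinducer-binding + GerE (HTH)

#' Validate QS candidates against conserved Pfam domains
#'
#' Synthase candidates are validated by an autoinducer-synthase domain hit
#' (Pfam00765); receptor candidates require both the autoinducer-binding
#' domain (Pfam03472) and the GerE helix-turn-helix domain (Pfam00196), each
#' at `evalue <= evalue_max`. With an empty domain table every candidate is
#' left `"untested"`.
#'
#' @param candidates data.frame from [classify_qs_orfs()].
#' @param domain_hits data.frame from [read_domain_table()].
#' @param evalue_max maximum e-value for a domain hit to count.
#' @return `candidates` with `domain_validated` set to `"true"`/`"false"`/
#'   `"untested"`.
#' @export
validate_domains <- function(candidates, domain_hits, evalue_max = 1e-5) {
  if (nrow(candidates) == 0L) return(candidates)
  if (is.null(domain_hits) || nrow(domain_hits) == 0L) {
    candidates$domain_validated <- "untested"
    return(candidates)
  }
  stray <- setdiff(unique(domain_hits$orf_id), candidates$orf_id)
  if (length(stray) > 0L) {
    warning("domain hits for unknown ORF(s) ignored: ",
            paste(stray, collapse = ", "))
  }
  dh <- domain_hits[domain_hits$evalue <= evalue_max, , drop = FALSE]
  dh$domain_id <- normalize_pfam(dh$domain_id)
  candidates$domain_validated <- vapply(seq_len(nrow(candidates)), function(i) {
    doms <- dh$domain_id[dh$orf_id == candidates$orf_id[[i]]]
    ok <- if (candidates$role[[i]] == "synthase") PFAM_SYNTHASE %in% doms
          else all(PFAM_RECEPTOR %in% doms)
    if (ok) "true" else "false"
  }, character(1))
  candidates
}

#' Global protein alignment with a reference-position map
#'
#' Needleman-Wunsch global alignment under affine gap penalties (BLOSUM62,
#' gap open 11, gap extend 1 by default — standard protein-search settings),
#' computed with `Biostrings::pairwiseAlignment`. In addition to the optimal
#' score, a map from each reference position to the aligned query residue
#' (or `"-"` for a gap) is returned, so residues can be addressed in
#' reference numbering.
#'
#' @param query,reference amino-acid strings (standard 20-letter alphabet).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param matrix substitution matrix name understood by `Biostrings`.
#' @return list with `score`, `aligned_query`, `aligned_reference`, and
#'   `ref_map` (character vector of length `nchar(reference)`).
#' @export
align_global <- function(query, reference, gap_open = 11, gap_extend = 1,
                         matrix = "BLOSUM62") {
  if (nchar(query) == 0L || nchar(reference) == 0L) {
    stop("empty protein sequence", call. = FALSE)
  }
  check_protein(query, "query")
  check_protein(reference, "reference")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(reference),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  aq <- as.character(Biostrings::alignedPattern(aln))
  ar <- as.character(Biostrings::alignedSubject(aln))
  qc <- chars_of(aq)
  rc <- chars_of(ar)
  ref_map <- qc[rc != "-"]
  names(ref_map) <- as.character(seq_len(nchar(reference)))
  list(score = Biostrings::score(aln), aligned_query = aq,
       aligned_reference = ar, ref_map = ref_map)
}

## annotated conserved positions of the LuxR reference scheme
LUXR_ACYL_POSITIONS <- c(`66` = "W", `79` = "D", `80` = "P", `94` = "W", `121` = "G")
LUXR_DNA_POSITIONS  <- c(`187` = "E", `191` = "L", `197` = "G")

#' Annotated LuxR reference for conserved-residue audits
#'
#' The residue audit addresses positions in the numbering of a reference
#' LuxR: acyl-binding domain W66, D79, P80, W94, G121 and DNA-binding domain
#' E187, L191, G197. The shipped default is a synthetic 210-aa reference with
#' exactly those residues planted at the annotated positions; supply your own
#' reference sequence to use a real numbering scheme.
#'
#' @param sequence amino-acid string carrying the expected residues at the
#'   annotated positions.
#' @return list with `sequence`, `acyl` and `dna` (named character vectors,
#'   names = 1-based reference positions, values = expected residues).
#' @export
luxr_reference <- function(sequence = NULL) {
  if (is.null(sequence)) {
    sequence <- paste0(
      "TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNYKMDSFWFCVT",
      "VFQIIEEHDPPWSTNKMSIGAPQWKSMLLAWTQQRGRMFSTTVCGGGYRCGNKACCMQCCLFLTTFDQQA",
      "FDPMYTYEYMTKTPTYATACISDFPNAWFRGSLHKKDVRRYSAGMKEPFMLCGAQSGMVCLEYRHTFYVK")
  }
  check_protein(sequence, "reference")
  ref <- list(sequence = sequence, acyl = LUXR_ACYL_POSITIONS,
              dna = LUXR_DNA_POSITIONS)
  chars <- chars_of(sequence)
  for (dom in c("acyl", "dna")) {
    pos <- as.integer(names(ref[[dom]]))
    if (max(pos) > length(chars) || any(chars[pos] != unname(ref[[dom]]))) {
      stop("reference lacks the expected residue at an annotated position",
           call. = FALSE)
    }
  }
  ref
}

#' Audit conserved LuxR residues in a candidate protein
#'
#' Globally aligns the candidate to the annotated reference and reports, for
#' each annotated reference position, the aligned query residue and whether
#' it is conserved (exact match). Gapped positions are reported but not
#' counted as missense.
#'
#' @param query candidate protein sequence.
#' @param reference annotated reference from [luxr_reference()].
#' @param ... passed to [align_global()].
#' @return list of class `"conservation_report"` with `orf_id` (`NA` unless
#'   set by the caller), per-domain data.frames `acyl` and `dna` (columns
#'   `position`, `expected`, `observed`, `conserved`), and counts
#'   `missense_acyl`, `missense_dna`, `gaps_acyl`, `gaps_dna`.
#' @export
check_luxr_conservation <- function(query, reference = luxr_reference(), ...) {
  aln <- align_global(query, reference$sequence, ...)
  audit <- function(annot) {
    pos <- as.integer(names(annot))
    observed <- unname(aln$ref_map[as.character(pos)])
    data.frame(position = pos, expected = unname(annot), observed = observed,
               conserved = observed == unname(annot), stringsAsFactors = FALSE)
  }
  acyl <- audit(reference$acyl)
  dna <- audit(reference$dna)
  out <- list(orf_id = NA_character_, acyl = acyl, dna = dna,
              missense_acyl = sum(!acyl$conserved & acyl$observed != "-"),
              missense_dna = sum(!dna$conserved & dna$observed != "-"),
              gaps_acyl = sum(acyl$observed == "-"),
              gaps_dna = sum(dna$observed == "-"))
  class(out) <- "conservation_report"
  out
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("LuxR conserved-residue audit",
      if (!is.na(x$orf_id)) paste0(" for ", x$orf_id), "\n", sep = "")
  cat(sprintf("  acyl-binding: %d/%d conserved, %d missense, %d gap(s)\n",
              sum(x$acyl$conserved), nrow(x$acyl), x$missense_acyl, x$gaps_acyl))
  cat(sprintf("  DNA-binding:  %d/%d conserved, %d missense, %d gap(s)\n",
              sum(x$dna$conserved), nrow(x$dna), x$missense_dna, x$gaps_dna))
  invisible(x)
}

#' Resolve cognate luxI/luxR pairs and luxR solos
#'
#' Synthase and receptor candidates on the same contig separated by at most
#' `max_intervening` ORFs (in contig order of start positions) are paired,
#' nearest first; each ORF joins at most one pair. Receptors left unpaired
#' are luxR "solos". Pair orientation is classified from the strands of the
#' two genes: `divergent` (transcribed away from each other), `convergent`
#' (toward each other) or `tandem` (same strand).
#'
#' @param candidates data.frame from [classify_qs_orfs()].
#' @param orfs ORF data.frame.
#' @param max_intervening maximum number of ORFs allowed between the pair.
#' @return list with `pairs` (data.frame: `synthase`, `receptor`,
#'   `intervening`, `orientation`), `solo_receptors`, `unpaired_synthases`.
#' @export
pair_lux_genes <- function(candidates, orfs, max_intervening = 3L) {
  empty_pairs <- data.frame(synthase = character(0), receptor = character(0),
                            intervening = integer(0), orientation = character(0),
                            stringsAsFactors = FALSE)
  synth <- candidates$orf_id[candidates$role == "synthase"]
  recep <- candidates$orf_id[candidates$role == "receptor"]
  if (length(synth) == 0L || length(recep) == 0L || nrow(orfs) == 0L) {
    return(list(pairs = empty_pairs, solo_receptors = sort(recep),
                unpaired_synthases = sort(synth)))
  }
  missing <- setdiff(c(synth, recep), orfs$orf_id)
  if (length(missing) > 0L) {
    stop("candidate ORF(s) absent from ORF table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ord <- orfs[order(orfs$contig_id, orfs$start, orfs$orf_id), , drop = FALSE]
  ord$index <- stats::ave(seq_len(nrow(ord)), ord$contig_id, FUN = seq_along)
  info <- ord[match(c(synth, recep), ord$orf_id), , drop = FALSE]
  rownames(info) <- info$orf_id

  combos <- expand.grid(synthase = synth, receptor = recep,
                        stringsAsFactors = FALSE)
  combos <- combos[info[combos$synthase, "contig_id"] ==
                   info[combos$receptor, "contig_id"], , drop = FALSE]
  if (nrow(combos) > 0L) {
    combos$intervening <- abs(info[combos$synthase, "index"] -
                              info[combos$receptor, "index"]) - 1L
    combos <- combos[combos$intervening <= max_intervening, , drop = FALSE]
    combos <- combos[order(combos$intervening, combos$synthase,
                           combos$receptor), , drop = FALSE]
  }
  pairs <- empty_pairs
  used <- character(0)
  for (i in seq_len(nrow(combos))) {
    s <- combos$synthase[[i]]; r <- combos$receptor[[i]]
    if (s %in% used || r %in% used) next
    used <- c(used, s, r)
    left <- if (info[s, "start"] <= info[r, "start"]) s else r
    right <- if (identical(left, s)) r else s
    ls <- info[left, "strand"]; rs <- info[right, "strand"]
    orientation <- if (ls == rs) "tandem"
                   else if (ls == "-" && rs == "+") "divergent"
                   else "convergent"
    pairs <- rbind(pairs, data.frame(synthase = s, receptor = r,
                                     intervening = combos$intervening[[i]],
                                     orientation = orientation,
                                     stringsAsFactors = FALSE))
  }
  list(pairs = pairs,
       solo_receptors = sort(setdiff(recep, pairs$receptor)),
       unpaired_synthases = sort(setdiff(synth, pairs$synthase)))
}
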