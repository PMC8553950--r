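## Per-ORF consensus function + LCA taxonomy from best-score hit windows, and
## tiered target-taxon contig binning.

#' Parameters of the best-score hit window
#'
#' For each ORF, annotation uses the hits whose bitscore is within
#' `sbest_factor` of the best hit's bitscore (the "Sbest window";
#' default factor 0.95).
#'
#' @param sbest_factor real in (0, 1].
#' @param strict if `TRUE`, a hit exactly on the `sbest_factor * Sbest`
#'   boundary is excluded; the default keeps it (floating-point-safe).
#' @return list of window parameters.
#' @export
window_params <- function(sbest_factor = 0.95, strict = FALSE) {
  if (!(sbest_factor > 0 && sbest_factor <= 1)) {
    stop("sbest_factor must be in (0, 1]", call. = FALSE)
  }
  list(sbest_factor = sbest_factor, strict = strict)
}

#' Select the best-score window of one ORF's hits
#'
#' @param hits hit rows for a single ORF.
#' @param params from [window_params()].
#' @return the subset of rows with `bitscore >= sbest_factor * max(bitscore)`
#'   (`>` under `strict`, but the best hit itself is always kept).
#' @export
best_score_window <- function(hits, params = window_params()) {
  if (nrow(hits) == 0L) return(hits)
  sbest <- max(hits$bitscore)
  cut <- params$sbest_factor * sbest
  keep <- if (params$strict) hits$bitscore > cut | hits$bitscore == sbest
          else hits$bitscore >= cut
  hits[keep, , drop = FALSE]
}

#' Majority-rule consensus function label of a hit window
#'
#' @param window hit rows (the Sbest window of one ORF).
#' @return the label held by a strict majority (> 50%) of the labelled hits,
#'   or `"ambiguous"` when no label has one (including ties and all-unlabelled
#'   windows).
#' @export
consensus_function <- function(window) {
  labels <- window$function_label
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) return("ambiguous")
  tab <- table(labels)
  top <- which(tab > length(labels) / 2)
  if (length(top) == 1L) names(tab)[top] else "ambiguous"
}

#' Lowest common ancestor of a hit window's lineages
#'
#' @param window hit rows; rows without a `taxonomy` lineage are excluded.
#' @return character vector of `rank:name` elements — the deepest lineage
#'   that is a prefix of every hit's lineage; `character(0)` (unclassified)
#'   when no hit carries taxonomy.
#' @export
lca_taxon <- function(window) {
  lineages <- window$taxonomy
  lineages <- lineages[!is.na(lineages) & nzchar(lineages)]
  if (length(lineages) == 0L) return(character(0))
  paths <- lapply(lineages, parse_lineage)
  common <- paths[[1]]
  for (p in paths[-1]) {
    k <- min(length(common), length(p))
    if (k == 0L) return(character(0))
    same <- common[seq_len(k)] == p[seq_len(k)]
    depth <- if (all(same)) k else (which(!same)[1] - 1L)
    if (depth == 0L) return(character(0))
    common <- common[seq_len(depth)]
  }
  common
}

#' Assign consensus function and LCA taxonomy to every ORF
#'
#' @param hits full hit table (grouped internally by `orf_id`).
#' @param params window parameters from [window_params()].
#' @param orf_ids optional character vector of all ORF ids; ids without hits
#'   are reported as unclassified with `window_size = 0`.
#' @return data.frame with columns `orf_id`, `window_size`,
#'   `consensus_function`, `lca_path` (semicolon-joined lineage or `NA`).
#' @export
assign_orf_taxonomy <- function(hits, params = window_params(), orf_ids = NULL) {
  groups <- if (nrow(hits) > 0L) split(hits, hits$orf_id) else list()
  rows <- lapply(names(groups), function(id) {
    win <- best_score_window(groups[[id]], params)
    data.frame(orf_id = id, window_size = nrow(win),
               consensus_function = consensus_function(win),
               lca_path = format_lineage(lca_taxon(win)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(orf_id = character(0), window_size = integer(0),
               consensus_function = character(0), lca_path = character(0),
               stringsAsFactors = FALSE)
  hitless <- setdiff(orf_ids %||% character(0), out$orf_id)
  if (length(hitless) > 0L) {
    out <- rbind(out, data.frame(orf_id = hitless, window_size = 0L,
                                 consensus_function = "ambiguous",
                                 lca_path = NA_character_,
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$orf_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tiered ORF-fraction rule for target-taxon contig calls
#'
#' The default tiers encode the empirical binning rule: a contig belongs to
#' the target taxon if (i) more than 50% of its ORFs are target and it has
#' more than 6 ORFs; (ii) more than 60% are target and it has 4-6 ORFs; or
#' (iii) 100% are target and it has at most 3 ORFs. Tier (iii) as published
#' covers fewer than 3 ORFs only; it is extended here to 3 ORFs (still
#' requiring 100%) so every positive ORF count is covered, and its firing at
#' exactly 3 ORFs is flagged in reports.
#'
#' @param tiers data.frame with columns `label`, `min_orfs`, `max_orfs`,
#'   `min_fraction`, `strict` (strict `>` vs `>=` on the fraction).
#' @return the tier table (validated).
#' @export
tier_rule <- function(tiers = NULL) {
  if (is.null(tiers)) {
    tiers <- data.frame(label = c("i", "ii", "iii"),
                        min_orfs = c(7L, 4L, 1L),
                        max_orfs = c(Inf, 6L, 3L),
                        min_fraction = c(0.5, 0.6, 1.0),
                        strict = c(TRUE, TRUE, FALSE),
                        stringsAsFactors = FALSE)
  }
  covered <- vapply(1:1000, function(n) any(n >= tiers$min_orfs & n <= tiers$max_orfs),
                    logical(1))
  if (!all(covered)) {
    stop("tier rule leaves ORF count(s) uncovered: ",
         paste(head(which(!covered)), collapse = ", "), call. = FALSE)
  }
  tiers
}

#' Does an ORF's lineage fall under the target taxon?
#'
#' Membership is prefix-based: an ORF counts as target when the `rank:name`
#' element appears in its LCA lineage, so a genus-level target matches any
#' deeper classification under that genus.
#'
#' @param lca_path semicolon-joined lineage string (or `NA`).
#' @param target_taxon a single `rank:name` string, e.g. `"genus:Nitrospira"`.
#' @return logical scalar.
#' @export
is_target_taxon <- function(lca_path, target_taxon) {
  if (is.na(lca_path)) return(FALSE)
  target_taxon %in% parse_lineage(lca_path)
}

#' Call one contig for the target taxon by the tiered rule
#'
#' @param assignments per-ORF assignment rows (from [assign_orf_taxonomy()])
#'   for a single contig.
#' @param target_taxon a `rank:name` string.
#' @param rule tier table from [tier_rule()].
#' @return one-row data.frame: `n_orfs`, `n_target`, `fraction`,
#'   `tier_applied` (tier label, `"iii*"` when the extended tier fires at
#'   exactly 3 ORFs, or `"none"`), `is_target`.
#' @export
classify_contig_taxon <- function(assignments, target_taxon, rule = tier_rule()) {
  n_orfs <- nrow(assignments)
  n_target <- if (n_orfs > 0L)
    sum(vapply(assignments$lca_path, is_target_taxon, logical(1),
               target_taxon = target_taxon, USE.NAMES = FALSE)) else 0L
  fraction <- if (n_orfs > 0L) n_target / n_orfs else 0
  tier_applied <- "none"
  is_target <- FALSE
  if (n_orfs > 0L) {
    j <- which(n_orfs >= rule$min_orfs & n_orfs <= rule$max_orfs)[1]
    if (!is.na(j)) {
      tier_applied <- rule$label[[j]]
      is_target <- if (rule$strict[[j]]) fraction > rule$min_fraction[[j]]
                   else fraction >= rule$min_fraction[[j]]
      if (tier_applied == "iii" && n_orfs == 3L) tier_applied <- "iii*"
    }
  }
  data.frame(n_orfs = n_orfs, n_target = as.integer(n_target),
             fraction = fraction, tier_applied = tier_applied,
             is_target = is_target, stringsAsFactors = FALSE)
}

#' Call every contig for the target taxon
#'
#' @param assignments per-ORF assignments from [assign_orf_taxonomy()].
#' @param orfs ORF table (maps ORF ids to contigs).
#' @param target_taxon a `rank:name` string.
#' @param rule tier table from [tier_rule()].
#' @return data.frame with one row per contig present in `orfs`: `contig_id`,
#'   `n_orfs`, `n_target`, `fraction`, `tier_applied`, `is_target`.
#' @export
classify_all_contigs <- function(assignments, orfs, target_taxon,
                                 rule = tier_rule()) {
  contig_of <- setNames(orfs$contig_id, orfs$orf_id)
  assignments$contig_id <- contig_of[assignments$orf_id]
  rows <- lapply(sort(unique(orfs$contig_id)), function(cid) {
    a <- assignments[!is.na(assignments$contig_id) &
                     assignments$contig_id == cid, , drop = FALSE]
    cbind(data.frame(contig_id = cid, stringsAsFactors = FALSE),
          classify_contig_taxon(a, target_taxon, rule))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(contig_id = character(0), n_orfs = integer(0),
                      n_target = integer(0), fraction = numeric(0),
                      tier_applied = character(0), is_target = logical(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
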