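# Shared fixtures and independent oracles used across the suite.

BASES <- c("A", "C", "G", "T")

random_dna_str <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# one hit-table row
hit_row <- function(orf_id, bitscore, ko = NA_character_, fun = NA_character_,
                    tax = NA_character_, subject = "sbj") {
  data.frame(orf_id = orf_id, subject_id = subject, bitscore = bitscore,
             ko_id = ko, function_label = fun, taxonomy = tax,
             stringsAsFactors = FALSE)
}

hit_table <- function(...) do.call(rbind, list(...))

# write a temporary FASTA from raw text
tmp_file <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# one-row ORF record
orf_row <- function(orf_id, contig_id, start, end, strand,
                    protein = NA_character_) {
  data.frame(orf_id = orf_id, contig_id = contig_id, start = start, end = end,
             strand = strand, protein = protein, stringsAsFactors = FALSE)
}

# ---- independent oracles --------------------------------------------------

# longest-common-prefix LCA over parsed lineages (element-wise comparison)
oracle_lca <- function(paths) {
  if (length(paths) == 0L) return(character(0))
  k <- min(lengths(paths))
  depth <- 0L
  for (i in seq_len(k)) {
    elems <- vapply(paths, `[`, character(1), i)
    if (length(unique(elems)) == 1L) depth <- i else break
  }
  if (depth == 0L) character(0) else paths[[1]][seq_len(depth)]
}

# strict-majority consensus over labels
oracle_majority <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) return("ambiguous")
  tab <- table(labels)
  win <- names(tab)[tab > length(labels) / 2]
  if (length(win) == 1L) win else "ambiguous"
}

# brute-force optimal global alignment score under affine gaps: enumerate
# every alignment (sequences of M / gap-in-query / gap-in-ref moves) of two
# short peptides; gap runs cost open + len * extend
oracle_align_score <- function(query, reference, gap_open = 11, gap_extend = 1) {
  submat <- NULL
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  submat <- get("BLOSUM62", envir = environment())
  q <- strsplit(query, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, last_gap) {
    if (i > length(q) && j > length(r)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(q) && j <= length(r)) {
      recurse(i + 1L, j + 1L, score + submat[q[i], r[j]], "none")
    }
    if (i <= length(q)) {   # gap in reference (query residue unmatched)
      cost <- gap_extend + if (last_gap == "ref") 0 else gap_open
      recurse(i + 1L, j, score - cost, "ref")
    }
    if (j <= length(r)) {   # gap in query
      cost <- gap_extend + if (last_gap == "query") 0 else gap_open
      recurse(i, j + 1L, score - cost, "query")
    }
  }
  recurse(1L, 1L, 0, "none")
  best
}

# exhaustive p-value: enumerate all 4^w sequences under the background
oracle_pvalue <- function(model, threshold) {
  w <- model$width
  grids <- rep(list(BASES), w)
  seqs <- do.call(paste0, rev(expand.grid(rev(grids), stringsAsFactors = FALSE)))
  probs <- rep(1, length(seqs))
  for (k in seq_len(w)) {
    base_k <- substr(seqs, k, k)
    probs <- probs * model$background[base_k]
  }
  scores <- vapply(seqs, function(s) score_site(model, s), numeric(1))
  sum(probs[scores >= threshold])
}

# substitute k random positions of a DNA string (always to a different base)
mutate_dna <- function(site, k) {
  ch <- strsplit(site, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  paste(ch, collapse = "")
}
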