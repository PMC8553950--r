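## Readers and writers for every external format the pipeline touches.
## Contigs are named character vectors (names = ids); ORFs, hits and domain
## hits are plain data.frames so every downstream module can be inspected and
## subset with base tools.

#' Read assembled contigs from a FASTA file
#'
#' Headers are truncated at the first whitespace to form the contig id;
#' sequences are upper-cased and must be over \{A,C,G,T,N\}. RNA (U) is
#' rejected rather than silently converted.
#'
#' @param path path to a FASTA file.
#' @return named character vector of contig sequences (names = ids), with the
#'   full header lines kept in attribute `"descriptions"`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  desc <- names(set)
  ids <- vapply(strsplit(desc, "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("FASTA record with empty id", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate id(s) in FASTA: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    if (grepl("U", seqs[[i]], fixed = TRUE)) {
      stop("RNA base 'U' in record '", ids[[i]], "'; DNA expected", call. = FALSE)
    }
    check_dna(seqs[[i]], what = paste0("record '", ids[[i]], "'"))
    if (nchar(seqs[[i]]) == 0L) stop("empty sequence in record '", ids[[i]], "'", call. = FALSE)
  }
  out <- setNames(unname(seqs), ids)
  attr(out, "descriptions") <- setNames(desc, ids)
  out
}

#' Write contigs (or any named DNA set) to FASTA
#'
#' @param contigs named character vector as returned by [read_fasta()].
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  set <- Biostrings::BStringSet(setNames(as.character(contigs), names(contigs)))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read ORF calls from a GFF3 file of CDS features
#'
#' Coordinates are kept 1-based inclusive; the `ID` attribute becomes the ORF
#' id. ORFs must be stranded and must fit inside their named contig.
#'
#' @param path path to a GFF3 file.
#' @param contigs named character vector of contigs the ORFs live on.
#' @return data.frame with columns `orf_id`, `contig_id`, `start`, `end`,
#'   `strand` and (all-`NA`) `protein`.
#' @export
read_orfs_gff <- function(path, contigs) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gff <- rtracklayer::readGFF(path, filter = list(type = "CDS"))
  gff <- as.data.frame(gff)
  if (nrow(gff) == 0L) {
    return(data.frame(orf_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), protein = character(0),
                      stringsAsFactors = FALSE))
  }
  ids <- as.character(gff$ID)
  if (anyNA(ids)) stop("CDS feature without ID attribute", call. = FALSE)
  orfs <- data.frame(orf_id = ids,
                     contig_id = as.character(gff$seqid),
                     start = as.integer(gff$start),
                     end = as.integer(gff$end),
                     strand = as.character(gff$strand),
                     protein = NA_character_,
                     stringsAsFactors = FALSE)
  validate_orfs(orfs, contigs)
}

## shared invariant checks for an ORF table against its contigs
validate_orfs <- function(orfs, contigs) {
  if (anyDuplicated(orfs$orf_id)) {
    stop("duplicate ORF id(s): ",
         paste(unique(orfs$orf_id[duplicated(orfs$orf_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_strand <- !(orfs$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    stop("unstranded or invalid strand for ORF(s): ",
         paste(orfs$orf_id[bad_strand], collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(orfs$contig_id, names(contigs))
  if (length(unknown) > 0L) {
    stop("ORF(s) reference unknown contig(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  len <- nchar(contigs)[orfs$contig_id]
  bad <- orfs$start < 1L | orfs$end > len | orfs$start > orfs$end
  if (any(bad)) {
    stop("ORF coordinates outside contig for: ",
         paste(orfs$orf_id[bad], collapse = ", "), call. = FALSE)
  }
  orfs
}

#' Write an ORF table as GFF3 CDS features
#'
#' @param orfs ORF data.frame as from [read_orfs_gff()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orfs_gff <- function(orfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(orfs) > 0L) {
    writeLines(sprintf("%s\tluxscreen\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       orfs$contig_id, orfs$start, orfs$end, orfs$strand,
                       orfs$orf_id), con)
  }
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Like [read_fasta()] but validated against the standard 20-letter
#' amino-acid alphabet.
#'
#' @param path path to a protein FASTA file.
#' @return named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate id(s) in FASTA: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    check_protein(seqs[[i]], what = paste0("record '", ids[[i]], "'"))
  }
  setNames(unname(seqs), ids)
}

#' Attach protein sequences to an ORF table
#'
#' @param orfs ORF data.frame.
#' @param proteins named character vector of amino-acid sequences keyed by
#'   ORF id (e.g. from [read_fasta()] on a protein FASTA read with
#'   `Biostrings`, or supplied directly).
#' @return the ORF table with its `protein` column filled where ids match.
#' @export
attach_proteins <- function(orfs, proteins) {
  hit <- orfs$orf_id %in% names(proteins)
  orfs$protein[hit] <- unname(proteins[orfs$orf_id[hit]])
  orfs
}

HIT_STD_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a tabular protein-search hit table
#'
#' Consumes the standard 12-column tabular search format (BLAST/DIAMOND
#' `outfmt 6`) with optional named extension columns `ko_id`,
#' `function_label` and `taxonomy` (a semicolon-joined `rank:name` lineage).
#' An optional header line starting with `#` names the columns.
#'
#' @param path path to a tab-separated hit table.
#' @return data.frame with columns `orf_id`, `subject_id`, `bitscore`, plus
#'   `ko_id`, `function_label`, `taxonomy` (`NA` where absent).
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  cols <- HIT_STD_COLS
  header_offset <- 0L
  if (length(lines) > 0L && startsWith(lines[[1]], "#")) {
    cols <- strsplit(sub("^#\\s*", "", lines[[1]]), "\t")[[1]]
    lines <- lines[-1L]
    header_offset <- 1L
  }
  lines <- lines[nzchar(lines)]
  empty <- data.frame(orf_id = character(0), subject_id = character(0),
                      bitscore = numeric(0), ko_id = character(0),
                      function_label = character(0), taxonomy = character(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop("hit table line ", which(nf < 12L)[1] + header_offset,
         " has fewer than 12 columns", call. = FALSE)
  }
  get_col <- function(name, idx) {
    j <- if (name %in% cols) match(name, cols) else idx
    if (is.na(j)) return(rep(NA_character_, length(fields)))
    out <- vapply(fields, function(f) if (j <= length(f)) f[[j]] else NA_character_,
                  character(1))
    out[out %in% c(".", "")] <- NA_character_   # "." is the missing marker
    out
  }
  bits_raw <- get_col("bitscore", 12L)
  bits <- suppressWarnings(as.numeric(bits_raw))
  if (anyNA(bits)) {
    stop("non-numeric bitscore at line ", which(is.na(bits))[1] + header_offset,
         ": '", bits_raw[which(is.na(bits))[1]], "'", call. = FALSE)
  }
  if (any(bits < 0)) stop("negative bitscore in hit table", call. = FALSE)
  ko <- get_col("ko_id", NA_integer_)
  ok_ko <- is.na(ko) | grepl("^K[0-9]{5}$", ko)
  if (!all(ok_ko)) {
    stop("malformed KO accession '", ko[!ok_ko][1], "' (expected K + 5 digits)",
         call. = FALSE)
  }
  data.frame(orf_id = get_col("qseqid", 1L),
             subject_id = get_col("sseqid", 2L),
             bitscore = bits,
             ko_id = ko,
             function_label = get_col("function_label", NA_integer_),
             taxonomy = get_col("taxonomy", NA_integer_),
             stringsAsFactors = FALSE)
}

#' Write a hit table with extension columns
#'
#' @param hits data.frame as from [read_hit_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(c(HIT_STD_COLS, "ko_id", "function_label",
                                 "taxonomy"), collapse = "\t")), con)
  if (nrow(hits) > 0L) {
    na2dot <- function(x) ifelse(is.na(x), ".", x)
    writeLines(sprintf("%s\t%s\t0\t0\t0\t0\t0\t0\t0\t0\t0\t%s\t%s\t%s\t%s",
                       hits$orf_id, hits$subject_id,
                       format(hits$bitscore, trim = TRUE, scientific = FALSE),
                       na2dot(hits$ko_id), na2dot(hits$function_label),
                       na2dot(hits$taxonomy)), con)
  }
  invisible(path)
}

#' Read a conserved-domain hit table
#'
#' Tab-separated with columns `orf_id`, `domain_id`, `score`, `evalue`
#' (header line starting `#` optional). Stands in for parsed HMMER/Pfam
#' output.
#'
#' @param path path to the table.
#' @return data.frame with those four columns.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   col.names = c("orf_id", "domain_id", "score", "evalue"),
                   colClasses = c("character", "character", "numeric", "numeric"),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L && any(df$evalue < 0)) {
    stop("negative e-value in domain table", call. = FALSE)
  }
  df
}

#' Write a conserved-domain hit table
#' @param domains data.frame as from [read_domain_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#orf_id\tdomain_id\tscore\tevalue", con)
  if (nrow(domains) > 0L) {
    writeLines(sprintf("%s\t%s\t%g\t%g", domains$orf_id, domains$domain_id,
                       domains$score, domains$evalue), con)
  }
  invisible(path)
}

#' Read an aligned motif-site library from FASTA
#'
#' All sites must share one length (the motif width); only A/C/G/T/N are
#' allowed, other IUPAC ambiguity codes are rejected.
#'
#' @param path path to a FASTA of aligned DNA sites.
#' @return character vector of sites (names = ids) with attribute `"width"`.
#' @export
read_motif_library <- function(path) {
  sites <- read_fasta(path)
  widths <- nchar(sites)
  if (length(unique(widths)) > 1L) {
    off <- names(sites)[widths != widths[[1]]]
    stop("motif sites of unequal length: ", paste(off, collapse = ", "),
         call. = FALSE)
  }
  attr(sites, "descriptions") <- NULL
  attr(sites, "width") <- unname(widths[1] %||% 0L)
  sites
}

## ---- taxonomy lineage strings -------------------------------------------

#' Parse a semicolon-joined `rank:name` lineage
#'
#' @param lineage character scalar like
#'   `"superkingdom:Bacteria;phylum:Nitrospirae"`, or `NA`.
#' @return character vector of `rank:name` elements, root first;
#'   `character(0)` for `NA`/empty input.
#' @export
parse_lineage <- function(lineage) {
  if (length(lineage) != 1L) stop("parse_lineage takes one lineage string")
  if (is.na(lineage) || !nzchar(lineage)) return(character(0))
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (any(!grepl(":", parts, fixed = TRUE))) {
    stop("lineage element without 'rank:name' form: ", lineage, call. = FALSE)
  }
  ranks <- sub(":.*$", "", parts)
  if (anyDuplicated(ranks)) stop("repeated rank in lineage: ", lineage, call. = FALSE)
  parts
}

#' Join lineage elements back into a lineage string
#' @param path character vector of `rank:name` elements.
#' @return semicolon-joined string, or `NA` for an empty path.
#' @export
format_lineage <- function(path) {
  if (length(path) == 0L) return(NA_character_)
  paste(path, collapse = ";")
}

#' Write a data.frame as a TSV report
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}
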