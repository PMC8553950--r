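## Seeded synthetic communities with planted ground truth: contigs, ORFs,
## hit and domain tables, motif libraries and lux boxes, plus a manifest
## sufficient to score any downstream recovery experiment.

LUXBOX_CONSENSUS <- "ACCTGGCGGTTCCGCCAGGT"   # common lux box, 2 palindrome mismatches

#' Generate an aligned lux-box site library by mutating a consensus
#'
#' Each of the `n` sites is an independent per-position mutation of the
#' consensus: every position is substituted (to a different base, uniformly)
#' with probability `mutation_rate`, so the per-site Hamming distance to the
#' consensus is Binomial(width, rate). Deterministic under `seed`.
#'
#' @param consensus DNA string; must itself be an imperfect palindrome
#'   (at most 8 mismatches against its reverse complement).
#' @param n number of sites (default 54).
#' @param mutation_rate per-position substitution probability in \[0, 0.5\].
#' @param seed integer seed (mandatory).
#' @return character vector of `n` sites with attribute `"width"`.
#' @export
generate_motif_library <- function(consensus = LUXBOX_CONSENSUS, n = 54L,
                                   mutation_rate = 0.05, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 0.5) {
    stop("mutation_rate must be in [0, 0.5]", call. = FALSE)
  }
  if (palindrome_mismatches(consensus) > 8L) {
    stop("consensus is not an imperfect palindrome (more than 8 mismatches)",
         call. = FALSE)
  }
  set.seed(child_seed(seed, "motif_library"))
  w <- nchar(consensus)
  base <- chars_of(consensus)
  sites <- vapply(seq_len(n), function(i) {
    mut <- runif(w) < mutation_rate
    out <- base
    if (any(mut)) {
      out[mut] <- vapply(base[mut], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1))
    }
    paste(out, collapse = "")
  }, character(1))
  names(sites) <- sprintf("site%02d", seq_len(n))
  attr(sites, "width") <- w
  sites
}

## substitute `k` random positions of a DNA string with different bases
mutate_site <- function(site, k) {
  if (k == 0L) return(site)
  chars <- chars_of(site)
  pos <- sample(seq_along(chars), k)
  chars[pos] <- vapply(chars[pos], function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1))
  paste(chars, collapse = "")
}

#' Configuration of a synthetic community
#'
#' Defaults emulate a small sludge-like community: a handful of multi-kb
#' contigs from two lineages, one cognate luxI/luxR pair arranged divergently
#' on a target-lineage contig with a lux box planted 81 bp upstream of the
#' synthase (the geometry of the characterised Nitrospira synthase
#' promoter), one luxR solo, and a 54-site
#' lux-box library mutated at 5% per column.
#'
#' @param n_contigs number of contigs.
#' @param contig_length `c(min, max)` contig length range in bp.
#' @param orf_density ORFs per kb.
#' @param gc_content background GC fraction.
#' @param taxa data.frame with columns `lineage` (semicolon `rank:name`
#'   strings) and `weight`.
#' @param target_taxon `rank:name` string the pipeline should recover.
#' @param n_luxI number of planted AHL synthase genes.
#' @param n_luxR_paired receptors placed divergently next to a synthase.
#' @param n_luxR_solo receptors without a cognate synthase.
#' @param luxbox_distance nucleotides strictly between the planted box's
#'   proximal edge and the synthase start codon (default 81; at most 380).
#' @param luxbox_mutations substitutions applied to each planted box.
#' @param plant_promoter_elements also write consensus −35/−10 (17 bp
#'   spacer) and a Shine–Dalgarno element into the synthase upstream region.
#' @param solo_missense_range `c(min, max)` acyl-domain missense mutations
#'   planted in each solo receptor's protein.
#' @param motif_consensus lux-box consensus used for the library and plants.
#' @param library_size,library_mutation_rate motif library parameters.
#' @param offtarget_fraction probability that a background ORF on a planted
#'   (target-lineage) contig is annotated with a non-target lineage.
#' @param seed integer root seed (mandatory).
#' @return list of class `"community_config"`.
#' @export
community_config <- function(n_contigs = 6L,
                             contig_length = c(5000L, 12000L),
                             orf_density = 1.0,
                             gc_content = 0.5,
                             taxa = NULL,
                             target_taxon = "genus:Nitrospira",
                             n_luxI = 1L, n_luxR_paired = 1L, n_luxR_solo = 1L,
                             luxbox_distance = 81L, luxbox_mutations = 0L,
                             plant_promoter_elements = TRUE,
                             solo_missense_range = c(1L, 3L),
                             motif_consensus = LUXBOX_CONSENSUS,
                             library_size = 54L, library_mutation_rate = 0.05,
                             offtarget_fraction = 0,
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(taxa)) {
    taxa <- data.frame(
      lineage = c("superkingdom:Bacteria;phylum:Nitrospirae;genus:Nitrospira",
                  "superkingdom:Bacteria;phylum:Proteobacteria;genus:Pseudomonas"),
      weight = c(0.4, 0.6), stringsAsFactors = FALSE)
  }
  if (any(taxa$weight <= 0)) stop("taxa weights must be positive", call. = FALSE)
  if (luxbox_distance > 380L) stop("luxbox_distance must be <= 380", call. = FALSE)
  cfg <- list(n_contigs = n_contigs, contig_length = contig_length,
              orf_density = orf_density, gc_content = gc_content, taxa = taxa,
              target_taxon = target_taxon, n_luxI = n_luxI,
              n_luxR_paired = n_luxR_paired, n_luxR_solo = n_luxR_solo,
              luxbox_distance = luxbox_distance,
              luxbox_mutations = luxbox_mutations,
              plant_promoter_elements = plant_promoter_elements,
              solo_missense_range = solo_missense_range,
              motif_consensus = motif_consensus, library_size = library_size,
              library_mutation_rate = library_mutation_rate,
              offtarget_fraction = offtarget_fraction, seed = as.integer(seed))
  class(cfg) <- "community_config"
  cfg
}

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

## write `what` into `sequence` at 1-based position `at`
splice_into <- function(sequence, what, at) {
  stopifnot(at >= 1L, at + nchar(what) - 1L <= nchar(sequence))
  paste0(substr(sequence, 1L, at - 1L), what,
         substr(sequence, at + nchar(what), nchar(sequence)))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[sort(names(unclass(cfg)))], tmp)
  unname(tools::md5sum(tmp))
}

#' Generate a synthetic community with planted ground truth
#'
#' Builds contigs, ORF calls, a KO/taxonomy-annotated hit table, a Pfam-style
#' domain table, receptor protein sequences and a truth manifest, all
#' cross-consistent and byte-deterministic under the config seed. Planted
#' luxI/luxR genes receive hit rows that make the best-KO rule true; each
#' cognate pair is arranged divergently with a lux box planted at the
#' configured distance upstream of the synthase (inside both genes' upstream
#' regions); background ORFs receive decoy hits consistent with their
#' contig's lineage.
#'
#' @param config a [community_config()].
#' @return list with `contigs` (named character vector), `orfs` (data.frame,
#'   receptor proteins attached), `hits`, `domains`, `library` (aligned
#'   sites), `truth` (manifest list) and `config`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  cfg <- config
  n_pairs <- min(cfg$n_luxI, cfg$n_luxR_paired)
  extra_synth <- cfg$n_luxI - n_pairs
  planted_contigs <- n_pairs + extra_synth + cfg$n_luxR_solo
  if (planted_contigs > cfg$n_contigs) {
    stop("not enough contigs for the planted genes; increase n_contigs",
         call. = FALSE)
  }
  if (cfg$orf_density > 2.5) {
    stop("infeasible ORF placement: orf_density too high", call. = FALSE)
  }

  set.seed(child_seed(cfg$seed, "contigs"))
  lens <- as.integer(round(runif(cfg$n_contigs, cfg$contig_length[1],
                                 cfg$contig_length[2])))
  if (planted_contigs > 0L && any(lens[seq_len(planted_contigs)] < 3500L)) {
    stop("contigs hosting planted genes must be at least 3.5 kb", call. = FALSE)
  }
  contig_ids <- sprintf("ctg%03d", seq_len(cfg$n_contigs))
  contigs <- setNames(vapply(lens, random_dna, character(1),
                             gc = cfg$gc_content), contig_ids)

  target_lineages <- cfg$taxa$lineage[vapply(cfg$taxa$lineage, function(l) {
    cfg$target_taxon %in% parse_lineage(l)
  }, logical(1))]
  if (planted_contigs > 0L && length(target_lineages) == 0L) {
    stop("no taxon in `taxa` falls under target_taxon", call. = FALSE)
  }
  nontarget <- setdiff(cfg$taxa$lineage, target_lineages)
  lineages <- character(cfg$n_contigs)
  lineages[seq_len(planted_contigs)] <- target_lineages[[1]]
  if (planted_contigs < cfg$n_contigs) {
    rest <- (planted_contigs + 1L):cfg$n_contigs
    lineages[rest] <- sample(cfg$taxa$lineage, length(rest), replace = TRUE,
                             prob = cfg$taxa$weight)
  }

  ## ---- ORF placement -----------------------------------------------------
  set.seed(child_seed(cfg$seed, "orfs"))
  orf_rows <- list()
  truth_rows <- list()
  pair_rows <- list()
  box_rows <- list()
  orf_n <- 0L
  new_id <- function() { orf_n <<- orf_n + 1L; sprintf("orf%04d", orf_n) }

  add_orf <- function(cid, start, end, strand, role, lineage) {
    id <- new_id()
    orf_rows[[length(orf_rows) + 1L]] <<- data.frame(
      orf_id = id, contig_id = cid, start = start, end = end, strand = strand,
      protein = NA_character_, stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      orf_id = id, contig_id = cid, role = role, lineage = lineage,
      stringsAsFactors = FALSE)
    id
  }

  fill_background <- function(cid, from, to, lineage, n_needed) {
    placed <- 0L
    pos <- from
    while (placed < n_needed && pos + 300L <= to) {
      len <- sample(300:900, 1L)
      if (pos + len - 1L > to) len <- to - pos + 1L
      if (len < 150L) break
      lin <- lineage
      if (length(nontarget) > 0L && runif(1) < cfg$offtarget_fraction) {
        lin <- sample(nontarget, 1L)
      }
      add_orf(cid, pos, pos + len - 1L, sample(c("+", "-"), 1L),
              "background", lin)
      placed <- placed + 1L
      pos <- pos + len + sample(50:200, 1L)
    }
    placed
  }

  w <- nchar(cfg$motif_consensus)
  ci <- 0L
  pair_geometry <- list()
  for (p in seq_len(n_pairs)) {
    ci <- ci + 1L
    cid <- contig_ids[[ci]]
    # divergent arrangement: receptor on -, synthase on +, 220 bp between
    r_start <- 1000L; r_end <- 1700L
    s_start <- r_end + 221L; s_end <- s_start + 779L
    rid <- add_orf(cid, r_start, r_end, "-", "receptor_paired", lineages[[ci]])
    sid <- add_orf(cid, s_start, s_end, "+", "synthase", lineages[[ci]])
    pair_rows[[p]] <- data.frame(synthase = sid, receptor = rid,
                                 contig_id = cid, stringsAsFactors = FALSE)
    pair_geometry[[p]] <- list(cid = cid, sid = sid, rid = rid,
                               s_start = s_start, r_end = r_end)
    n_left <- max(0L, as.integer(round(cfg$orf_density * lens[[ci]] / 1000)) - 2L)
    fill_background(cid, s_end + 150L, lens[[ci]] - 50L, lineages[[ci]], n_left)
  }
  for (k in seq_len(extra_synth)) {
    ci <- ci + 1L
    cid <- contig_ids[[ci]]
    add_orf(cid, 1000L, 1800L, "+", "synthase", lineages[[ci]])
    n_left <- max(0L, as.integer(round(cfg$orf_density * lens[[ci]] / 1000)) - 1L)
    fill_background(cid, 1950L, lens[[ci]] - 50L, lineages[[ci]], n_left)
  }
  solo_ids <- character(0)
  for (k in seq_len(cfg$n_luxR_solo)) {
    ci <- ci + 1L
    cid <- contig_ids[[ci]]
    solo_ids <- c(solo_ids, add_orf(cid, 1000L, 1700L, "+", "receptor_solo",
                                    lineages[[ci]]))
    n_left <- max(0L, as.integer(round(cfg$orf_density * lens[[ci]] / 1000)) - 1L)
    fill_background(cid, 1850L, lens[[ci]] - 50L, lineages[[ci]], n_left)
  }
  for (ci2 in seq_len(cfg$n_contigs)) {
    if (ci2 > ci) {
      cid <- contig_ids[[ci2]]
      n_needed <- max(1L, as.integer(round(cfg$orf_density * lens[[ci2]] / 1000)))
      fill_background(cid, 200L, lens[[ci2]] - 50L, lineages[[ci2]], n_needed)
    }
  }
  orfs <- do.call(rbind, orf_rows)
  truth_orfs <- do.call(rbind, truth_rows)

  ## ---- lux-box (and promoter element) planting ---------------------------
  set.seed(child_seed(cfg$seed, "boxes"))
  for (p in seq_along(pair_geometry)) {
    g <- pair_geometry[[p]]
    site <- mutate_site(cfg$motif_consensus, cfg$luxbox_mutations)
    box_end <- g$s_start - cfg$luxbox_distance - 1L   # proximal (3') edge
    box_start <- box_end - w + 1L
    stopifnot(box_start > g$r_end)   # box must sit in the intergenic gap
    contigs[[g$cid]] <- splice_into(contigs[[g$cid]], site, box_start)
    if (cfg$plant_promoter_elements) {
      contigs[[g$cid]] <- splice_into(contigs[[g$cid]], "TTGACA", box_end + 7L)
      contigs[[g$cid]] <- splice_into(contigs[[g$cid]], "TATAAT",
                                      box_end + 7L + 6L + 17L)
      contigs[[g$cid]] <- splice_into(contigs[[g$cid]], "AGGAGG", g$s_start - 13L)
    }
    dist_receptor <- box_start - g$r_end - 1L
    box_rows[[p]] <- data.frame(
      contig_id = g$cid, genomic_start = box_start, genomic_end = box_end,
      site = site, n_mutations = cfg$luxbox_mutations,
      synthase = g$sid, receptor = g$rid,
      distance_synthase = cfg$luxbox_distance,
      distance_receptor = dist_receptor, stringsAsFactors = FALSE)
  }

  ## ---- hit table ---------------------------------------------------------
  set.seed(child_seed(cfg$seed, "hits"))
  kos <- qs_ko_sets()
  decoy_kos <- c("K00001", "K00012", "K01952", "K02335", "K03088")
  hit_rows <- list()
  add_hit <- function(orf_id, subject, bits, ko = NA_character_,
                      fun = NA_character_, tax = NA_character_) {
    hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
      orf_id = orf_id, subject_id = subject, bitscore = bits, ko_id = ko,
      function_label = fun, taxonomy = tax, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(truth_orfs))) {
    id <- truth_orfs$orf_id[[i]]
    lin <- truth_orfs$lineage[[i]]
    role <- truth_orfs$role[[i]]
    if (role == "synthase") {
      add_hit(id, "ref|luxI", 250, sample(kos$synthase_kos, 1L),
              "acyl-homoserine-lactone synthase", lin)
      add_hit(id, "ref|decoy", 180, sample(decoy_kos, 1L),
              "hypothetical protein", lin)
      add_hit(id, "ref|self", 150, NA_character_,
              "acyl-homoserine-lactone synthase", lin)
    } else if (role %in% c("receptor_paired", "receptor_solo")) {
      add_hit(id, "ref|luxR", 250, sample(kos$receptor_kos, 1L),
              "LuxR family transcriptional regulator", lin)
      add_hit(id, "ref|decoy", 180, sample(decoy_kos, 1L),
              "hypothetical protein", lin)
      add_hit(id, "ref|self", 150, NA_character_,
              "LuxR family transcriptional regulator", lin)
    } else {
      base <- runif(1, 80, 150)
      fun <- "hypothetical protein"
      for (j in 1:3) {
        add_hit(id, sprintf("ref|bg%d", j), round(base * (1 - 0.02 * (j - 1)), 1),
                sample(decoy_kos, 1L), fun, lin)
      }
    }
  }
  hits <- do.call(rbind, hit_rows)

  ## ---- domain table and receptor proteins --------------------------------
  domain_rows <- list()
  for (i in seq_len(nrow(truth_orfs))) {
    id <- truth_orfs$orf_id[[i]]
    role <- truth_orfs$role[[i]]
    if (role == "synthase") {
      domain_rows[[length(domain_rows) + 1L]] <- data.frame(
        orf_id = id, domain_id = "Pfam00765", score = 150, evalue = 1e-20,
        stringsAsFactors = FALSE)
    } else if (role %in% c("receptor_paired", "receptor_solo")) {
      domain_rows[[length(domain_rows) + 1L]] <- data.frame(
        orf_id = rep(id, 2L), domain_id = c("Pfam03472", "Pfam00196"),
        score = c(120, 90), evalue = c(1e-18, 1e-12), stringsAsFactors = FALSE)
    }
  }
  domains <- if (length(domain_rows) > 0L) do.call(rbind, domain_rows) else
    data.frame(orf_id = character(0), domain_id = character(0),
               score = numeric(0), evalue = numeric(0), stringsAsFactors = FALSE)

  set.seed(child_seed(cfg$seed, "proteins"))
  ref <- luxr_reference()
  mut_rows <- list()
  receptor_ids <- truth_orfs$orf_id[truth_orfs$role %in%
                                    c("receptor_paired", "receptor_solo")]
  for (id in receptor_ids) {
    chars <- chars_of(ref$sequence)
    if (id %in% solo_ids) {
      k <- sample(cfg$solo_missense_range[1]:cfg$solo_missense_range[2], 1L)
      pos <- sample(as.integer(names(ref$acyl)), k)
      for (p in pos) {
        to <- sample(setdiff(chars_of(AA_ALPHABET), chars[[p]]), 1L)
        chars[[p]] <- to
        mut_rows[[length(mut_rows) + 1L]] <- data.frame(
          orf_id = id, position = p, from = chars_of(ref$sequence)[[p]],
          to = to, stringsAsFactors = FALSE)
      }
    }
    orfs$protein[orfs$orf_id == id] <- paste(chars, collapse = "")
  }
  planted_mutations <- if (length(mut_rows) > 0L) do.call(rbind, mut_rows) else
    data.frame(orf_id = character(0), position = integer(0),
               from = character(0), to = character(0), stringsAsFactors = FALSE)

  library_sites <- generate_motif_library(cfg$motif_consensus,
                                          cfg$library_size,
                                          cfg$library_mutation_rate,
                                          seed = cfg$seed)

  truth <- list(
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    target_taxon = cfg$target_taxon,
    contigs = data.frame(contig_id = contig_ids, length = lens,
                         lineage = lineages,
                         is_target = lineages %in% target_lineages,
                         stringsAsFactors = FALSE),
    orfs = truth_orfs,
    pairs = if (length(pair_rows) > 0L) do.call(rbind, pair_rows) else
      data.frame(synthase = character(0), receptor = character(0),
                 contig_id = character(0), stringsAsFactors = FALSE),
    solo_receptors = solo_ids,
    boxes = if (length(box_rows) > 0L) do.call(rbind, box_rows) else
      data.frame(contig_id = character(0), genomic_start = integer(0),
                 genomic_end = integer(0), site = character(0),
                 n_mutations = integer(0), synthase = character(0),
                 receptor = character(0), distance_synthase = integer(0),
                 distance_receptor = integer(0), stringsAsFactors = FALSE),
    planted_luxr_mutations = planted_mutations)

  list(contigs = contigs, orfs = validate_orfs(orfs, contigs), hits = hits,
       domains = domains, library = library_sites, truth = truth,
       config = cfg)
}

#' Write a synthetic community to disk in the pipeline's input formats
#'
#' Emits `contigs.fasta`, `orfs.gff3`, `hits.tsv`, `domains.tsv`,
#' `proteins.fasta` (receptor proteins), `library.fasta` and `truth.json`.
#'
#' @param community list from [generate_community()].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(contigs = file.path(dir, "contigs.fasta"),
             orfs = file.path(dir, "orfs.gff3"),
             hits = file.path(dir, "hits.tsv"),
             domains = file.path(dir, "domains.tsv"),
             proteins = file.path(dir, "proteins.fasta"),
             library = file.path(dir, "library.fasta"),
             truth = file.path(dir, "truth.json"))
  write_fasta(community$contigs, paths[["contigs"]])
  write_orfs_gff(community$orfs, paths[["orfs"]])
  write_hit_table(community$hits, paths[["hits"]])
  write_domain_table(community$domains, paths[["domains"]])
  prot <- community$orfs[!is.na(community$orfs$protein), , drop = FALSE]
  write_fasta(setNames(prot$protein, prot$orf_id), paths[["proteins"]])
  write_fasta(setNames(as.character(community$library),
                       names(community$library)), paths[["library"]])
  jsonlite::write_json(community$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Degrade a hit table with score ties and hit dropouts
#'
#' For each ORF that carries a QS-KO hit, with probability `tie_fraction` a
#' decoy non-QS hit is added whose bitscore equals the ORF's best QS-KO
#' bitscore (defeating the strict best-KO rule). Independently, each ORF
#' loses all of its hits with probability `dropout_fraction`. The applied
#' corruptions are recorded in the `"corruption"` attribute.
#'
#' @param hits hit data.frame.
#' @param tie_fraction,dropout_fraction probabilities in \[0, 1\].
#' @param seed integer seed.
#' @param ko_sets QS KO sets (defaults to [qs_ko_sets()]).
#' @return the degraded hit table.
#' @export
corrupt_hits <- function(hits, tie_fraction = 0, dropout_fraction = 0, seed,
                         ko_sets = qs_ko_sets()) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(tie_fraction >= 0, tie_fraction <= 1,
            dropout_fraction >= 0, dropout_fraction <= 1)
  set.seed(child_seed(seed, "corrupt"))
  qs_kos <- c(ko_sets$synthase_kos, ko_sets$receptor_kos)
  out <- hits
  record <- data.frame(orf_id = character(0), action = character(0),
                       stringsAsFactors = FALSE)
  qs_orfs <- unique(hits$orf_id[!is.na(hits$ko_id) & hits$ko_id %in% qs_kos])
  for (id in qs_orfs) {
    if (runif(1) < tie_fraction) {
      sub <- out[out$orf_id == id, , drop = FALSE]
      best_qs <- max(sub$bitscore[!is.na(sub$ko_id) & sub$ko_id %in% qs_kos])
      out <- rbind(out, data.frame(orf_id = id, subject_id = "ref|tie_decoy",
                                   bitscore = best_qs, ko_id = "K00001",
                                   function_label = "hypothetical protein",
                                   taxonomy = NA_character_,
                                   stringsAsFactors = FALSE))
      record <- rbind(record, data.frame(orf_id = id, action = "tie",
                                         stringsAsFactors = FALSE))
    }
  }
  for (id in unique(out$orf_id)) {
    if (runif(1) < dropout_fraction) {
      out <- out[out$orf_id != id, , drop = FALSE]
      record <- rbind(record, data.frame(orf_id = id, action = "dropout",
                                         stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  attr(out, "corruption") <- record
  out
}
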