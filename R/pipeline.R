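## Full-screen orchestration (genes -> taxonomy -> target contigs -> regulon)
## and the GFP reporter fold-induction statistic.

#' Assemble a run configuration for [run_screen()]
#'
#' Either file paths (read with the formats_io readers) or an in-memory
#' community from [generate_community()] can be supplied.
#'
#' @param community optional list from [generate_community()].
#' @param contigs,orfs,hits,domains,proteins,library input file paths (used
#'   when `community` is `NULL`; `domains`, `proteins` optional).
#' @param out_dir run directory for reports, summary and log.
#' @param target_taxon `rank:name` string.
#' @param ko_sets from [qs_ko_sets()].
#' @param window from [window_params()].
#' @param tiers from [tier_rule()].
#' @param max_intervening cognate-pairing distance in ORFs.
#' @param evalue_max Pfam validation e-value cutoff.
#' @param pseudocount PWM pseudocount.
#' @param regulon from [regulon_config()].
#' @param fold_cutoff reporter fold-induction cutoff (strict `>`).
#' @param seed echoed into the summary for provenance.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(community = NULL, contigs = NULL, orfs = NULL,
                       hits = NULL, domains = NULL, proteins = NULL,
                       library = NULL, out_dir = tempfile("luxscreen_run_"),
                       target_taxon = "genus:Nitrospira",
                       ko_sets = qs_ko_sets(), window = window_params(),
                       tiers = tier_rule(), max_intervening = 3L,
                       evalue_max = 1e-5, pseudocount = 0.1,
                       regulon = regulon_config(), fold_cutoff = 1.5,
                       seed = NA_integer_) {
  cfg <- list(community = community, contigs = contigs, orfs = orfs,
              hits = hits, domains = domains, proteins = proteins,
              library = library, out_dir = out_dir,
              target_taxon = target_taxon, ko_sets = ko_sets, window = window,
              tiers = tiers, max_intervening = max_intervening,
              evalue_max = evalue_max, pseudocount = pseudocount,
              regulon = regulon, fold_cutoff = fold_cutoff, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML or JSON file
#'
#' Recognised keys mirror the arguments of [run_config()]; nested parameter
#' blocks (`window`, `regulon`) are passed through to their constructors.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (key in c("contigs", "orfs", "hits", "domains", "proteins", "library",
                "out_dir", "target_taxon", "max_intervening", "evalue_max",
                "pseudocount", "fold_cutoff", "seed")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$window)) args$window <- do.call(window_params, raw$window)
  if (!is.null(raw$regulon)) args$regulon <- do.call(regulon_config, raw$regulon)
  if (!is.null(raw$ko_sets)) args$ko_sets <- do.call(qs_ko_sets, raw$ko_sets)
  do.call(run_config, args)
}

#' Run the full quorum-sensing screen
#'
#' Stages, in order: load inputs; classify putative luxI/luxR ORFs by the
#' best-KO rule; validate conserved domains; audit LuxR conserved residues
#' (where receptor proteins are available); resolve cognate pairs and solos;
#' assign per-ORF consensus function and LCA taxonomy; call target-taxon
#' contigs by the tiered rule; build the lux-box PWM from the aligned
#' library; predict the regulon on target contigs. Every stage's parameters
#' are echoed to the run log; the run is deterministic given identical
#' inputs.
#'
#' @param config a `"run_config"` (or path readable by [read_run_config()]).
#' @return list with all stage outputs (`candidates`, `conservation`,
#'   `pairing`, `assignments`, `contig_calls`, `model`, `regulon`) and
#'   `summary` (named counts); reports, `summary.json` and `run.log` are
#'   written under `config$out_dir`.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logf <- function(fmt, ...) {
    writeLines(sprintf("%s %s", iso_now(), sprintf(fmt, ...)), log_con)
  }
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      logf("stage %s: ERROR %s", name, conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ## -- load ---------------------------------------------------------------
  inputs <- stage("load", {
    if (!is.null(config$community)) {
      cm <- config$community
      list(contigs = cm$contigs, orfs = cm$orfs, hits = cm$hits,
           domains = cm$domains, library = cm$library)
    } else {
      contigs <- read_fasta(config$contigs)
      orfs <- read_orfs_gff(config$orfs, contigs)
      if (!is.null(config$proteins)) {
        orfs <- attach_proteins(orfs, read_protein_fasta(config$proteins))
      }
      list(contigs = contigs, orfs = orfs,
           hits = read_hit_table(config$hits),
           domains = if (!is.null(config$domains))
             read_domain_table(config$domains) else NULL,
           library = read_motif_library(config$library))
    }
  })
  logf("inputs: %d contigs, %d ORFs, %d hits", length(inputs$contigs),
       nrow(inputs$orfs), nrow(inputs$hits))
  if (nrow(inputs$hits) == 0L) warning("empty hit table: screen will be empty")

  candidates <- stage("classify_qs_orfs", {
    logf("params: synthase KOs {%s}, receptor KOs {%s}",
         paste(config$ko_sets$synthase_kos, collapse = ","),
         paste(config$ko_sets$receptor_kos, collapse = ","))
    classify_qs_orfs(inputs$hits, config$ko_sets)
  })
  logf("candidates: %d (ties rejected: %d)", nrow(candidates),
       length(attr(candidates, "rejected_ties")))

  candidates <- stage("validate_domains", {
    logf("params: evalue_max %g", config$evalue_max)
    validate_domains(candidates, inputs$domains, config$evalue_max)
  })

  conservation <- stage("check_luxr_conservation", {
    recs <- candidates$orf_id[candidates$role == "receptor"]
    prot <- setNames(inputs$orfs$protein, inputs$orfs$orf_id)[recs]
    rows <- lapply(recs[!is.na(prot[recs])], function(id) {
      rep <- check_luxr_conservation(prot[[id]])
      cbind(data.frame(orf_id = id, stringsAsFactors = FALSE),
            rbind(cbind(rep$acyl, domain = "acyl_binding"),
                  cbind(rep$dna, domain = "dna_binding")))
    })
    if (length(rows) > 0L) do.call(rbind, rows) else
      data.frame(orf_id = character(0), position = integer(0),
                 expected = character(0), observed = character(0),
                 conserved = logical(0), domain = character(0),
                 stringsAsFactors = FALSE)
  })

  pairing <- stage("pair_lux_genes", {
    logf("params: max_intervening %d", config$max_intervening)
    pair_lux_genes(candidates, inputs$orfs, config$max_intervening)
  })

  assignments <- stage("assign_orf_taxonomy", {
    logf("params: sbest_factor %g", config$window$sbest_factor)
    assign_orf_taxonomy(inputs$hits, config$window,
                        orf_ids = inputs$orfs$orf_id)
  })

  contig_calls <- stage("classify_contig_taxon", {
    logf("params: target_taxon %s", config$target_taxon)
    classify_all_contigs(assignments, inputs$orfs, config$target_taxon,
                         config$tiers)
  })

  model <- stage("build_motif", {
    logf("params: pseudocount %g, %d library sites", config$pseudocount,
         length(inputs$library))
    build_motif(as.character(inputs$library), config$pseudocount)
  })

  regulon <- stage("predict_regulon", {
    logf("params: upstream %d bp, p < %g, palindrome_max %d",
         config$regulon$upstream_length, config$regulon$p_threshold,
         config$regulon$palindrome_max)
    predict_regulon(inputs$contigs, inputs$orfs, model, config$regulon,
                    target_calls = contig_calls)
  })

  ## -- reports ------------------------------------------------------------
  cand_report <- candidates
  partner <- c(setNames(pairing$pairs$receptor, pairing$pairs$synthase),
               setNames(pairing$pairs$synthase, pairing$pairs$receptor))
  cls <- c(setNames(pairing$pairs$orientation, pairing$pairs$synthase),
           setNames(pairing$pairs$orientation, pairing$pairs$receptor))
  cand_report$pair_partner <- unname(partner[cand_report$orf_id])
  cand_report$pairing_class <- unname(cls[cand_report$orf_id])
  cand_report$pairing_class[is.na(cand_report$pairing_class) &
                            cand_report$role == "receptor"] <- "solo"

  write_tsv_report(cand_report, file.path(config$out_dir, "candidates.tsv"))
  write_tsv_report(conservation, file.path(config$out_dir, "conservation.tsv"))
  write_tsv_report(assignments, file.path(config$out_dir, "assignments.tsv"))
  write_tsv_report(contig_calls, file.path(config$out_dir, "contig_calls.tsv"))
  write_tsv_report(regulon, file.path(config$out_dir, "regulon.tsv"))
  write_meme_motif(model, file.path(config$out_dir, "motif.meme"))

  summary <- list(n_orfs = nrow(inputs$orfs),
                  n_candidates = nrow(candidates),
                  n_luxI = sum(candidates$role == "synthase"),
                  n_luxR = sum(candidates$role == "receptor"),
                  n_luxR_paired = nrow(pairing$pairs),
                  n_luxR_solo = length(pairing$solo_receptors),
                  n_target_contigs = sum(contig_calls$is_target),
                  n_regulon_candidates = nrow(regulon),
                  target_taxon = config$target_taxon,
                  seed = config$seed)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("summary: %s", paste(sprintf("%s=%s", names(summary), unlist(summary)),
                            collapse = " "))

  list(candidates = cand_report, conservation = conservation,
       pairing = pairing, assignments = assignments,
       contig_calls = contig_calls, model = model, regulon = regulon,
       summary = summary, out_dir = config$out_dir)
}

#' GFP reporter fold induction
#'
#' For each sample, GFP fluorescence is normalized to OD600 per replicate;
#' the fold induction is the mean normalized signal of the induced
#' replicates over the mean of the uninduced replicates, and a sample is
#' called induced when the fold strictly exceeds `cutoff` (default 1.5).
#'
#' @param measurements data.frame with columns `sample`, `condition`
#'   (`"induced"`/`"uninduced"`), `gfp`, `od600` (and optionally
#'   `replicate`).
#' @param cutoff fold-induction cutoff (strict `>`).
#' @return data.frame with one row per sample: `sample`, `fold`, `induced`.
#' @export
fold_induction <- function(measurements, cutoff = 1.5) {
  req <- c("sample", "condition", "gfp", "od600")
  if (!all(req %in% names(measurements))) {
    stop("measurements need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(measurements$od600 <= 0)) stop("od600 must be > 0", call. = FALSE)
  rows <- lapply(split(measurements, measurements$sample), function(m) {
    norm <- m$gfp / m$od600
    ind <- norm[m$condition == "induced"]
    un <- norm[m$condition == "uninduced"]
    if (length(ind) == 0L || length(un) == 0L) {
      stop("sample '", m$sample[[1]], "' lacks a condition", call. = FALSE)
    }
    if (mean(un) <= 0) {
      stop("uninduced mean signal <= 0 for sample '", m$sample[[1]], "'",
           call. = FALSE)
    }
    fold <- mean(ind) / mean(un)
    data.frame(sample = m$sample[[1]], fold = fold, induced = fold > cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read reporter measurements from CSV
#'
#' Expected columns: `sample`, `condition`, `replicate`, `gfp`, `od600`.
#'
#' @param path CSV file path.
#' @return data.frame of measurements.
#' @export
read_reporter_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition", "gfp", "od600") %in% names(df))) {
    stop("reporter CSV needs columns sample, condition, gfp, od600",
         call. = FALSE)
  }
  df
}
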