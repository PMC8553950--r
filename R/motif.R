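## Position weight matrix over an aligned lux-box library, log-odds scoring,
## and exact p-values by convolving per-column score distributions.

DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from aligned sites
#'
#' Counts are tallied per column and converted to log-odds as
#' `log2((counts + pseudocount) / (N + 4 * pseudocount) / background)`.
#'
#' @param sites character vector of equal-length DNA sites over \{A,C,G,T\}
#'   (at least 2; N is disallowed in training).
#' @param pseudocount positive real added to every cell.
#' @param background length-4 base frequencies (A, C, G, T) summing to 1;
#'   all strictly positive.
#' @return object of class `"motif_model"`: list with `width`, `nsites`,
#'   `counts` (width x 4 matrix), `pseudocount`, `background`, `log_odds`.
#' @export
build_motif <- function(sites, pseudocount = 0.1,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  sites <- as.character(sites)
  if (length(sites) < 2L) stop("need at least 2 aligned sites", call. = FALSE)
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("sites of unequal length", call. = FALSE)
  for (s in sites) {
    if (grepl("N", s, fixed = TRUE)) {
      stop("ambiguous base N not allowed in training sites", call. = FALSE)
    }
    check_dna(s, "motif site", allow_n = FALSE)
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  background <- validate_background(background)
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  counts <- t(apply(mat, 2, function(col) {
    vapply(DNA_BASES, function(b) sum(col == b), numeric(1))
  }))
  dimnames(counts) <- list(NULL, DNA_BASES)
  n <- length(sites)
  model <- list(width = w, nsites = n, counts = counts,
                pseudocount = pseudocount, background = background,
                log_odds = motif_log_odds(counts, n, pseudocount, background))
  class(model) <- "motif_model"
  model
}

validate_background <- function(background) {
  if (length(background) != 4L) stop("background must have 4 frequencies", call. = FALSE)
  if (any(background <= 0)) stop("zero or negative background frequency", call. = FALSE)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1", call. = FALSE)
  setNames(as.numeric(background), DNA_BASES)
}

motif_log_odds <- function(counts, n, pseudocount, background) {
  probs <- (counts + pseudocount) / (n + 4 * pseudocount)
  lo <- log2(sweep(probs, 2, background, "/"))
  dimnames(lo) <- dimnames(counts)
  lo
}

#' Replace a motif model's background and recompute its log-odds
#'
#' Used when scanning against a locally-estimated (per-region) background.
#'
#' @param model a `"motif_model"`.
#' @param background length-4 base frequencies.
#' @return the model with `background` and `log_odds` updated.
#' @export
set_motif_background <- function(model, background) {
  background <- validate_background(background)
  model$background <- background
  model$log_odds <- motif_log_odds(model$counts, model$nsites,
                                   model$pseudocount, background)
  model
}

#' Base composition of a sequence as a background estimate
#'
#' Add-one smoothed so that no frequency is zero; N is ignored.
#'
#' @param sequence DNA string.
#' @return length-4 named frequency vector (A, C, G, T).
#' @export
sequence_background <- function(sequence) {
  chars <- if (nchar(sequence) > 0L) chars_of(sequence) else character(0)
  counts <- vapply(DNA_BASES, function(b) sum(chars == b), numeric(1))
  (counts + 1) / (sum(counts) + 4)
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("PWM motif model: width %d, %d training sites, pseudocount %g\n",
              x$width, x$nsites, x$pseudocount))
  cat("consensus:", motif_consensus(x), "\n")
  invisible(x)
}

#' @export
#' @method summary motif_model
summary.motif_model <- function(object, ...) {
  print(object)
  cat("background:", paste(sprintf("%s=%.3f", DNA_BASES, object$background),
                           collapse = " "), "\n")
  cat("log-odds score range: [",
      sprintf("%.3f", sum(apply(object$log_odds, 1, min))), ", ",
      sprintf("%.3f", sum(apply(object$log_odds, 1, max))), "]\n", sep = "")
  invisible(object)
}

#' Column-wise consensus of a motif model
#' @param model a `"motif_model"`.
#' @return DNA string of per-column most frequent bases.
#' @export
motif_consensus <- function(model) {
  paste(DNA_BASES[apply(model$counts, 1, which.max)], collapse = "")
}

#' Log-odds score of one site under a motif model
#'
#' `N` contributes 0 (the background-expected contribution).
#'
#' @param model a `"motif_model"`.
#' @param site DNA string of length `model$width`.
#' @return numeric log-odds score.
#' @export
score_site <- function(model, site) {
  if (nchar(site) != model$width) {
    stop("site length ", nchar(site), " does not match motif width ",
         model$width, call. = FALSE)
  }
  check_dna(site, "site")
  chars <- chars_of(site)
  contrib <- numeric(model$width)
  known <- chars != "N"
  idx <- match(chars[known], DNA_BASES)
  contrib[known] <- model$log_odds[cbind(which(known), idx)]
  # left-to-right double accumulation, bit-identical to the p-value DP's
  # prefix sums, so score ties are resolved consistently
  total <- 0
  for (x in contrib) total <- total + x
  total
}

## Exact score distribution for small widths: convolve per-column score
## distributions keeping every achievable total (support <= 4^w). Additions
## run left-to-right so totals match score_site() bit-for-bit.
exact_score_distribution <- function(model) {
  totals <- unname(model$log_odds[1, ])
  probs <- unname(model$background)
  if (model$width > 1L) {
    for (j in 2:model$width) {
      m <- length(totals)
      # each prefix total is extended by the 4 possible column scores;
      # addition stays left-to-right so totals match score_site() exactly
      totals <- rep(totals, each = 4L) + rep(unname(model$log_odds[j, ]), times = m)
      probs <- rep(probs, each = 4L) * rep(unname(model$background), times = m)
    }
  }
  ord <- order(totals)
  list(totals = totals[ord], probs = unname(probs[ord]))
}

## Discretized score distribution: per-column integer scores on a shared
## scale with `granularity` bins spanning the widest column range.
discrete_score_distribution <- function(model, granularity) {
  lo <- model$log_odds
  col_min <- apply(lo, 1, min)
  col_range <- apply(lo, 1, max) - col_min
  scale <- granularity / max(col_range, 1e-12)
  int_scores <- round(sweep(lo, 1, col_min, "-") * scale)
  total_max <- sum(apply(int_scores, 1, max))
  probs <- numeric(total_max + 1L)
  probs[1L] <- 1
  for (j in seq_len(model$width)) {
    nxt <- numeric(total_max + 1L)
    for (b in 1:4) {
      s <- int_scores[j, b]
      p <- model$background[[b]]
      if (p > 0) {
        src <- seq_len(total_max + 1L - s)
        nxt[src + s] <- nxt[src + s] + probs[src] * p
      }
    }
    probs <- nxt
  }
  list(int_probs = probs, offset = sum(col_min), scale = scale)
}

#' Exact p-value of a motif score under the background model
#'
#' Computes `P(score of a random width-mer >= score)` where the random
#' sequence is drawn i.i.d. from the model's background. Per-column score
#' distributions are convolved by dynamic programming: exactly (over all
#' achievable score sums) for widths up to 10, and on a discretized scale
#' with `granularity` bins per column for wider motifs.
#'
#' @param model a `"motif_model"`.
#' @param score query log-odds score.
#' @param granularity integer >= 100; bins per column for the discretized DP.
#' @return p-value in (0, 1]; a score above the maximum achievable returns
#'   the minimum positive mass of the distribution, never 0.
#' @export
motif_score_pvalue <- function(model, score, granularity = 1000L) {
  motif_pvalue_fun(model, granularity)(score)
}

#' Precompute a score-to-p-value lookup for repeated queries
#'
#' @inheritParams motif_score_pvalue
#' @return a function mapping a numeric score to its p-value; shares the
#'   semantics of [motif_score_pvalue()].
#' @export
motif_pvalue_fun <- function(model, granularity = 1000L) {
  if (granularity < 100L) stop("granularity must be >= 100", call. = FALSE)
  if (model$width <= 10L) {
    dist <- exact_score_distribution(model)
    ## tail mass from the top; totals sorted ascending
    tail_from <- rev(cumsum(rev(dist$probs)))
    min_mass <- min(dist$probs[dist$probs > 0])
    function(score) {
      n_below <- findInterval(score, dist$totals, left.open = TRUE)
      p <- if (n_below >= length(dist$totals)) 0 else tail_from[[n_below + 1L]]
      if (p <= 0) min_mass else min(p, 1)
    }
  } else {
    dist <- discrete_score_distribution(model, granularity)
    tail_from <- rev(cumsum(rev(dist$int_probs)))
    pos <- dist$int_probs[dist$int_probs > 0]
    min_mass <- if (length(pos) > 0) min(pos) else .Machine$double.xmin
    function(score) {
      t_int <- ceiling((score - dist$offset) * dist$scale - 1e-9)
      t_int <- max(t_int, 0)
      p <- if (t_int + 1 > length(tail_from)) 0 else tail_from[[t_int + 1L]]
      if (p <= 0) min_mass else min(p, 1)
    }
  }
}

#' Number of palindrome mismatches of a DNA site
#'
#' Positions at which the site differs from its own reverse complement; a
#' perfect palindrome scores 0 and the count is always even. Lux boxes are
#' imperfect palindromes, typically with few mismatched pairs.
#'
#' @param site even-length DNA string without N.
#' @return integer in `0..nchar(site)`.
#' @export
palindrome_mismatches <- function(site) {
  if (nchar(site) %% 2L != 0L) {
    stop("palindrome check requires an even-length site", call. = FALSE)
  }
  check_dna(site, "site", allow_n = FALSE)
  hamming(site, revcomp(site))
}

#' Serialize a motif model to MEME minimal format
#'
#' Writes the position probability matrix (counts + pseudocount, normalized)
#' as a MEME-minimal motif file for interoperability with FIMO-style tools.
#'
#' @param model a `"motif_model"`.
#' @param path output path.
#' @param name motif name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_meme_motif <- function(model, path, name = "luxbox") {
  ppm <- (model$counts + model$pseudocount) /
    (model$nsites + 4 * model$pseudocount)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, model$background),
                     collapse = " "), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       model$width, model$nsites)), con)
  writeLines(apply(ppm, 1, function(r) paste(sprintf("%.6f", r), collapse = "  ")),
             con)
  invisible(path)
}
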