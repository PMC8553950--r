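## Small shared helpers. DNA is carried as plain upper-case character strings
## over {A,C,G,T,N}; coordinates are 1-based inclusive everywhere they are
## user-visible.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings over \{A,C,G,T,N\}.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    comp <- DNA_COMPLEMENT[chars]
    if (anyNA(comp)) stop("non-ACGTN character in DNA string: ", s, call. = FALSE)
    paste(rev(comp), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## split a string into single characters
chars_of <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## validate a DNA string; returns invisibly or stops naming `what`
check_dna <- function(s, what = "sequence", allow_n = TRUE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", s)
  if (nchar(bad) > 0L) {
    stop(sprintf("non-%s character(s) '%s' in %s", alphabet,
                 paste(unique(chars_of(bad)), collapse = ""), what),
         call. = FALSE)
  }
  invisible(s)
}

AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"

check_protein <- function(s, what = "protein") {
  bad <- gsub(sprintf("[%s]", AA_ALPHABET), "", s)
  if (nchar(bad) > 0L) {
    stop(sprintf("non-standard residue(s) '%s' in %s",
                 paste(unique(chars_of(bad)), collapse = ""), what),
         call. = FALSE)
  }
  invisible(s)
}

## count of mismatches between equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(chars_of(a) != chars_of(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic child seed derived from a root seed and a stream label
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) * 1009L + as.integer(h %% 1000003L)) %% 2147483587L
}

iso_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
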