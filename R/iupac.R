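# IUPAC nucleotide degeneracy semantics, primer representation, and
# enumeration/sampling of non-degenerate primer variants.

# Degeneracy sets for the 15-letter IUPAC nucleotide alphabet (U folded into T).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Normalize a nucleotide string to the internal IUPAC alphabet
#'
#' Uppercases, converts U to T, and validates every character against the
#' 15-letter IUPAC nucleotide alphabet.
#'
#' @param seq A character scalar.
#' @param what Label used in error messages (e.g. `"primer"`).
#' @return The normalized string.
#' @keywords internal
normalize_iupac <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) {
    stop(sprintf("%s must be non-empty", what), call. = FALSE)
  }
  seq <- chartr("u", "t", seq)
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop(sprintf(
      "invalid IUPAC character '%s' at position %d in %s '%s'",
      chars[bad[1L]], bad[1L], what, seq
    ), call. = FALSE)
  }
  seq
}

#' Construct a primer set
#'
#' A primer set holds one or more forward and one or more reverse primer
#' sequences, possibly containing IUPAC degeneracy codes. Sequences are
#' uppercased and U is normalized to T on ingest.
#'
#' @param forward,reverse Character vectors of primer sequences (IUPAC codes
#'   allowed).
#' @param name Label for the primer set.
#' @return An object of class `primer_set` with elements `forward`,
#'   `reverse` and `name`.
#' @examples
#' primer_set("GTCGGTAAAACTCGTGCCAGC", "CATAGTGGGGTATCTAATCCCAGTTTG", "MiFish-U")
#' @export
primer_set <- function(forward, reverse, name = "primer_set") {
  if (length(forward) < 1L || length(reverse) < 1L) {
    stop("at least one forward and one reverse primer are required", call. = FALSE)
  }
  forward <- vapply(forward, normalize_iupac, character(1L),
                    what = "forward primer", USE.NAMES = FALSE)
  reverse <- vapply(reverse, normalize_iupac, character(1L),
                    what = "reverse primer", USE.NAMES = FALSE)
  structure(list(forward = forward, reverse = reverse, name = name),
            class = "primer_set")
}

#' Read a primer set from a FASTA file
#'
#' Records whose names contain `"R"`/`"rev"`-style suffixes are not guessed;
#' instead the first record(s) whose header matches `reverse_pattern` become
#' reverse primers and the rest forward primers.
#'
#' @param path FASTA file with at least two records.
#' @param reverse_pattern Regular expression applied to record headers to
#'   identify reverse primers (default `"(?i)rev|_R$"`).
#' @return A `primer_set`.
#' @export
read_primer_fasta <- function(path, reverse_pattern = "(?i)rev|_R$") {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) < 2L) {
    stop("primer FASTA must contain at least 2 records (forward and reverse)",
         call. = FALSE)
  }
  ids <- names(seqs)
  is_rev <- grepl(reverse_pattern, ids, perl = TRUE)
  if (!any(is_rev) || all(is_rev)) {
    stop("could not split primer FASTA into forward and reverse records; ",
         "mark reverse primers with 'rev' (or '_R') in their headers",
         call. = FALSE)
  }
  primer_set(as.character(seqs[!is_rev]), as.character(seqs[is_rev]),
             name = tools::file_path_sans_ext(basename(path)))
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("primer_set '%s': %d forward, %d reverse\n",
              x$name, length(x$forward), length(x$reverse)))
  cat("  forward:", paste(x$forward, collapse = ", "), "\n")
  cat("  reverse:", paste(x$reverse, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate all non-degenerate versions of a degenerate primer
#'
#' Expands every IUPAC ambiguity code into its base set and returns the full
#' Cartesian product, lexicographically sorted. A primer with no degenerate
#' positions returns itself.
#'
#' @param primer IUPAC nucleotide string.
#' @return Character vector of A/C/G/T-only strings; length equals the
#'   product of per-position degeneracies.
#' @examples
#' expand_degenerate("ACR") # "ACA" "ACG"
#' @export
expand_degenerate <- function(primer) {
  primer <- normalize_iupac(primer, "primer")
  chars <- strsplit(primer, "", fixed = TRUE)[[1L]]
  sets <- IUPAC_SETS[chars]
  n <- prod(lengths(sets))
  if (n == 1L) return(primer)
  grid <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  variants <- do.call(paste0, rev(grid))
  sort(unique(variants))
}

#' Number of non-degenerate variants a primer encodes
#' @param primer IUPAC nucleotide string.
#' @return Integer product of per-position degeneracies.
#' @export
degeneracy <- function(primer) {
  primer <- normalize_iupac(primer, "primer")
  chars <- strsplit(primer, "", fixed = TRUE)[[1L]]
  prod(lengths(IUPAC_SETS[chars]))
}

#' Enumerate (and optionally subsample) primer variants for a primer set
#'
#' Expands every primer of one role to its non-degenerate variants, then, if
#' the pooled variant count exceeds `n_max`, draws exactly `n_max` variants
#' uniformly without replacement using `seed`. Sampling is deterministic for
#' a fixed seed and leaves the caller's RNG state untouched.
#'
#' @param primers Character vector of IUPAC primers (one role: all forward or
#'   all reverse).
#' @param n_max Maximum number of variants to retain (default 25, bounding
#'   downstream search cost).
#' @param seed RNG seed for subsampling.
#' @param role Label stored alongside each variant (`"forward"`/`"reverse"`).
#' @return A data.frame with columns `variant`, `source` (the input primer
#'   the variant came from), `role`, plus attributes `sampled` (logical) and
#'   `sample_seed`.
#' @export
enumerate_primers <- function(primers, n_max = 25L, seed = 1L,
                              role = "forward") {
  stopifnot(n_max >= 1L)
  expanded <- lapply(primers, expand_degenerate)
  out <- data.frame(
    variant = unlist(expanded, use.names = FALSE),
    source = rep(primers, lengths(expanded)),
    role = role,
    stringsAsFactors = FALSE
  )
  # A variant reachable from two input primers is kept once (first source).
  out <- out[!duplicated(out$variant), , drop = FALSE]
  sampled <- FALSE
  if (nrow(out) > n_max) {
    idx <- withr::with_seed(seed, sample.int(nrow(out), n_max))
    out <- out[sort(idx), , drop = FALSE]
    sampled <- TRUE
  }
  rownames(out) <- NULL
  attr(out, "sampled") <- sampled
  attr(out, "sample_seed") <- seed
  out
}

#' Reverse-complement an IUPAC nucleotide string
#'
#' IUPAC-aware: R pairs with Y, S with S, W with W, K with M, B with V,
#' D with H, and N with N, so the operation is an involution on the full
#' ambiguity alphabet.
#'
#' @param seq IUPAC nucleotide string.
#' @return The reverse complement, same length and alphabet.
#' @examples
#' reverse_complement("AAR") # "YTT"
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_iupac(seq)
  comp <- chartr(paste(names(IUPAC_COMPLEMENT), collapse = ""),
                 paste(IUPAC_COMPLEMENT, collapse = ""), seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Precomputed 15x15 primer-vs-subject match table. Row = primer base,
# column = subject base. Entry is TRUE when the subject base's set
# intersects the primer base's set (so a subject N matches any primer base).
iupac_match_table <- local({
  letters15 <- names(IUPAC_SETS)
  m <- matrix(FALSE, 15L, 15L, dimnames = list(letters15, letters15))
  for (p in letters15) for (s in letters15) {
    m[p, s] <- length(intersect(IUPAC_SETS[[p]], IUPAC_SETS[[s]])) > 0L
  }
  m
})

#' Does a subject base satisfy a primer base?
#'
#' IUPAC-aware on the primer side: the subject base matches when its
#' degeneracy set intersects the primer base's set. Under the default
#' semantics an ambiguous subject base (e.g. N) matches any primer base;
#' set `subject_n_matches = FALSE` to treat subject ambiguity codes as
#' literal characters, in which case a subject N mismatches every
#' non-degenerate primer base.
#'
#' @param primer_base,subject_base Single IUPAC characters (vectorized).
#' @param subject_n_matches Logical flag described above.
#' @return Logical vector.
#' @export
iupac_match <- function(primer_base, subject_base, subject_n_matches = TRUE) {
  p <- toupper(primer_base)
  s <- toupper(subject_base)
  ok_p <- p %in% rownames(iupac_match_table)
  ok_s <- s %in% colnames(iupac_match_table)
  if (!all(ok_p) || !all(ok_s)) {
    bad <- c(p[!ok_p], s[!ok_s])[1L]
    stop(sprintf("invalid IUPAC character '%s'", bad), call. = FALSE)
  }
  if (subject_n_matches) {
    iupac_match_table[cbind(p, s)]
  } else {
    # Literal subject: match iff the subject character itself is in the
    # primer base's degeneracy set.
    mapply(function(pb, sb) sb %in% IUPAC_SETS[[pb]], p, s, USE.NAMES = FALSE)
  }
}

#' Count primer-vs-subject mismatches over an aligned window
#'
#' @param primer,subject Equal-length IUPAC strings.
#' @inheritParams iupac_match
#' @return Integer mismatch count.
#' @keywords internal
count_mismatches <- function(primer, subject, subject_n_matches = TRUE) {
  p <- strsplit(toupper(primer), "", fixed = TRUE)[[1L]]
  s <- strsplit(toupper(subject), "", fixed = TRUE)[[1L]]
  stopifnot(length(p) == length(s))
  sum(!iupac_match(p, s, subject_n_matches = subject_n_matches))
}
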