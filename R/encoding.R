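#' The seven-class reduced amino-acid alphabet
#'
#' The 20 standard amino acids grouped into seven classes by side-chain
#' volume and dipole moment: small/hydrophobic (1: A, G, V), large
#' hydrophobic (2: I, L, F, P), polar with small dipole (3: Y, M, T, S),
#' polar with intermediate dipole (4: H, N, Q, W), basic (5: R, K),
#' acidic (6: D, E), and cysteine alone (7: C).
#'
#' @return A tibble with columns `residue` (one-letter code), `class`
#'   (integer 1-7), and `group` (descriptive label).
#' @examples
#' reduced_alphabet()
#' @export
reduced_alphabet <- function() {
  tibble::tibble(
    residue = names(.aa_class_map),
    class = unname(.aa_class_map),
    group = dplyr::case_match(
      unname(.aa_class_map),
      1L ~ "small (vol < 50 A^3), dipole ~ 0",
      2L ~ "large hydrophobic, dipole ~ 0",
      3L ~ "polar, dipole < 1.0 D",
      4L ~ "polar, dipole 1.0-2.0 D",
      5L ~ "basic, dipole 2.0-3.0 D",
      6L ~ "acidic, dipole > 3.0 D",
      7L ~ "cysteine"
    )
  )
}

.aa_class_map <- c(
  A = 1L, G = 1L, V = 1L,
  I = 2L, L = 2L, F = 2L, P = 2L,
  Y = 3L, M = 3L, T = 3L, S = 3L,
  H = 4L, N = 4L, Q = 4L, W = 4L,
  R = 5L, K = 5L,
  D = 6L, E = 6L,
  C = 7L
)

#' Map amino-acid residues to reduced-alphabet classes
#'
#' @param aa Character vector of single-letter residue codes
#'   (case-insensitive).
#' @return Integer vector of class digits in 1..7.
#' @examples
#' reduce_residue(c("G", "R", "C"))
#' @export
reduce_residue <- function(aa) {
  aa <- toupper(as.character(aa))
  bad_len <- nchar(aa) != 1L
  if (any(bad_len)) {
    stop("reduce_residue() expects single-letter codes; got: ",
         paste(unique(aa[bad_len]), collapse = ", "), call. = FALSE)
  }
  cls <- .aa_class_map[aa]
  if (anyNA(cls)) {
    pos <- which(is.na(cls))
    stop(sprintf(
      "invalid residue(s) not in the 20-letter standard alphabet: %s",
      paste(sprintf("'%s' (position %d)", aa[pos], pos), collapse = ", ")
    ), call. = FALSE)
  }
  unname(cls)
}

#' Reduce amino-acid sequences to class-digit strings
#'
#' Applies [reduce_residue()] position-wise, so `"GLGF"` becomes `"1212"`.
#' Length is preserved; the empty string maps to the empty string.
#'
#' @param seq Character vector of amino-acid sequences.
#' @return Character vector of digit strings over 1..7.
#' @examples
#' reduce_sequence(c("GLGF", "AGV"))
#' @export
reduce_sequence <- function(seq) {
  seq <- toupper(as.character(seq))
  vapply(seq, function(s) {
    if (!nzchar(s)) return("")
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    cls <- .aa_class_map[chars]
    if (anyNA(cls)) {
      pos <- which(is.na(cls))[1L]
      stop(sprintf(
        "invalid residue '%s' at position %d of sequence '%s'",
        chars[pos], pos,
        if (nchar(s) > 20) paste0(substr(s, 1, 20), "...") else s
      ), call. = FALSE)
    }
    paste(cls, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate consecutive n-grams of a reduced sequence
#'
#' A string of length L yields the L - n + 1 consecutive windows, in order;
#' shorter strings yield an empty vector.
#'
#' @param digits A single reduced digit string.
#' @param n Gram length, 2 or 3.
#' @return Character vector of n-grams.
#' @examples
#' enumerate_ngrams("12345", 3)
#' @export
enumerate_ngrams <- function(digits, n) {
  stopifnot(length(digits) == 1L)
  n <- .check_n(n)
  L <- nchar(digits)
  if (L < n) return(character(0))
  starts <- seq_len(L - n + 1L)
  substring(digits, starts, starts + n - 1L)
}

.check_n <- function(n) {
  if (length(n) != 1L || !n %in% c(2, 3)) {
    stop("n must be 2 (bigram) or 3 (trigram)", call. = FALSE)
  }
  as.integer(n)
}

.check_gram <- function(gram) {
  if (!grepl("^[1-7]+$", gram)) {
    stop(sprintf("malformed gram '%s': digits must be in 1..7", gram),
         call. = FALSE)
  }
  invisible(gram)
}

#' Index of an n-gram in the lexicographic feature order
#'
#' Grams over class digits are ordered lexicographically; the gram
#' c1 c2 (c3) has 0-based index 7^(n-1) (c1 - 1) + ... + (c_n - 1). This
#' ordering is part of the on-disk feature contract, so saved models and
#' feature tables are portable.
#'
#' @param gram Digit string over 1..7 of length 2 or 3.
#' @return 0-based integer index in 0 .. 7^n - 1.
#' @examples
#' gram_index("111")  # 0
#' gram_index("777")  # 342
#' @export
gram_index <- function(gram) {
  vapply(as.character(gram), function(g) {
    .check_gram(g)
    d <- as.integer(strsplit(g, "", fixed = TRUE)[[1L]])
    as.integer(sum((d - 1L) * 7L^(rev(seq_along(d)) - 1L)))
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname gram_index
#' @param index 0-based integer index.
#' @param n Gram length, 2 or 3.
#' @return `gram_label()` returns the digit string, the inverse of
#'   `gram_index()`.
#' @export
gram_label <- function(index, n) {
  n <- .check_n(n)
  if (any(index < 0 | index >= 7^n)) {
    stop("index out of range 0 .. 7^n - 1", call. = FALSE)
  }
  vapply(as.integer(index), function(i) {
    d <- integer(n)
    for (k in seq_len(n)) {
      d[n - k + 1L] <- i %% 7L + 1L
      i <- i %/% 7L
    }
    paste(d, collapse = "")
  }, character(1))
}

#' All n-gram labels in feature order
#' @param n Gram length, 2 or 3.
#' @return Character vector of length 7^n ("111" ... "777" for n = 3).
#' @export
gram_labels <- function(n) {
  n <- .check_n(n)
  gram_label(0:(7^n - 1L), n)
}

#' N-gram frequency vector of a reduced sequence
#'
#' Counts each n-gram of the digit string and divides by the total number
#' of windows (L - n + 1), yielding a vector of length 7^n (49 for bigrams,
#' 343 for trigrams) that sums to 1.
#'
#' @param digits A single reduced digit string (see [reduce_sequence()]).
#' @param n Gram length, 2 or 3.
#' @return Named numeric vector of length `7^n`; names are gram labels in
#'   lexicographic order.
#' @examples
#' v <- ngram_frequency_vector(reduce_sequence("GLGF"), 3)
#' v[v > 0]
#' @export
ngram_frequency_vector <- function(digits, n) {
  n <- .check_n(n)
  grams <- enumerate_ngrams(digits, n)
  if (length(grams) == 0L) {
    stop(sprintf(
      "sequence too short for %d-grams: length %d < %d",
      n, nchar(digits), n
    ), call. = FALSE)
  }
  out <- numeric(7L^n)
  names(out) <- gram_labels(n)
  tab <- table(grams)
  out[names(tab)] <- as.numeric(tab) / length(grams)
  if (anyNA(out)) stop("malformed gram encountered", call. = FALSE)
  out
}

# Feature matrix for a set of sequences: one row per sequence, 7^n columns
# named <prefix>_<tg|bg>_<gram>. Internal workhorse for dataset builders.
.feature_matrix <- function(seqs, n, prefix) {
  reduced <- reduce_sequence(seqs)
  mat <- t(vapply(reduced, ngram_frequency_vector, numeric(7L^n), n = n,
                  USE.NAMES = FALSE))
  tag <- if (n == 3L) "tg" else "bg"
  colnames(mat) <- paste(prefix, tag, gram_labels(n), sep = "_")
  mat
}

#' Encode sequences as an n-gram feature table
#'
#' @param sequences Tibble with columns `id` and `seq`.
#' @param n Gram length, 2 or 3.
#' @param prefix Column-name prefix for the feature block (e.g. `"pdz"`,
#'   `"pep"`).
#' @return Tibble with `id` plus `7^n` frequency columns named
#'   `<prefix>_tg_<gram>` (trigram) or `<prefix>_bg_<gram>` (bigram).
#' @export
encode_sequences <- function(sequences, n = 3, prefix = "pdz") {
  .check_sequences(sequences)
  mat <- .feature_matrix(sequences$seq, .check_n(n), prefix)
  dplyr::bind_cols(
    tibble::tibble(id = sequences$id),
    tibble::as_tibble(mat)
  )
}

.check_sequences <- function(sequences, require_nonempty = TRUE) {
  if (!is.data.frame(sequences) ||
      !all(c("id", "seq") %in% names(sequences))) {
    stop("sequences must be a data frame with columns 'id' and 'seq'",
         call. = FALSE)
  }
  if (require_nonempty && any(!nzchar(sequences$seq))) {
    stop("empty sequence for id(s): ",
         paste(sequences$id[!nzchar(sequences$seq)], collapse = ", "),
         call. = FALSE)
  }
  invisible(sequences)
}
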