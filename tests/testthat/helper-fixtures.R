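# Shared fixtures and independent oracles for the test suite.

AA20 <- c("A", "G", "V", "I", "L", "F", "P", "Y", "M", "T", "S",
          "H", "N", "Q", "W", "R", "K", "D", "E", "C")

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# Naive dictionary-count oracle for n-gram frequencies, independent of the
# package's vectorized path.
oracle_ngram_freq <- function(digits, n) {
  L <- nchar(digits)
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(L - n + 1)) {
    g <- substr(digits, i, i + n - 1)
    counts[[g]] <- (if (is.null(counts[[g]])) 0 else counts[[g]]) + 1
  }
  out <- numeric(7^n)
  names(out) <- gram_labels(n)
  for (g in ls(counts)) out[g] <- counts[[g]] / (L - n + 1)
  out
}

# Pairwise-concordance oracle for AUC: P(score+ > score-) + 0.5 P(tie).
oracle_auc <- function(scores, is_pos) {
  sp <- scores[is_pos]
  sn <- scores[!is_pos]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}

# Small linearly separable encoded dataset: the label is determined by the
# frequency of one planted gram. Positives are runs of "AGV" (digits 111),
# negatives runs of "RKR"-style basic residues.
separable_gram_dataset <- function(n_per_class = 10, seed = 42) {
  withr::with_seed(seed, {
    pos <- replicate(n_per_class, paste(
      c(sample(c("A", "G", "V"), 12, TRUE), sample(AA20, 8, TRUE)),
      collapse = ""))
    neg <- replicate(n_per_class, paste(
      c(sample(c("R", "K"), 12, TRUE), sample(AA20, 8, TRUE)),
      collapse = ""))
  })
  seqs <- tibble::tibble(
    id = sprintf("s%02d", seq_len(2 * n_per_class)),
    seq = c(pos, neg)
  )
  feats <- encode_sequences(seqs, n = 3, prefix = "pdz")
  feats$label <- factor(rep(c("binding", "non-binding"),
                            each = n_per_class),
                        levels = c("binding", "non-binding"))
  feats
}

# Dataset whose label is a deterministic threshold on one gram frequency
# (planted rule, no noise).
planted_rule_dataset <- function(n = 200, seed = 7) {
  withr::with_seed(seed, {
    has_gram <- rep(c(TRUE, FALSE), length.out = n)
    seqs <- vapply(has_gram, function(h) {
      chars <- sample(AA20, 40, TRUE)
      if (h) {
        for (at in c(5, 20, 33)) chars[at:(at + 2)] <- c("R", "D", "C")
      } else {
        # scrub chance occurrences of the planted gram (classes 5,6,7)
        repeat {
          dig <- reduce_sequence(paste(chars, collapse = ""))
          hit <- regexpr("567", dig, fixed = TRUE)
          if (hit < 0) break
          chars[hit] <- "A"
        }
      }
      paste(chars, collapse = "")
    }, character(1))
  })
  feats <- encode_sequences(tibble::tibble(
    id = sprintf("r%03d", seq_len(n)), seq = seqs), n = 3, prefix = "pdz")
  feats$label <- factor(ifelse(has_gram, "binding", "non-binding"),
                        levels = c("binding", "non-binding"))
  feats
}

# Tiny sequence tables for io/labels tests.
toy_domains <- function() {
  tibble::tibble(
    id = c("d1", "d2"),
    seq = c("GLGFAGVRKDEC", "PLGIHNQWYMTS")
  )
}

toy_peptides <- function() {
  tibble::tibble(
    id = c("p1", "p2", "p3"),
    seq = c("AAKETWLVTSV",  # class I tail (T.V)
            "GGGGGGGYKV",   # class II tail (Y.V)
            "QQQQQQQEDV")   # class III tail (E.V)
  )
}

write_temp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Exhaustive CFS optimum over all non-empty subsets (<= 15 features).
exhaustive_cfs_best <- function(X, labels) {
  p <- ncol(X)
  stopifnot(p <= 15)
  best <- NULL
  best_merit <- -Inf
  for (mask in 1:(2^p - 1)) {
    subset <- which(bitwAnd(mask, 2^(0:(p - 1))) > 0)
    m <- cfs_merit(subset, X, labels)
    if (m > best_merit + 1e-12) {
      best_merit <- m
      best <- subset
    }
  }
  list(subset = best, merit = best_merit)
}
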