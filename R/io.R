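#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return Tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq`. Order follows the file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(id = ids, seq = unname(as.character(set)))
}

#' Write sequences to a FASTA file
#' @param sequences Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  .check_sequences(sequences, require_nonempty = FALSE)
  set <- Biostrings::AAStringSet(sequences$seq)
  names(set) <- sequences$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a multiple alignment from aligned FASTA
#'
#' Rows must all have the same width; gap characters (`-`) are preserved.
#'
#' @param path Path to an aligned FASTA file.
#' @return Tibble with columns `id` and `seq`, all `seq` of equal width.
#' @export
read_alignment <- function(path) {
  aln <- read_fasta(path)
  widths <- nchar(aln$seq)
  if (length(unique(widths)) != 1L) {
    off <- aln$id[widths != stats::median(widths)]
    stop("ragged alignment: row(s) with deviant width: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  aln
}

.read_table <- function(path, delim) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
}

#' Read a domain-peptide interaction table
#'
#' The canonical dialect is TSV with header columns `pdz_id`, `peptide_id`,
#' `label`. Labels are normalized case-insensitively to `binding` /
#' `non-binding`; `1` / `0` are accepted as synonyms.
#'
#' @param path Path to the table.
#' @param delim Field delimiter (default tab; use `","` for CSV).
#' @return Tibble with columns `pdz_id`, `peptide_id`, `label` (factor with
#'   levels binding, non-binding).
#' @export
read_interactions <- function(path, delim = "\t") {
  tab <- .read_table(path, delim)
  need <- c("pdz_id", "peptide_id", "label")
  if (!all(need %in% names(tab))) {
    stop("interaction table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lab <- .normalize_binding_labels(tab$label)
  key <- paste(tab$pdz_id, tab$peptide_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("duplicate (pdz_id, peptide_id) pair at line %d: (%s, %s)",
                 d + 1L, tab$pdz_id[d], tab$peptide_id[d]), call. = FALSE)
  }
  tibble::tibble(pdz_id = tab$pdz_id, peptide_id = tab$peptide_id,
                 label = lab)
}

.normalize_binding_labels <- function(x) {
  lc <- tolower(trimws(as.character(x)))
  out <- dplyr::case_match(
    lc,
    c("binding", "1", "bind", "positive") ~ "binding",
    c("non-binding", "nonbinding", "non_binding", "0", "negative") ~
      "non-binding",
    .default = NA_character_
  )
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("unknown interaction label '%s' at line %d", x[bad],
                 bad + 1L), call. = FALSE)
  }
  factor(out, levels = c("binding", "non-binding"))
}

#' Read a PDZ domain class table
#'
#' TSV with header columns `pdz_id`, `class`; classes are `I`, `II`, `I-II`.
#'
#' @inheritParams read_interactions
#' @return Tibble with columns `pdz_id`, `class` (factor I, II, I-II).
#' @export
read_classes <- function(path, delim = "\t") {
  tab <- .read_table(path, delim)
  if (!all(c("pdz_id", "class") %in% names(tab))) {
    stop("class table must have columns: pdz_id, class", call. = FALSE)
  }
  cls <- toupper(trimws(tab$class))
  ok <- cls %in% c("I", "II", "I-II")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("unknown class label '%s' at line %d (expected I, II, I-II)",
                 tab$class[bad], bad + 1L), call. = FALSE)
  }
  if (anyDuplicated(tab$pdz_id)) {
    stop("duplicate pdz_id in class table: ",
         paste(unique(tab$pdz_id[duplicated(tab$pdz_id)]), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(pdz_id = tab$pdz_id,
                 class = factor(cls, levels = c("I", "II", "I-II")))
}

#' Summarize an interaction dataset
#'
#' @param interactions Tibble from [read_interactions()].
#' @param domains,peptides Sequence tibbles (`id`, `seq`); every id referenced
#'   by `interactions` must resolve.
#' @return One-row tibble: `n_binding`, `n_nonbinding`, `n_domains`,
#'   `n_peptides` (distinct ids appearing in the table).
#' @export
dataset_summary <- function(interactions, domains, peptides) {
  missing_d <- setdiff(interactions$pdz_id, domains$id)
  missing_p <- setdiff(interactions$peptide_id, peptides$id)
  if (length(missing_d) + length(missing_p) > 0L) {
    stop("unresolved id(s): ",
         paste(c(missing_d, missing_p), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    n_binding = sum(interactions$label == "binding"),
    n_nonbinding = sum(interactions$label == "non-binding"),
    n_domains = dplyr::n_distinct(interactions$pdz_id),
    n_peptides = dplyr::n_distinct(interactions$peptide_id)
  )
}

#' Write an evaluation report as JSON
#'
#' Serializes the confusion counts, summary metrics and ROC/PR point lists of
#' a cross-validation or evaluation result to a single structured JSON
#' document suitable for external plotting.
#'
#' @param report A `pdz_cv` or `pdz_eval` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass_report(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# Plain-list view of a report object for serialization.
unclass_report <- function(report) {
  lapply(report, function(x) {
    if (inherits(x, "pdz_roc")) {
      list(points = as.data.frame(x$points), auc = x$auc)
    } else if (is.data.frame(x)) {
      as.data.frame(x)
    } else if (inherits(x, "forest_params")) {
      unclass(x)
    } else x
  })
}
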