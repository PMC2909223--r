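#' Peptide class rule configuration
#'
#' PDZ ligand classes are defined by the last (position 0) and
#' third-from-last (position -2) residues of the peptide: Class I is
#' S/T at -2 with a hydrophobic C-terminus, Class II hydrophobic at both,
#' Class III D/E at -2 with a hydrophobic C-terminus. The hydrophobic set
#' (Phi) is configurable; it must stay disjoint from {S, T, D, E} so the
#' three rules remain mutually exclusive.
#'
#' @param phi Character vector of hydrophobic one-letter codes.
#' @param truncation_length Number of C-terminal residues retained by
#'   [truncate_peptide()] (default 10, matching the up-to-position
#'   -10 specificity of PDZ ligand recognition).
#' @return A `class_rule_config` list.
#' @export
class_rule_config <- function(phi = c("A", "C", "F", "I", "L", "M", "V",
                                      "W", "Y"),
                              truncation_length = 10) {
  phi <- toupper(phi)
  if (length(phi) == 0L) stop("phi must be non-empty", call. = FALSE)
  clash <- intersect(phi, c("S", "T", "D", "E"))
  if (length(clash) > 0L) {
    stop("phi may not contain S/T/D/E (keeps class rules disjoint): ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  if (truncation_length < 1) stop("truncation_length must be >= 1",
                                  call. = FALSE)
  structure(list(phi = phi,
                 truncation_length = as.integer(truncation_length)),
            class = "class_rule_config")
}

#' Keep the C-terminal residues of peptides
#'
#' Returns the last `truncation_length` residues of each peptide (the whole
#' peptide if shorter). PDZ recognition involves positions down to about
#' -10, so longer constructs are truncated before encoding.
#'
#' @param seq Character vector of peptide sequences.
#' @param cfg A [class_rule_config()].
#' @return Character vector of truncated sequences.
#' @examples
#' truncate_peptide("AAKETWLVTSDV")
#' @export
truncate_peptide <- function(seq, cfg = class_rule_config()) {
  seq <- as.character(seq)
  if (any(!nzchar(seq))) stop("empty peptide sequence", call. = FALSE)
  L <- nchar(seq)
  keep <- pmin(L, cfg$truncation_length)
  substring(seq, L - keep + 1L, L)
}

#' Classify peptides by their C-terminal motif
#'
#' Applies the class rules to positions 0 (C-terminus) and -2: Class I if
#' position -2 is S/T and position 0 is hydrophobic; Class II if both are
#' hydrophobic; Class III if position -2 is D/E and position 0 hydrophobic;
#' otherwise `unclassified`. The rules depend only on the last three
#' residues.
#'
#' @param seq Character vector of peptide sequences (length >= 3 each).
#' @param cfg A [class_rule_config()].
#' @return Factor with levels I, II, III, unclassified.
#' @examples
#' peptide_class(c("KETWLVETSV", "GGYKV", "QEDV"))
#' @export
peptide_class <- function(seq, cfg = class_rule_config()) {
  seq <- toupper(as.character(seq))
  if (any(nchar(seq) < 3L)) {
    stop("peptide_class needs sequences of length >= 3", call. = FALSE)
  }
  L <- nchar(seq)
  p0 <- substring(seq, L, L)
  pm2 <- substring(seq, L - 2L, L - 2L)
  hydro0 <- p0 %in% cfg$phi
  out <- dplyr::case_when(
    pm2 %in% c("S", "T") & hydro0 ~ "I",
    pm2 %in% cfg$phi & hydro0 ~ "II",
    pm2 %in% c("D", "E") & hydro0 ~ "III",
    .default = "unclassified"
  )
  factor(out, levels = c("I", "II", "III", "unclassified"))
}

#' Assign PDZ domain classes from observed binding partners
#'
#' A domain binding at least one Class I and one Class II peptide is
#' promiscuous Class I-II; a domain binding only Class I (respectively only
#' Class II) peptides is Class I (II); domains binding nothing, or only
#' Class III / unclassified peptides, are `unassigned` and excluded from the
#' class-prediction task. Only records labelled `binding` count as evidence.
#'
#' @param interactions Interaction tibble (`pdz_id`, `peptide_id`, `label`).
#' @param peptides Peptide sequence tibble (`id`, `seq`).
#' @param cfg A [class_rule_config()].
#' @param extra_classes Optional class tibble (`pdz_id`, `class`) merged in
#'   for domains with external class evidence; external assignments win for
#'   domains present in both.
#' @return Tibble with one row per domain seen in `interactions`: `pdz_id`,
#'   `class` (factor I, II, I-II, unassigned), `n_class1_partners`,
#'   `n_class2_partners`.
#' @export
assign_domain_classes <- function(interactions, peptides,
                                  cfg = class_rule_config(),
                                  extra_classes = NULL) {
  missing_p <- setdiff(interactions$peptide_id, peptides$id)
  if (length(missing_p) > 0L) {
    stop("unresolved peptide id(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  pep_cls <- tibble::tibble(
    peptide_id = peptides$id,
    pep_class = peptide_class(truncate_peptide(peptides$seq, cfg), cfg)
  )
  out <- interactions |>
    dplyr::left_join(pep_cls, by = "peptide_id") |>
    dplyr::group_by(.data$pdz_id) |>
    dplyr::summarise(
      n_class1_partners = sum(.data$label == "binding" &
                                .data$pep_class == "I"),
      n_class2_partners = sum(.data$label == "binding" &
                                .data$pep_class == "II"),
      .groups = "drop"
    ) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$n_class1_partners > 0 & .data$n_class2_partners > 0 ~ "I-II",
      .data$n_class1_partners > 0 ~ "I",
      .data$n_class2_partners > 0 ~ "II",
      .default = "unassigned"
    ))
  if (!is.null(extra_classes)) {
    ext <- tibble::tibble(pdz_id = extra_classes$pdz_id,
                          ext_class = as.character(extra_classes$class))
    out <- out |>
      dplyr::left_join(ext, by = "pdz_id") |>
      dplyr::mutate(class = dplyr::coalesce(.data$ext_class, .data$class)) |>
      dplyr::select(-"ext_class")
  }
  out |>
    dplyr::mutate(class = factor(.data$class,
                                 levels = c("I", "II", "I-II",
                                            "unassigned"))) |>
    dplyr::select("pdz_id", "class", "n_class1_partners",
                  "n_class2_partners")
}

#' Build the interaction-prediction feature table
#'
#' Each interaction becomes one row: the domain's n-gram frequency block
#' (columns `pdz_tg_*` / `pdz_bg_*`) concatenated with the truncated
#' peptide's block (`pep_tg_*` / `pep_bg_*`), 686 features for trigrams and
#' 98 for bigrams, plus the binding label. Each block sums to 1 on its own.
#'
#' @param interactions Interaction tibble (`pdz_id`, `peptide_id`, `label`).
#' @param domains,peptides Sequence tibbles (`id`, `seq`).
#' @param n Gram length, 2 or 3 (default 3).
#' @param cfg A [class_rule_config()] (controls peptide truncation).
#' @return Tibble: `pdz_id`, `peptide_id`, `label`, then `2 * 7^n` feature
#'   columns.
#' @export
build_interaction_dataset <- function(interactions, domains, peptides,
                                      n = 3, cfg = class_rule_config()) {
  n <- .check_n(n)
  missing_d <- setdiff(interactions$pdz_id, domains$id)
  missing_p <- setdiff(interactions$peptide_id, peptides$id)
  if (length(missing_d) + length(missing_p) > 0L) {
    stop("unresolved id(s): ", paste(c(missing_d, missing_p),
                                     collapse = ", "), call. = FALSE)
  }
  dom_used <- domains[domains$id %in% interactions$pdz_id, ]
  pep_used <- peptides[peptides$id %in% interactions$peptide_id, ]
  pep_used$seq <- truncate_peptide(pep_used$seq, cfg)
  dom_feat <- encode_sequences(dom_used, n, "pdz")
  pep_feat <- encode_sequences(pep_used, n, "pep")
  interactions |>
    dplyr::mutate(label = .normalize_binding_labels_safe(.data$label)) |>
    dplyr::left_join(dom_feat, by = c(pdz_id = "id")) |>
    dplyr::left_join(pep_feat, by = c(peptide_id = "id"))
}

# labels may arrive already normalized (factor) or as raw strings/0-1
.normalize_binding_labels_safe <- function(x) {
  if (is.factor(x) && identical(levels(x), c("binding", "non-binding"))) {
    return(x)
  }
  factor(dplyr::case_match(tolower(as.character(x)),
                           c("binding", "1") ~ "binding",
                           c("non-binding", "nonbinding", "0") ~
                             "non-binding"),
         levels = c("binding", "non-binding"))
}

#' Build the class-prediction feature table
#'
#' Domain-only n-gram frequency blocks (343 trigram or 49 bigram features)
#' with the three-valued class label; peptides play no role here because
#' the peptide classes define the label itself.
#'
#' @param class_records Class tibble (`pdz_id`, `class` in I / II / I-II).
#' @param domains Sequence tibble (`id`, `seq`).
#' @param n Gram length, 2 or 3 (default 3).
#' @return Tibble: `pdz_id`, `class`, then `7^n` feature columns.
#' @export
build_class_dataset <- function(class_records, domains, n = 3) {
  n <- .check_n(n)
  missing_d <- setdiff(class_records$pdz_id, domains$id)
  if (length(missing_d) > 0L) {
    stop("unresolved domain id(s): ", paste(missing_d, collapse = ", "),
         call. = FALSE)
  }
  cls <- as.character(class_records$class)
  ok <- cls %in% c("I", "II", "I-II")
  if (!all(ok)) {
    stop("unknown class label(s): ",
         paste(unique(cls[!ok]), collapse = ", "), call. = FALSE)
  }
  dom_used <- domains[domains$id %in% class_records$pdz_id, ]
  dom_feat <- encode_sequences(dom_used, n, "pdz")
  tibble::tibble(
    pdz_id = class_records$pdz_id,
    class = factor(cls, levels = c("I", "II", "I-II"))
  ) |>
    dplyr::left_join(dom_feat, by = c(pdz_id = "id"))
}
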