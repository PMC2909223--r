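#' Find conserved occurrences of a reduced-alphabet motif in an alignment
#'
#' Slides the motif over the alignment columns. At each start column a row
#' contributes only if its window is gap-free; the window matches when its
#' residues reduce to the motif's digits. Occupancy is matches over
#' gap-free rows (rows with a gap in the window are excluded from both
#' numerator and denominator). Columns with occupancy at or above
#' `min_occupancy` are reported.
#'
#' @param alignment Tibble from [read_alignment()] (`id`, `seq`, equal
#'   widths, gaps `-`).
#' @param motif Digit string over 1..7 (length 2 or 3 in practice).
#' @param min_occupancy Minimum fraction of gap-free rows matching
#'   (default 0.7, the package's operationalization of "most conserved").
#' @return Tibble of hits sorted by column: `motif`, `column` (0-based
#'   start), `occupancy`, `n_rows` (gap-free rows at that window).
#' @export
motif_occurrences <- function(alignment, motif, min_occupancy = 0.7) {
  if (nrow(alignment) == 0L) stop("alignment is empty", call. = FALSE)
  .check_gram(motif)
  width <- nchar(alignment$seq[1L])
  len <- nchar(motif)
  if (len > width) {
    stop(sprintf("motif length %d exceeds alignment width %d", len, width),
         call. = FALSE)
  }
  # per-row reduced digits with gaps marked as NA
  rows <- lapply(alignment$seq, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    dig <- rep(NA_integer_, length(chars))
    ok <- chars != "-"
    dig[ok] <- reduce_residue(chars[ok])
    dig
  })
  digit_mat <- do.call(rbind, rows)
  target <- as.integer(strsplit(motif, "", fixed = TRUE)[[1L]])
  hits <- purrr::map(0:(width - len), function(col) {
    win <- digit_mat[, (col + 1L):(col + len), drop = FALSE]
    gap_free <- !apply(is.na(win), 1L, any)
    n <- sum(gap_free)
    if (n == 0L) return(NULL)
    matches <- colSums(t(win[gap_free, , drop = FALSE]) == target) == len
    occ <- sum(matches) / n
    if (occ >= min_occupancy) {
      tibble::tibble(motif = motif, column = col, occupancy = occ,
                     n_rows = n)
    }
  })
  out <- purrr::list_rbind(purrr::compact(hits))
  if (nrow(out) == 0L) {
    return(tibble::tibble(motif = character(0), column = integer(0),
                          occupancy = numeric(0), n_rows = integer(0)))
  }
  out
}

#' Label motif hits with secondary-structure regions
#'
#' Regions are user-supplied half-open column intervals `[start, end)`,
#' typically the beta strands (betaA-betaF), alpha helices (alphaA,
#' alphaB) and connecting loops of the PDZ fold; assignment is by the
#' hit's start column. Overlapping regions are rejected.
#'
#' @param hits Tibble from [motif_occurrences()].
#' @param regions Tibble with columns `label`, `start`, `end` (0-based,
#'   half-open).
#' @return `hits` with an added `region` column (`"unassigned"` outside
#'   all intervals).
#' @export
annotate_regions <- function(hits, regions) {
  need <- c("label", "start", "end")
  if (!all(need %in% names(regions))) {
    stop("regions must have columns: label, start, end", call. = FALSE)
  }
  reg <- dplyr::arrange(regions, .data$start)
  if (nrow(reg) > 1L && any(utils::head(reg$end, -1) >
                              utils::tail(reg$start, -1))) {
    stop("overlapping region intervals", call. = FALSE)
  }
  hits$region <- vapply(hits$column, function(col) {
    in_reg <- reg$label[reg$start <= col & col < reg$end]
    if (length(in_reg) == 0L) "unassigned" else in_reg[1L]
  }, character(1))
  hits
}

#' Rank conserved motifs from selected features on an alignment
#'
#' Pipeline step tying feature selection to sequence interpretation:
#' selected bigrams are intersected with selected trigrams via
#' [consensus_features()] (bigrams contained in trigrams survive), every
#' consensus gram (bigram and host trigram) is mapped onto the alignment
#' with [motif_occurrences()], hits are region-annotated when a region
#' table is given, and motifs are ranked by their maximum column
#' occupancy. On real PDZ alignments this surfaces motifs such as "12"
#' (small hydrophobic followed by large hydrophobic, the GLGF
#' carboxylate-binding loop signature).
#'
#' @param selected Tibble from [select_features()], or any tibble with a
#'   `gram` column of digit strings.
#' @param alignment Tibble from [read_alignment()].
#' @param regions Optional region tibble for [annotate_regions()].
#' @param min_occupancy Passed to [motif_occurrences()].
#' @return Tibble ranked by `max_occupancy`: `motif`, `kind`
#'   (`consensus-bigram` / `host-trigram`), `hosts`, `n_hits`,
#'   `best_column`, `max_occupancy`, `region` (of the best column).
#' @export
motif_report <- function(selected, alignment, regions = NULL,
                         min_occupancy = 0.7) {
  grams <- unique(selected$gram)
  tri <- grams[nchar(grams) == 3L]
  bi <- grams[nchar(grams) == 2L]
  cons <- consensus_features(tri, bi)
  if (nrow(cons) == 0L) {
    return(tibble::tibble(motif = character(0), kind = character(0),
                          hosts = character(0), n_hits = integer(0),
                          best_column = integer(0),
                          max_occupancy = numeric(0),
                          region = character(0)))
  }
  host_tri <- unique(unlist(strsplit(cons$hosts, ",", fixed = TRUE)))
  queries <- dplyr::bind_rows(
    tibble::tibble(motif = cons$bigram, kind = "consensus-bigram",
                   hosts = cons$hosts),
    tibble::tibble(motif = host_tri, kind = "host-trigram",
                   hosts = host_tri)
  )
  rows <- purrr::pmap(queries, function(motif, kind, hosts) {
    hits <- motif_occurrences(alignment, motif, min_occupancy)
    if (nrow(hits) == 0L) return(NULL)
    if (!is.null(regions)) hits <- annotate_regions(hits, regions)
    best <- hits[which.max(hits$occupancy), ]
    tibble::tibble(
      motif = motif, kind = kind, hosts = hosts, n_hits = nrow(hits),
      best_column = best$column, max_occupancy = best$occupancy,
      region = if (!is.null(regions)) best$region else NA_character_
    )
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (nrow(out) == 0L) {
    return(tibble::tibble(motif = character(0), kind = character(0),
                          hosts = character(0), n_hits = integer(0),
                          best_column = integer(0),
                          max_occupancy = numeric(0),
                          region = character(0)))
  }
  dplyr::arrange(out, dplyr::desc(.data$max_occupancy), .data$motif)
}
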