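#' Alignment matrix container
#'
#' A light wrapper around a set of equal-length aligned amino-acid strings.
#' Gap (`-`, `.`) and ambiguity (`X`) characters are treated as missing
#' throughout the completeness machinery, mirroring how alignment
#' completeness tools score ambiguous residues.
#'
#' @param ids unique sequence identifiers.
#' @param rows aligned residue strings, all the same length.
#' @return object of class `alignment_matrix` with elements `ids`, `rows`,
#'   `n_sites`.
#' @export
alignment_matrix <- function(ids, rows) {
  ids <- as.character(ids); rows <- toupper(as.character(rows))
  if (length(ids) != length(rows))
    stop_input("alignment_matrix(): ids and rows differ in length")
  if (anyDuplicated(ids)) stop_input("alignment_matrix(): ids must be unique")
  n <- unique(nchar(rows))
  if (length(n) != 1L) stop_input("alignment_matrix(): ragged rows")
  structure(list(ids = ids, rows = rows, n_sites = n),
            class = "alignment_matrix")
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat("<alignment_matrix>", length(x$ids), "sequences x", x$n_sites, "sites\n")
  invisible(x)
}

#' Read / write an aligned FASTA file as an alignment matrix
#' @param path FASTA file path.
#' @return an [alignment_matrix()].
#' @export
read_alignment <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  alignment_matrix(names(s), as.character(s))
}

#' @rdname read_alignment
#' @param msa an `alignment_matrix`.
#' @export
write_alignment <- function(msa, path) {
  s <- Biostrings::AAStringSet(msa$rows)
  names(s) <- msa$ids
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

missing_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$rows, ""))
  m == "-" | m == "." | m == "X"
}

#' Alignment completeness scores
#'
#' Computes the completeness report for an alignment: `Cr[i]` is the
#' fraction of non-missing sites in row i, `Cc[j]` the fraction of
#' non-missing entries in column j, `Ca` the overall fraction of non-missing
#' cells (equal to both `mean(Cr)` and `mean(Cc)`), and `Cij` the pairwise
#' matrix of shared non-missing sites divided by the total number of sites.
#'
#' @param msa an [alignment_matrix()].
#' @return object of class `completeness_report`: list with `Ca`, `Cr`,
#'   `Cc`, `Cij` (named symmetric matrix, diagonal = `Cr`).
#' @export
completeness <- function(msa) {
  if (!inherits(msa, "alignment_matrix")) stop_input("completeness(): need an alignment_matrix")
  if (!length(msa$ids)) stop_input("completeness(): empty alignment")
  present <- !missing_matrix(msa)
  mode(present) <- "numeric"
  Cr <- rowMeans(present)
  Cc <- colMeans(present)
  Cij <- tcrossprod(present) / msa$n_sites
  dimnames(Cij) <- list(msa$ids, msa$ids)
  names(Cr) <- msa$ids
  structure(list(Ca = mean(present), Cr = Cr, Cc = Cc, Cij = Cij),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat("<completeness_report> Ca =", round(x$Ca, 4),
      "|", length(x$Cr), "sequences x", length(x$Cc), "sites\n")
  invisible(x)
}

#' Remove sequences with insufficient pairwise overlap
#'
#' A sequence is removed iff its best pairwise completeness against any
#' other sequence is strictly below the cutoff (`max_j Cij < 0.5` by
#' default), i.e. it does not align adequately with anything else.
#'
#' @param msa an [alignment_matrix()].
#' @param report its [completeness()] report (recomputed when `NULL`).
#' @param cij_cutoff strict lower bound on the best pairwise score.
#' @return list with `msa` (reduced alignment) and `removed` (ids).
#' @export
filter_sequences <- function(msa, report = NULL, cij_cutoff = 0.5) {
  report <- report %||% completeness(msa)
  C <- report$Cij
  diag(C) <- NA
  best <- apply(C, 1, function(r) if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
  removed <- msa$ids[best < cij_cutoff]
  keep <- !(msa$ids %in% removed)
  list(msa = alignment_matrix(msa$ids[keep], msa$rows[keep]), removed = removed)
}

#' Mask incomplete alignment columns
#'
#' Columns whose completeness `Cc` is strictly below the cutoff (0.6 by
#' default) are removed; column order is otherwise preserved.
#'
#' @inheritParams filter_sequences
#' @param cc_cutoff strict lower bound on column completeness.
#' @return the masked [alignment_matrix()].
#' @export
mask_columns <- function(msa, report = NULL, cc_cutoff = 0.6) {
  report <- report %||% completeness(msa)
  keep <- report$Cc >= cc_cutoff
  rows <- vapply(strsplit(msa$rows, ""),
                 function(ch) paste(ch[keep], collapse = ""), character(1))
  alignment_matrix(msa$ids, rows)
}

#' Collapse identical aligned sequences
#'
#' Exact string duplicates are collapsed to a single representative (the
#' lexicographically smallest id, for determinism); the surplus map records
#' which ids each representative stands for so they can be re-attached
#' after tree inference.
#'
#' @param msa an [alignment_matrix()].
#' @return list with `msa` (unique rows) and `surplus` (named list:
#'   representative id -> character vector of removed identical ids).
#' @export
dedup <- function(msa) {
  groups <- split(msa$ids, msa$rows)
  reps <- vapply(groups, function(g) sort(g)[1], character(1))
  surplus <- lapply(groups, function(g) setdiff(sort(g), sort(g)[1]))
  names(surplus) <- reps
  surplus <- surplus[vapply(surplus, length, integer(1)) > 0]
  keep <- msa$ids %in% reps
  list(msa = alignment_matrix(msa$ids[keep], msa$rows[keep]),
       surplus = surplus)
}

#' Re-attach surplus duplicate ids to a per-id table
#'
#' Expands a table keyed by representative ids so that every surplus id
#' receives its representative's rows (with its own id substituted),
#' restoring the pre-deduplication id universe.
#'
#' @param tab data.frame whose first column holds representative ids.
#' @param surplus the surplus map from [dedup()].
#' @return data.frame covering representatives and surplus ids.
#' @export
reattach_surplus <- function(tab, surplus) {
  extra <- list()
  idcol <- names(tab)[1]
  for (rep_id in names(surplus)) {
    base <- tab[tab[[idcol]] == rep_id, , drop = FALSE]
    if (!nrow(base)) next
    for (dup in surplus[[rep_id]]) {
      r <- base
      r[[idcol]] <- dup
      extra[[length(extra) + 1L]] <- r
    }
  }
  out <- rbind(tab, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Per-sequence completeness report as a table
#'
#' @param msa an [alignment_matrix()].
#' @param cij_cutoff cutoff used for the removal flag.
#' @return data.frame with `id`, `Cr`, `max_Cij`, `removed`.
#' @export
completeness_table <- function(msa, cij_cutoff = 0.5) {
  rep <- completeness(msa)
  C <- rep$Cij; diag(C) <- NA
  best <- apply(C, 1, function(r) if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
  data.frame(id = msa$ids, Cr = unname(rep$Cr), max_Cij = unname(best),
             removed = unname(best) < cij_cutoff, stringsAsFactors = FALSE)
}
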