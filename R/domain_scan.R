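#' Position-specific log-odds profile for the NAM domain
#'
#' Builds an ungapped log-odds profile from an alignment of NAM-domain
#' sequences. Columns with 50% or more gap characters are dropped; each kept
#' cell scores `log2(((count + pc) / (n + 20 * pc)) / background)` where the
#' background is the residue frequency of the training alignment itself
#' (pseudocounted the same way). The profile is a desk-scale stand-in for a
#' profile HMM: it supports ungapped window scoring only.
#'
#' @param aligned_seqs character vector of aligned amino-acid sequences
#'   (gap characters `-` or `.`), all the same length, length >= 2.
#' @param pseudocount additive pseudocount per residue (default 1).
#' @return an object of class `nam_profile`: list with `scores` (20 x width
#'   matrix, rows named by residue), `width`, `background`, `consensus`,
#'   `kept_columns` (indices into the input alignment).
#' @export
build_profile <- function(aligned_seqs, pseudocount = 1) {
  if (length(aligned_seqs) < 2L)
    stop_input("build_profile() needs at least 2 aligned sequences")
  n <- nchar(aligned_seqs)
  if (length(unique(n)) != 1L)
    stop_input("aligned sequences must all have the same length")
  aa <- aa_alphabet()
  m <- do.call(rbind, strsplit(toupper(aligned_seqs), ""))
  is_gap <- m == "-" | m == "."
  keep <- colMeans(is_gap) < 0.5
  if (!any(keep)) stop_input("no alignment column has fewer than 50% gaps")
  m <- m[, keep, drop = FALSE]
  is_gap <- is_gap[, keep, drop = FALSE]
  res <- m[!is_gap]
  res <- res[res %in% aa]
  bg <- (table(factor(res, levels = aa)) + pseudocount) /
    (length(res) + 20 * pseudocount)
  bg <- as.numeric(bg)
  names(bg) <- aa
  scores <- matrix(0, nrow = 20, ncol = ncol(m), dimnames = list(aa, NULL))
  for (j in seq_len(ncol(m))) {
    col <- m[!is_gap[, j], j]
    col <- col[col %in% aa]
    cnt <- table(factor(col, levels = aa))
    p <- (as.numeric(cnt) + pseudocount) / (length(col) + 20 * pseudocount)
    scores[, j] <- unname(log2(p / bg))
  }
  consensus <- paste(aa[apply(scores, 2, which.max)], collapse = "")
  structure(list(scores = scores, width = ncol(scores), background = bg,
                 consensus = consensus, kept_columns = which(keep)),
            class = "nam_profile")
}

#' @export
print.nam_profile <- function(x, ...) {
  cat("<nam_profile> width", x$width, "\nconsensus:", x$consensus, "\n")
  invisible(x)
}

# Sum of per-position scores for every window start; residues outside the
# 20-letter alphabet (e.g. X) contribute 0.
window_scores <- function(profile, sequence) {
  aa <- rownames(profile$scores)
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, aa)
  L <- length(chars); W <- profile$width
  if (L < W) return(numeric(0))
  n_win <- L - W + 1L
  out <- numeric(n_win)
  sc <- profile$scores
  for (k in seq_len(W)) {
    ii <- idx[k:(k + n_win - 1L)]
    v <- sc[ii + (k - 1L) * 20L]
    v[is.na(v)] <- 0
    out <- out + v
  }
  out
}

#' Scan a protein for NAM-like regions with a log-odds profile
#'
#' Scores every window of the profile's width and returns maximal
#' non-overlapping windows with score at or above the threshold, highest
#' score first when resolving overlaps, reported sorted by position.
#' A crude E-value is attached (`E = n_windows * 2^-score`, a
#' Karlin-Altschul-style conversion) so downstream E-value filtering can be
#' exercised on internal scans.
#'
#' @param profile a `nam_profile` from [build_profile()].
#' @param protein either a single amino-acid string or a list/record with
#'   elements `id` and `sequence`.
#' @param score_threshold minimum window bit score to report (default 30).
#' @param id protein identifier when `protein` is a bare string.
#' @return data.frame of domain hits with columns `protein_id`,
#'   `profile_name`, `full_seq_evalue`, `bit_score`, `domain_index`,
#'   `domain_cond_evalue`, `env_start`, `env_end` (1-based inclusive).
#' @export
scan_sequence <- function(profile, protein, score_threshold = 30,
                          id = "protein") {
  if (is.list(protein)) {
    id <- protein$id %||% id
    sequence <- protein$sequence
  } else sequence <- protein
  stopifnot(is.character(sequence), length(sequence) == 1L)
  ws <- window_scores(profile, sequence)
  hits <- empty_hits()
  if (!length(ws)) return(hits)
  cand <- which(ws >= score_threshold)
  if (!length(cand)) return(hits)
  cand <- cand[order(ws[cand], decreasing = TRUE)]
  W <- profile$width
  taken <- rep(FALSE, nchar(sequence))
  starts <- integer(0)
  for (s in cand) {
    span <- s:(s + W - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      starts <- c(starts, s)
    }
  }
  starts <- sort(starts)
  n_win <- length(ws)
  ev <- pmin(n_win * 2^(-ws[starts]), 1e6)
  data.frame(protein_id = id, profile_name = "NAM",
             full_seq_evalue = ev, bit_score = ws[starts],
             domain_index = seq_along(starts), domain_cond_evalue = ev,
             env_start = starts, env_end = starts + W - 1L,
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(protein_id = character(0), profile_name = character(0),
             full_seq_evalue = numeric(0), bit_score = numeric(0),
             domain_index = integer(0), domain_cond_evalue = numeric(0),
             env_start = integer(0), env_end = integer(0),
             stringsAsFactors = FALSE)
}

#' Parse a HMMER3 per-domain tabular output file (domtblout layout)
#'
#' One `DomainHit` row per data row; `#` comment lines are skipped.
#' Coordinates are taken from the envelope columns (1-based inclusive) and
#' the bit score from the full-sequence score column.
#'
#' @param path path to a domtblout-format text file.
#' @return data.frame of domain hits (see [scan_sequence()] for columns).
#' @export
read_domtbl <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- lines[keep]
  lineno <- which(keep)
  if (!length(rows)) return(empty_hits())
  parse_row <- function(i) {
    f <- strsplit(trimws(rows[i]), "[[:space:]]+")[[1]]
    if (length(f) < 22)
      stop_input(sprintf("read_domtbl(): malformed row at line %d (%d fields, need 22)",
                         lineno[i], length(f)))
    num <- suppressWarnings(as.numeric(f[c(7, 8, 10, 12, 20, 21)]))
    if (anyNA(num))
      stop_input(sprintf("read_domtbl(): non-numeric field at line %d", lineno[i]))
    data.frame(protein_id = f[1], profile_name = f[4],
               full_seq_evalue = num[1], bit_score = num[2],
               domain_index = as.integer(num[3]), domain_cond_evalue = num[4],
               env_start = as.integer(num[5]), env_end = as.integer(num[6]),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(rows), parse_row))
  rownames(out) <- NULL
  out
}

#' Write domain hits in HMMER3 domtblout layout
#'
#' Inverse of [read_domtbl()]: a round trip through both functions
#' preserves the hit list.
#'
#' @param hits data.frame of domain hits.
#' @param path output path.
#' @export
write_domtbl <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", "target name  accession tlen query name accession qlen",
                   "E-value score bias # of c-Evalue i-Evalue score bias",
                   "hmm:from to ali:from to env:from to acc description"), con)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    writeLines(sprintf("%s - %d %s - %d %.3g %.1f 0.0 %d %d %.3g %.3g %.1f 0.0 1 %d %d %d %d %d 0.90 -",
                       h$protein_id, h$env_end + 10L, h$profile_name,
                       h$env_end - h$env_start + 1L,
                       h$full_seq_evalue, h$bit_score, h$domain_index,
                       max(h$domain_index, 1L), h$domain_cond_evalue,
                       h$domain_cond_evalue, h$bit_score,
                       h$env_end - h$env_start + 1L,
                       h$env_start, h$env_end, h$env_start, h$env_end), con)
  }
  invisible(path)
}

#' Retain proteins whose best hit beats an E-value cutoff
#'
#' A protein is retained iff it has at least one hit with E-value strictly
#' below the cutoff (`E < 0.01` by default, so a hit at exactly 0.01 is
#' excluded). Hits are collapsed to a nonredundant set of protein ids.
#'
#' @param hits data.frame of domain hits.
#' @param evalue_cutoff strict upper bound (default 0.01).
#' @param use `"full"` to filter on the full-sequence E-value (default) or
#'   `"domain"` for the per-domain conditional E-value.
#' @return character vector of retained protein ids (sorted, unique).
#' @export
filter_hits <- function(hits, evalue_cutoff = 0.01, use = c("full", "domain")) {
  use <- match.arg(use)
  if (!nrow(hits)) return(character(0))
  ev <- if (use == "full") hits$full_seq_evalue else hits$domain_cond_evalue
  sort(unique(hits$protein_id[ev < evalue_cutoff]))
}

#' Fixed anchor motifs marking NAC subdomains A-E in synthetic proteins
#'
#' The synthetic generator plants these five strings at the canonical
#' positions of NAC subdomains A-E; [locate_subdomains()] finds them back by
#' exact match. With real data, subdomain coordinates are supplied as an
#' annotation table instead.
#' @return named character vector (names `A`..`E`).
#' @export
nac_subdomain_anchors <- function() {
  c(A = "LPPGFRFHPTDEELV",
    B = "DLYKFDPWELPE",
    C = "GYWKATGTDKPI",
    D = "TNWIMHEYRLAD",
    E = "VLCRIYKKNNSG")
}

#' Locate NAC subdomains A-E by their anchor motifs
#'
#' @param sequence amino-acid string.
#' @param anchors named character vector of anchor motifs (default
#'   [nac_subdomain_anchors()]).
#' @return named list mapping each found subdomain to `c(start, end)`
#'   (1-based inclusive); absent subdomains are omitted.
#' @export
locate_subdomains <- function(sequence, anchors = nac_subdomain_anchors()) {
  out <- list()
  for (nm in names(anchors)) {
    p <- regexpr(anchors[[nm]], sequence, fixed = TRUE)
    if (p > 0) out[[nm]] <- c(start = as.integer(p),
                              end = as.integer(p) + nchar(anchors[[nm]]) - 1L)
  }
  out
}

#' Partition a NAC protein into its N-terminal NAM region and C-terminal TAR
#'
#' The NT region runs from residue 1 to the envelope end of the last
#' qualifying NAM domain; the TAR (CT region) is the remainder and may be
#' empty. For two-domain proteins both envelopes are recorded and the CT
#' starts after the last envelope.
#'
#' @param protein list with `id` and `sequence`, or a bare string plus `id`.
#' @param hits data.frame of domain hits for this protein (>= 1 row).
#' @param subdomain_coords optional precomputed subdomain coordinates; when
#'   `NULL` they are located with [locate_subdomains()].
#' @param id protein id when `protein` is a bare string.
#' @return object of class `nac_protein`: list with `id`, `sequence`,
#'   `hits`, `nt_region`, `ct_region` (both `c(start, end)`; an empty CT has
#'   `start > end`), `subdomain_coords`.
#' @export
split_nt_ct <- function(protein, hits, subdomain_coords = NULL,
                        id = "protein") {
  if (is.list(protein)) {
    id <- protein$id %||% id
    sequence <- protein$sequence
  } else sequence <- protein
  if (any(hits$protein_id == id))
    hits <- hits[hits$protein_id == id, , drop = FALSE]
  if (!nrow(hits)) stop_input("split_nt_ct(): no domain hit for protein ", id)
  L <- nchar(sequence)
  if (any(hits$env_end > L) || any(hits$env_start < 1))
    stop_input("split_nt_ct(): hit coordinates exceed sequence length for ", id)
  nt_end <- max(hits$env_end)
  structure(list(id = id, sequence = sequence, hits = hits,
                 nt_region = c(start = 1L, end = as.integer(nt_end)),
                 ct_region = c(start = as.integer(nt_end) + 1L, end = L),
                 subdomain_coords = subdomain_coords %||% locate_subdomains(sequence)),
            class = "nac_protein")
}

#' @export
print.nac_protein <- function(x, ...) {
  cat("<nac_protein>", x$id, "len", nchar(x$sequence),
      "NT", x$nt_region[1], "-", x$nt_region[2],
      "CT", x$ct_region[1], "-", x$ct_region[2], "\n")
  invisible(x)
}
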