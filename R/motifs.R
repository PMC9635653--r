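#' Scan proteins for planted motifs by exact string match
#'
#' Deterministic stand-in for a motif-discovery run on synthetic data:
#' every exact occurrence of each library motif is reported. When region
#' boundaries are supplied, NT motifs are searched in the NT region and CT
#' motifs in the CT region, and coordinates are reported 1-based within the
#' region (absolute protein coordinates are kept alongside).
#'
#' @param sequences named character vector of protein sequences.
#' @param motif_library named character vector; names must be namespaced
#'   `NT-k` / `CT-k`.
#' @param regions optional data.frame with `protein_id`, `nt_start`,
#'   `nt_end`, `ct_start`, `ct_end` (from [split_nt_ct()] output); without
#'   it the whole protein is scanned and treated as region NT.
#' @return data.frame of motif occurrences: `motif`, `protein_id`,
#'   `region`, `start`, `end` (within region), `abs_start`, `abs_end`,
#'   `score`.
#' @export
find_motif_occurrences <- function(sequences, motif_library, regions = NULL) {
  out <- list()
  for (m in names(motif_library)) {
    pat <- motif_library[[m]]
    reg <- if (startsWith(m, "CT")) "CT" else "NT"
    for (id in names(sequences)) {
      seq <- sequences[[id]]
      off <- 0L
      if (!is.null(regions)) {
        r <- regions[regions$protein_id == id, , drop = FALSE]
        if (!nrow(r)) next
        bounds <- if (reg == "NT") c(r$nt_start[1], r$nt_end[1]) else
          c(r$ct_start[1], r$ct_end[1])
        if (bounds[2] < bounds[1]) next
        seq <- substr(seq, bounds[1], bounds[2])
        off <- bounds[1] - 1L
      }
      hits <- gregexpr(pat, seq, fixed = TRUE)[[1]]
      if (hits[1] == -1) next
      for (h in as.integer(hits)) {
        out[[length(out) + 1L]] <- data.frame(
          motif = m, protein_id = id, region = reg,
          start = h, end = h + nchar(pat) - 1L,
          abs_start = h + off, abs_end = h + off + nchar(pat) - 1L,
          score = nchar(pat), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(motif = character(0), protein_id = character(0),
                      region = character(0), start = integer(0),
                      end = integer(0), abs_start = integer(0),
                      abs_end = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write motif occurrences as MEME-style text
#'
#' Emits a minimal MEME-text-dialect file: a version header, the alphabet,
#' and per motif a `MOTIF <id> width=<w> sites=<n>` line followed by one
#' site line (`sequence start score site`) per occurrence and a blank
#' line. [read_meme()] parses exactly this dialect.
#'
#' @param occurrences occurrence data.frame from
#'   [find_motif_occurrences()] / [read_meme()].
#' @param path output path.
#' @param motif_widths optional named widths (defaults to occurrence spans).
#' @export
write_meme_text <- function(occurrences, path, motif_widths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 5", "",
               paste0("ALPHABET= ", paste(aa_alphabet(), collapse = "")), ""), con)
  for (m in unique(occurrences$motif)) {
    occ <- occurrences[occurrences$motif == m, , drop = FALSE]
    w <- motif_widths[[m]] %||% (occ$end[1] - occ$start[1] + 1L)
    writeLines(sprintf("MOTIF %s width=%d sites=%d", m, w, nrow(occ)), con)
    for (i in seq_len(nrow(occ)))
      writeLines(sprintf("%s %d %.2f %s", occ$protein_id[i], occ$start[i],
                         occ$score[i], strrep("X", w)), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Parse MEME-style motif output
#'
#' Reads the text dialect written by [write_meme_text()]: `MOTIF` header
#' lines with `width=`/`sites=` attributes followed by site lines. The
#' region (`NT`/`CT`) is inferred from the motif id prefix. With
#' `mode = "zoops"` (zero or one site per sequence, the CT discovery
#' setting) multiple sites of one motif in one sequence trigger a warning,
#' or an error when `strict = TRUE`.
#'
#' @param path file path.
#' @param mode `"any"` (default) or `"zoops"`.
#' @param strict error (instead of warn) on a zoops violation.
#' @return occurrence data.frame (see [find_motif_occurrences()]).
#' @export
read_meme <- function(path, mode = c("any", "zoops"), strict = FALSE) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  out <- list()
  cur <- NULL; width <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { cur <- NULL; next }
    if (grepl("^MEME version", ln) || grepl("^ALPHABET", ln)) next
    if (grepl("^MOTIF ", ln)) {
      f <- strsplit(ln, "[[:space:]]+")[[1]]
      cur <- f[2]
      wf <- grep("^width=", f, value = TRUE)
      width <- if (length(wf)) as.integer(sub("width=", "", wf)) else NA_integer_
      if (is.na(width))
        stop_input("read_meme(): malformed MOTIF header at line ", i)
      next
    }
    if (is.null(cur)) stop_input("read_meme(): site line outside a MOTIF block at line ", i)
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) < 3) stop_input("read_meme(): malformed site line at line ", i)
    st <- suppressWarnings(as.integer(f[2]))
    sc <- suppressWarnings(as.numeric(f[3]))
    if (is.na(st) || is.na(sc))
      stop_input("read_meme(): malformed site line at line ", i)
    out[[length(out) + 1L]] <- data.frame(
      motif = cur, protein_id = f[1],
      region = if (startsWith(cur, "CT")) "CT" else "NT",
      start = st, end = st + width - 1L,
      abs_start = st, abs_end = st + width - 1L,
      score = sc, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    find_motif_occurrences(character(0), character(0))
  rownames(res) <- NULL
  if (mode == "zoops" && nrow(res)) {
    dup <- duplicated(res[, c("motif", "protein_id")])
    if (any(dup)) {
      msg <- paste0("read_meme(): ", sum(dup),
                    " extra site(s) violate the zero-or-one-site contract")
      if (strict) stop_input(msg) else warning(msg, call. = FALSE)
    }
  }
  res
}

#' Binary motif presence matrix
#'
#' @param occurrences occurrence data.frame.
#' @param proteins protein ids for the columns.
#' @param motifs motif universe for the rows (default: motifs seen in the
#'   occurrences; pass explicitly to keep all-zero rows).
#' @return 0/1 integer matrix, motifs x proteins.
#' @export
presence_matrix <- function(occurrences, proteins, motifs = NULL) {
  motifs <- motifs %||% unique(occurrences$motif)
  bad <- setdiff(occurrences$protein_id, proteins)
  if (length(bad))
    stop_input("presence_matrix(): occurrences reference unknown proteins: ",
               paste(utils::head(bad, 5), collapse = ", "))
  m <- matrix(0L, nrow = length(motifs), ncol = length(proteins),
              dimnames = list(motifs, proteins))
  occ <- occurrences[occurrences$motif %in% motifs, , drop = FALSE]
  if (nrow(occ)) m[cbind(occ$motif, occ$protein_id)] <- 1L
  m
}

#' Classify motif presence per subfamily
#'
#' Per subfamily, a motif is a `signature` when present in strictly more
#' than 90% of members, `absent` when present in strictly fewer than 10%,
#' and `present` otherwise (so fractions of exactly 0.1 and 0.9 are both
#' `present`). A motif is `conserved` when its overall presence exceeds
#' 50%, and `specific` to a subfamily when it reaches 10% presence there
#' and stays below 10% in every other subfamily.
#'
#' @param matrix presence matrix from [presence_matrix()].
#' @param assignment data.frame with `leaf`/`gene_id` and `subfamily`
#'   covering all matrix columns.
#' @return object of class `motif_summary`: list with `fractions`
#'   (motif x subfamily), `class` (character matrix, same shape),
#'   `overall` (named overall fractions), `conserved` (logical),
#'   `specific_to` (named character, NA when not specific).
#' @export
classify_motifs <- function(matrix, assignment) {
  idcol <- if ("leaf" %in% names(assignment)) "leaf" else "gene_id"
  sf <- assignment$subfamily[match(colnames(matrix), assignment[[idcol]])]
  if (anyNA(sf))
    stop_input("classify_motifs(): matrix columns without subfamily assignment: ",
               paste(utils::head(colnames(matrix)[is.na(sf)], 5), collapse = ", "))
  subfams <- sort(unique(sf))
  fractions <- vapply(subfams, function(s)
    rowMeans(matrix[, sf == s, drop = FALSE]), numeric(nrow(matrix)))
  fractions <- base::matrix(fractions, nrow = nrow(matrix),
                            dimnames = list(rownames(matrix), subfams))
  cls <- ifelse(fractions > 0.9, "signature",
                ifelse(fractions < 0.1, "absent", "present"))
  overall <- rowMeans(matrix)
  specific <- apply(fractions, 1, function(fr) {
    hit <- fr >= 0.1
    if (sum(hit) == 1L) colnames(fractions)[hit] else NA_character_
  })
  structure(list(fractions = fractions, class = cls, overall = overall,
                 conserved = overall > 0.5, specific_to = specific),
            class = "motif_summary")
}

#' @export
print.motif_summary <- function(x, ...) {
  cat("<motif_summary>", nrow(x$fractions), "motifs x",
      ncol(x$fractions), "subfamilies;", sum(x$conserved), "conserved\n")
  invisible(x)
}

#' Map motif occurrences to NAC subdomains
#'
#' An occurrence is labeled with a subdomain when at least half of the
#' motif's length lies inside the subdomain interval (the subdomain with
#' the largest overlap wins); otherwise it is `between-subdomain`. The
#' motif-level label is the majority label across its occurrences.
#'
#' @param occurrences occurrence data.frame (absolute coordinates used).
#' @param subdomain_coords named list: protein id -> named list
#'   (`A`..`E` -> `c(start, end)`), e.g. from [locate_subdomains()].
#' @param min_overlap minimum fraction of the motif length inside a
#'   subdomain (default 0.5).
#' @return list with `per_occurrence` (adds `subdomain`) and `per_motif`
#'   (`motif`, `subdomain`, `n_occurrences`).
#' @export
map_to_subdomains <- function(occurrences, subdomain_coords, min_overlap = 0.5) {
  known <- occurrences$protein_id %in% names(subdomain_coords)
  if (any(!known))
    warning("map_to_subdomains(): skipped ", sum(!known),
            " occurrence(s) lacking subdomain coordinates", call. = FALSE)
  occ <- occurrences[known, , drop = FALSE]
  lab <- vapply(seq_len(nrow(occ)), function(i) {
    sd <- subdomain_coords[[occ$protein_id[i]]]
    len <- occ$abs_end[i] - occ$abs_start[i] + 1L
    best <- "between-subdomain"; best_ov <- 0
    for (nm in names(sd)) {
      ov <- min(occ$abs_end[i], sd[[nm]]["end"]) -
        max(occ$abs_start[i], sd[[nm]]["start"]) + 1
      if (ov >= min_overlap * len && ov > best_ov) { best <- nm; best_ov <- ov }
    }
    best
  }, character(1))
  occ$subdomain <- lab
  per_motif <- do.call(rbind, lapply(split(occ, occ$motif), function(o) {
    tab <- sort(table(o$subdomain), decreasing = TRUE)
    data.frame(motif = o$motif[1],
               subdomain = names(tab)[1],
               n_occurrences = nrow(o), stringsAsFactors = FALSE)
  }))
  rownames(per_motif) <- NULL
  list(per_occurrence = occ, per_motif = per_motif)
}

#' Motif-trait association (Fisher's exact test per motif)
#'
#' Tests each motif's presence against a binary gene trait (pathogen
#' responsiveness, grain-specific expression, ...) with a two-sided exact
#' test; q-values are Benjamini-Hochberg over the tested motifs.
#'
#' @param matrix presence matrix (motifs x proteins).
#' @param trait named logical vector covering every matrix column.
#' @return data.frame with `motif`, `n_with_trait`, `n_without_trait`,
#'   `odds_ratio`, `p.value`, `q.value`.
#' @export
associate_motif <- function(matrix, trait) {
  miss <- setdiff(colnames(matrix), names(trait))
  if (length(miss))
    stop_input("associate_motif(): trait undefined for: ",
               paste(utils::head(miss, 5), collapse = ", "))
  tr <- trait[colnames(matrix)]
  rows <- lapply(rownames(matrix), function(m) {
    pres <- matrix[m, ] == 1L
    a <- sum(pres & tr); b <- sum(pres & !tr)
    c_ <- sum(!pres & tr); d <- sum(!pres & !tr)
    p <- stats::fisher.test(base::matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
    data.frame(motif = m, n_with_trait = a, n_without_trait = b,
               odds_ratio = or, p.value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q.value <- stats::p.adjust(out$p.value, method = "BH")
  rownames(out) <- NULL
  out
}
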