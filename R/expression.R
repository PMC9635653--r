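#' Default pathogen panel with lifestyles
#'
#' The panel mirrors a typical wheat disease RNA-seq design: three fungal
#' hemibiotrophs (Fg *Fusarium graminearum*, Fp *F. pseudograminearum*, Zt
#' *Zymoseptoria tritici*), two biotrophs (Bg *Blumeria graminis*, Ps
#' *Puccinia striiformis*) and one bacterial hemibiotroph (Xt *Xanthomonas
#' translucens*).
#'
#' @return data.frame with `pathogen`, `lifestyle`.
#' @export
nac_pathogen_panel <- function() {
  data.frame(pathogen = c("Fg", "Fp", "Zt", "Bg", "Ps", "Xt"),
             lifestyle = c("hemibiotroph", "hemibiotroph", "hemibiotroph",
                           "biotroph", "biotroph", "hemibiotroph"),
             stringsAsFactors = FALSE)
}

#' Classify pathogen responsiveness from a differential-expression table
#'
#' A gene is responsive to a pathogen iff at least one condition (any
#' genotype/timepoint) satisfies `|log2fc| > lfc_cutoff` and
#' `padj < p_cutoff` (both strict, so log2FC = 1.0 or padj = 0.05 exactly
#' never qualify). The lifestyle category summarises which lifestyles a
#' gene responds to; `universal` flags response to at least two pathogens.
#'
#' @param de data.frame with columns `gene_id`, `pathogen`, `genotype`,
#'   `timepoint`, `log2fc`, `padj`.
#' @param panel pathogen/lifestyle map (default [nac_pathogen_panel()]);
#'   a pathogen absent from the panel is a configuration error.
#' @param lfc_cutoff strict absolute log2 fold-change bound (default 1).
#' @param p_cutoff strict adjusted-p bound (default 0.05).
#' @param p_col column used as the significance value (default `"padj"`;
#'   point it at a raw-p column to switch modes).
#' @return object of class `response_profile`: list with `profiles`
#'   (per-gene data.frame: `gene_id`, `responsive_pathogens`,
#'   `n_pathogens`, `lifestyle_category`, `universal`) and `directions`
#'   (per passing condition: `gene_id`, `pathogen`, `genotype`,
#'   `timepoint`, `direction`).
#' @export
classify_responsiveness <- function(de, panel = nac_pathogen_panel(),
                                    lfc_cutoff = 1, p_cutoff = 0.05,
                                    p_col = "padj") {
  unknown <- setdiff(unique(de$pathogen), panel$pathogen)
  if (length(unknown))
    stop_input("classify_responsiveness(): pathogens not in the panel: ",
               paste(unknown, collapse = ", "))
  pv <- de[[p_col]]
  if (is.null(pv)) stop_input("classify_responsiveness(): no column `", p_col, "`")
  pass <- abs(de$log2fc) > lfc_cutoff & pv < p_cutoff
  hits <- de[pass, , drop = FALSE]
  directions <- data.frame(gene_id = hits$gene_id, pathogen = hits$pathogen,
                           genotype = hits$genotype, timepoint = hits$timepoint,
                           direction = ifelse(hits$log2fc > 0, "up", "down"),
                           stringsAsFactors = FALSE)
  genes <- sort(unique(de$gene_id))
  resp <- lapply(genes, function(g) {
    p <- unique(hits$pathogen[hits$gene_id == g])
    p[order(match(p, panel$pathogen))]
  })
  lifestyle <- vapply(resp, function(p) {
    ls <- unique(panel$lifestyle[match(p, panel$pathogen)])
    if (!length(ls)) "none"
    else if (setequal(ls, "hemibiotroph")) "hemibiotroph-only"
    else if (setequal(ls, "biotroph")) "biotroph-only"
    else "both"
  }, character(1))
  profiles <- data.frame(
    gene_id = genes,
    responsive_pathogens = vapply(resp, join_csv_field, character(1)),
    n_pathogens = vapply(resp, length, integer(1)),
    lifestyle_category = lifestyle,
    universal = vapply(resp, length, integer(1)) >= 2L,
    stringsAsFactors = FALSE)
  structure(list(profiles = profiles, directions = directions,
                 panel = panel), class = "response_profile")
}

#' @export
print.response_profile <- function(x, ...) {
  cat("<response_profile>", nrow(x$profiles), "genes;",
      sum(x$profiles$n_pathogens > 0), "responsive\n")
  invisible(x)
}

#' Summarise lifestyle specificity of pathogen-responsive genes
#'
#' @param profiles a `response_profile` (or its `profiles` data.frame).
#' @return list with `categories` (counts and fractions of
#'   hemibiotroph-only / biotroph-only / both among responsive genes, plus
#'   `none`) and `per_pathogen` (responsive gene count per pathogen).
#' @export
lifestyle_summary <- function(profiles) {
  panel <- nac_pathogen_panel()
  if (inherits(profiles, "response_profile")) {
    panel <- profiles$panel
    profiles <- profiles$profiles
  }
  cat_levels <- c("hemibiotroph-only", "biotroph-only", "both", "none")
  counts <- table(factor(profiles$lifestyle_category, levels = cat_levels))
  n_resp <- sum(counts[c("hemibiotroph-only", "biotroph-only", "both")])
  frac <- if (n_resp > 0)
    as.numeric(counts[1:3]) / n_resp else rep(0, 3)
  categories <- data.frame(category = cat_levels,
                           n = as.integer(counts),
                           fraction_of_responsive = c(frac, NA),
                           stringsAsFactors = FALSE)
  sets <- lapply(profiles$responsive_pathogens, split_csv_field)
  per_pathogen <- data.frame(
    pathogen = panel$pathogen,
    lifestyle = panel$lifestyle,
    n_responsive = vapply(panel$pathogen, function(p)
      sum(vapply(sets, function(s) p %in% s, logical(1))), integer(1)),
    stringsAsFactors = FALSE)
  rownames(per_pathogen) <- NULL
  list(categories = categories, per_pathogen = per_pathogen)
}

#' Bin baseline expression per organ
#'
#' Organ-level tpm values are averaged per gene and organ, flagged as
#' expressed at `tpm >= expressed_cutoff`, and binned as `low` (below the
#' first quartile edge), `moderate` (between the edges, inclusive) or
#' `high` (above the second edge). With `bin_edges = "auto"` the edges are
#' the 1st and 3rd quartiles of the expressed values; fixed edges (e.g.
#' `c(0.3, 3.7)`, the published wheat values) can be supplied instead.
#'
#' @param tpm data.frame with `gene_id`, `organ`, `tpm` (>= 0; replicate
#'   rows per gene/organ are averaged).
#' @param expressed_cutoff tpm at or above which a gene counts as
#'   expressed in an organ (default 0.1).
#' @param bin_edges `"auto"` or a numeric length-2 vector.
#' @return object of class `baseline_profile`: list with `values` (gene x
#'   organ rows: `gene_id`, `organ`, `tpm`, `expressed`, `bin`), `edges`,
#'   `genes` (per gene: `n_organs_expressed`, `mean_tpm`,
#'   `grain_specific` when a "grain" organ is present).
#' @export
baseline_bins <- function(tpm, expressed_cutoff = 0.1, bin_edges = "auto") {
  if (any(tpm$tpm < 0)) stop_input("baseline_bins(): negative tpm")
  agg <- stats::aggregate(tpm ~ gene_id + organ, data = tpm, FUN = mean)
  expressed <- agg$tpm >= expressed_cutoff
  if (identical(bin_edges, "auto")) {
    edges <- unname(stats::quantile(agg$tpm[expressed], c(0.25, 0.75), type = 7))
  } else {
    stopifnot(is.numeric(bin_edges), length(bin_edges) == 2)
    edges <- bin_edges
  }
  bin <- ifelse(!expressed, "not-expressed",
                ifelse(agg$tpm < edges[1], "low",
                       ifelse(agg$tpm > edges[2], "high", "moderate")))
  values <- data.frame(gene_id = agg$gene_id, organ = agg$organ,
                       tpm = agg$tpm, expressed = expressed, bin = bin,
                       stringsAsFactors = FALSE)
  values <- values[order(values$gene_id, values$organ), , drop = FALSE]
  rownames(values) <- NULL
  per_gene <- split(values, values$gene_id)
  genes <- data.frame(
    gene_id = names(per_gene),
    n_organs_expressed = vapply(per_gene, function(v) sum(v$expressed), integer(1)),
    mean_tpm = vapply(per_gene, function(v) mean(v$tpm), numeric(1)),
    stringsAsFactors = FALSE)
  if ("grain" %in% values$organ) {
    genes$grain_specific <- vapply(per_gene, function(v) {
      g <- v$expressed[v$organ == "grain"]
      length(g) == 1 && g && sum(v$expressed) == 1
    }, logical(1))
  }
  rownames(genes) <- NULL
  structure(list(values = values, edges = edges, genes = genes,
                 expressed_cutoff = expressed_cutoff),
            class = "baseline_profile")
}

#' @export
print.baseline_profile <- function(x, ...) {
  cat("<baseline_profile>", nrow(x$genes), "genes; bin edges",
      paste(signif(x$edges, 3), collapse = " / "), "tpm\n")
  invisible(x)
}

#' Per-subfamily enrichment of responsive genes (Fisher's exact test)
#'
#' For each subfamily, builds the 2x2 table (responsive in / not in the
#' subfamily vs the rest of the family) and computes the two-sided exact
#' p-value, the sample odds ratio, and Benjamini-Hochberg adjusted
#' p-values across subfamilies.
#'
#' @param assignment data.frame with `leaf` (or `gene_id`) and `subfamily`.
#' @param responsive_set character vector of responsive gene ids; every
#'   responsive gene must be present in the assignment.
#' @return data.frame with `subfamily`, `n`, `n_responsive`,
#'   `fraction_responsive`, `odds_ratio`, `p.value`, `p.adj`.
#' @export
subfamily_enrichment <- function(assignment, responsive_set) {
  idcol <- if ("leaf" %in% names(assignment)) "leaf" else "gene_id"
  ids <- assignment[[idcol]]
  miss <- setdiff(responsive_set, ids)
  if (length(miss))
    stop_input("subfamily_enrichment(): responsive genes without assignment: ",
               paste(utils::head(miss, 5), collapse = ", "))
  sf <- assignment$subfamily
  resp <- ids %in% responsive_set
  subfams <- sort(unique(sf))
  rows <- lapply(subfams, function(s) {
    inside <- sf == s
    if (!any(inside)) {
      warning("subfamily ", s, " has zero members; skipped", call. = FALSE)
      return(NULL)
    }
    a <- sum(inside & resp); b <- sum(inside & !resp)
    c_ <- sum(!inside & resp); d <- sum(!inside & !resp)
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
    data.frame(subfamily = s, n = a + b, n_responsive = a,
               fraction_responsive = a / (a + b), odds_ratio = or,
               p.value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p.adj <- stats::p.adjust(out$p.value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Hierarchical-clustering leaf order of an expression matrix
#'
#' Agglomerative clustering with Euclidean distance (average linkage by
#' default); missing values are imputed with `impute` (conditions where a
#' gene was not tested), which is logged with a message.
#'
#' @param mat numeric matrix, genes in rows (rownames used as ids).
#' @param method linkage passed to [stats::hclust()] (default "average").
#' @param impute value substituted for NAs (default 0).
#' @return character vector of row ids in dendrogram order.
#' @export
hclust_order <- function(mat, method = "average", impute = 0) {
  if (!nrow(mat)) stop_input("hclust_order(): empty matrix")
  if (anyNA(mat)) {
    message("hclust_order(): imputing ", sum(is.na(mat)), " missing values with ",
            impute)
    mat[is.na(mat)] <- impute
  }
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  if (nrow(mat) == 1) return(rownames(mat))
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"), method = method)
  rownames(mat)[hc$order]
}
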