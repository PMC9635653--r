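#' Pipeline configuration
#'
#' Collects every numeric threshold of the workflow in one declarative
#' object, together with the seed and the synthetic-generator settings.
#' Thresholds default to the workflow's canonical values: domain E-value
#' 0.01, bootstrap support 70, inparalog identity 80%, |log2FC| 1.0,
#' adjusted p 0.05, expressed cutoff 0.1 tpm with bin edges 0.3/3.7 tpm,
#' enriched-subclade fraction 0.6, motif class bounds 0.1/0.5/0.9.
#'
#' @param seed master seed for every stochastic stage.
#' @param family a [family_config()] for the synthetic inputs (its seed is
#'   overridden by `seed`).
#' @param evalue_cutoff,score_threshold domain-scan settings.
#' @param support_threshold,identity_threshold grouping/assignment settings.
#' @param lfc_cutoff,p_cutoff responsiveness thresholds.
#' @param expressed_cutoff,bin_edges baseline-expression settings.
#' @param subclade_fraction,subclade_min_size enriched-subclade settings.
#' @param tree_noise support-degradation rate for the synthetic tree.
#' @param effect planted log2FC magnitude for the synthetic DE tables.
#' @param start_number first base number for anchorless gene names.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 42, family = family_config(),
                            evalue_cutoff = 0.01, score_threshold = 30,
                            support_threshold = 70, identity_threshold = 80,
                            lfc_cutoff = 1.0, p_cutoff = 0.05,
                            expressed_cutoff = 0.1, bin_edges = c(0.3, 3.7),
                            subclade_fraction = 0.6, subclade_min_size = 5,
                            tree_noise = 0, effect = 2.5, start_number = 153) {
  stopifnot(evalue_cutoff > 0, support_threshold >= 0, support_threshold <= 100,
            identity_threshold >= 0, identity_threshold <= 100,
            lfc_cutoff >= 0, p_cutoff > 0, p_cutoff <= 1,
            expressed_cutoff >= 0, subclade_fraction >= 0,
            subclade_fraction <= 1, tree_noise >= 0, tree_noise <= 1)
  family$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), family = family,
                 evalue_cutoff = evalue_cutoff,
                 score_threshold = score_threshold,
                 support_threshold = support_threshold,
                 identity_threshold = identity_threshold,
                 lfc_cutoff = lfc_cutoff, p_cutoff = p_cutoff,
                 expressed_cutoff = expressed_cutoff, bin_edges = bin_edges,
                 subclade_fraction = subclade_fraction,
                 subclade_min_size = subclade_min_size,
                 tree_noise = tree_noise, effect = effect,
                 start_number = start_number),
            class = "pipeline_config")
}

#' Run the full family-curation pipeline on synthetic data
#'
#' Stages, in dependency order: synthetic family generation; NAM-profile
#' construction and domain scan with E-value filtering and NT/CT
#' partitioning; alignment completeness QC; tree generation, rerooting on
#' subfamily "b" and subfamily assignment; homoeolog grouping and name
#' assignment; responsiveness classification, lifestyle summary, baseline
#' binning and subfamily enrichment; enriched-subclade detection; motif
#' scanning, classification, subdomain mapping and trait association; and
#' a machine-readable summary. When `out_dir` is given every stage writes
#' its TSV before the next stage starts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for stage TSVs.
#' @return a named list with every stage result plus `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop_input("run_pipeline(): config must come from pipeline_config()")
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv_plain(df, file.path(out_dir, paste0(name, ".tsv")))
    }
  }
  res <- list(config = config)

  # --- stage: simulate -----------------------------------------------------
  fam <- generate_family(config$family)
  res$family <- fam
  emit(fam$truth, "truth")
  emit(fam$chrom_map, "chrom_map")
  emit(fam$ortholog_table, "ortholog_table")

  # --- stage: scan ---------------------------------------------------------
  profile <- build_profile(unname(fam$nam_alignment))
  hits <- do.call(rbind, lapply(names(fam$sequences), function(id)
    scan_sequence(profile, fam$sequences[[id]], config$score_threshold, id = id)))
  retained <- filter_hits(hits, config$evalue_cutoff)
  genes <- fam$truth$gene_id
  decoys <- setdiff(names(fam$sequences), genes)
  nac_proteins <- lapply(retained, function(id)
    split_nt_ct(fam$sequences[[id]], hits, id = id))
  names(nac_proteins) <- retained
  regions <- do.call(rbind, lapply(nac_proteins, function(p)
    data.frame(protein_id = p$id, nt_start = p$nt_region[1],
               nt_end = p$nt_region[2], ct_start = p$ct_region[1],
               ct_end = p$ct_region[2], stringsAsFactors = FALSE)))
  res$scan <- list(profile = profile, hits = hits, retained = retained,
                   proteins = nac_proteins, regions = regions,
                   decoys_rejected = setdiff(decoys, retained))
  emit(hits, "domain_hits")
  emit(regions, "nt_ct_regions")

  # --- stage: qc -----------------------------------------------------------
  kept_genes <- intersect(genes, retained)
  msa <- alignment_matrix(kept_genes, unname(fam$sequences[kept_genes]))
  rep <- completeness(msa)
  flt <- filter_sequences(msa, rep)
  masked <- mask_columns(flt$msa, completeness(flt$msa))
  dd <- dedup(masked)
  res$qc <- list(report = rep, removed = flt$removed, surplus = dd$surplus,
                 Ca = rep$Ca)
  emit(completeness_table(msa), "completeness")

  # --- stage: classify (tree + subfamilies) --------------------------------
  tr <- generate_tree(fam$truth, noise = config$tree_noise, seed = config$seed)
  b_leaves <- clade_of_subfamily(tr, "b")
  tree <- if (length(b_leaves)) reroot_on_clade(tr$tree, b_leaves) else tr$tree
  assignment <- assign_subfamilies(tree, tr$reference_labels,
                                   config$support_threshold)
  res$tree <- tree
  res$reference_labels <- tr$reference_labels
  res$assignment <- assignment
  emit(assignment, "subfamily_assignment")

  # --- stage: name ---------------------------------------------------------
  groups <- group_homoeologs(tree, assignment, fam$chrom_map,
                             fam$ortholog_table, fam$sequences,
                             config$support_threshold,
                             config$identity_threshold, fam$anchor_meta)
  names_df <- assign_names(groups, tree, assignment,
                           start_number = config$start_number)
  res$groups <- groups
  res$names <- names_df
  emit(names_df, "gene_names")

  # --- stage: express ------------------------------------------------------
  expr <- generate_expression(fam$truth, effect = config$effect,
                              seed = config$seed)
  profiles <- classify_responsiveness(expr$de_table,
                                      lfc_cutoff = config$lfc_cutoff,
                                      p_cutoff = config$p_cutoff)
  lifestyle <- lifestyle_summary(profiles)
  bins <- baseline_bins(expr$baseline_tpm, config$expressed_cutoff,
                        config$bin_edges)
  responsive <- profiles$profiles$gene_id[profiles$profiles$n_pathogens > 0]
  gene_assignment <- assignment[assignment$leaf %in% genes, , drop = FALSE]
  enrichment <- subfamily_enrichment(gene_assignment, responsive)
  res$expression <- list(de = expr$de_table, baseline = expr$baseline_tpm,
                         profiles = profiles, lifestyle = lifestyle,
                         bins = bins, enrichment = enrichment,
                         responsive = responsive)
  emit(profiles$profiles, "response_profiles")
  emit(bins$values, "baseline_bins")
  emit(enrichment, "subfamily_enrichment")

  # --- stage: subclades ----------------------------------------------------
  subclades <- find_enriched_subclades(tree, responsive,
                                       config$subclade_fraction,
                                       config$subclade_min_size,
                                       universe = genes,
                                       assignment = assignment)
  res$subclades <- subclades
  emit(subclades, "enriched_subclades")

  # --- stage: motifs -------------------------------------------------------
  occ <- find_motif_occurrences(fam$sequences[kept_genes], fam$motif_library,
                                regions)
  pm <- presence_matrix(occ, kept_genes, motifs = names(fam$motif_library))
  msum <- classify_motifs(pm, gene_assignment)
  sdc <- lapply(nac_proteins[kept_genes], `[[`, "subdomain_coords")
  sdmap <- map_to_subdomains(occ, sdc)
  trait_resp <- stats::setNames(kept_genes %in% responsive, kept_genes)
  assoc_resp <- associate_motif(pm, trait_resp)
  grain <- bins$genes$gene_id[bins$genes$grain_specific %||% FALSE]
  trait_grain <- stats::setNames(kept_genes %in% grain, kept_genes)
  assoc_grain <- associate_motif(pm, trait_grain)
  res$motifs <- list(occurrences = occ, matrix = pm, summary = msum,
                     subdomains = sdmap, assoc_responsive = assoc_resp,
                     assoc_grain = assoc_grain)
  emit(occ, "motif_occurrences")
  emit(assoc_resp, "motif_assoc_responsive")

  # --- summary -------------------------------------------------------------
  truth <- fam$truth
  name_ok <- names_df$assigned_name[match(truth$gene_id, names_df$gene_id)] ==
    truth$true_name
  sf_ok <- assignment$subfamily[match(truth$gene_id, assignment$leaf)] ==
    truth$true_subfamily
  prof <- profiles$profiles
  resp_ok <- prof$responsive_pathogens[match(truth$gene_id, prof$gene_id)] ==
    truth$responsive_pathogens
  per_pathogen <- lifestyle$per_pathogen
  summary <- list(
    n_sequences = length(fam$sequences),
    n_genes = length(genes),
    n_nac_identified = length(kept_genes),
    n_decoys = length(decoys),
    n_decoys_rejected = length(res$scan$decoys_rejected),
    alignment_Ca = rep$Ca,
    n_named = nrow(names_df),
    name_accuracy = mean(name_ok, na.rm = FALSE),
    subfamily_accuracy = mean(sf_ok),
    responsiveness_accuracy = mean(resp_ok),
    n_responsive = length(responsive),
    n_universal = sum(prof$universal),
    n_enriched_subfamilies = sum(enrichment$p.adj < 0.05),
    n_enriched_subclades = nrow(subclades),
    n_signature_motifs = sum(apply(msum$class == "signature", 1, any)),
    n_conserved_motifs = sum(msum$conserved),
    tpm_edges = bins$edges)
  summary <- c(summary,
               stats::setNames(as.list(per_pathogen$n_responsive),
                               paste0("n_responsive_", per_pathogen$pathogen)))
  res$summary <- summary
  if (!is.null(out_dir)) {
    kv <- data.frame(key = names(unlist(summary)), value = unlist(summary))
    write_tsv_plain(kv, file.path(out_dir, "summary.tsv"))
  }
  res
}

# leaves of the synthetic tree that belong to one subfamily (references
# included); used to reroot on subfamily "b"
clade_of_subfamily <- function(tr, sf) {
  refs <- names(tr$reference_labels)[tr$reference_labels == sf]
  if (!length(refs)) return(character(0))
  tips <- tr$tree$tip.label
  # walk up from the reference until the clade contains a foreign reference
  qi <- match(refs[1], tips)
  anc <- phangorn::Ancestors(tr$tree, qi, type = "all")
  other_refs <- names(tr$reference_labels)[tr$reference_labels != sf]
  best <- refs[1]
  for (nd in anc) {
    cl <- clade_tips(tr$tree, nd)
    if (any(cl %in% other_refs)) break
    best <- cl
  }
  best
}

#' Export iTOL-compatible annotation files
#'
#' Writes three plain-text annotation files keyed by leaf id: a color
#' strip for subfamily membership, binary symbols for per-pathogen
#' responsiveness, and a heatmap of per-organ baseline tpm means. Leaves
#' missing from the tree are excluded and reported in a warning.
#'
#' @param assignments subfamily assignment data.frame (`leaf`,
#'   `subfamily`).
#' @param profiles a `response_profile` (or its `profiles` data.frame).
#' @param bins a `baseline_profile`.
#' @param tree_leaves character vector of valid leaf ids.
#' @param dir output directory.
#' @return named character vector of the three file paths.
#' @export
export_itol_annotations <- function(assignments, profiles, bins, tree_leaves,
                                    dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(profiles, "response_profile")) profiles <- profiles$profiles
  palette <- c(a = "#e41a1c", b = "#377eb8", c = "#4daf4a", d = "#984ea3",
               e = "#ff7f00", f = "#ffff33", g = "#a65628", h = "#f781bf",
               unclassified = "#999999")
  missing <- unique(c(setdiff(assignments$leaf, tree_leaves),
                      setdiff(profiles$gene_id, tree_leaves),
                      setdiff(bins$values$gene_id, tree_leaves)))
  if (length(missing))
    warning("export_itol_annotations(): leaves not in tree, excluded: ",
            paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)

  strip <- file.path(dir, "itol_subfamily_strip.txt")
  a <- assignments[assignments$leaf %in% tree_leaves, , drop = FALSE]
  writeLines(c("DATASET_COLORSTRIP", "SEPARATOR TAB",
               "DATASET_LABEL\tsubfamily", "COLOR\t#000000", "DATA",
               paste(a$leaf, palette[ifelse(a$subfamily %in% names(palette),
                                            a$subfamily, "unclassified")],
                     a$subfamily, sep = "\t")), strip)

  binf <- file.path(dir, "itol_pathogen_binary.txt")
  p <- profiles[profiles$gene_id %in% tree_leaves, , drop = FALSE]
  panel <- nac_pathogen_panel()$pathogen
  lines <- vapply(seq_len(nrow(p)), function(i) {
    s <- split_csv_field(p$responsive_pathogens[i])
    paste(c(p$gene_id[i], ifelse(panel %in% s, "1", "-1")), collapse = "\t")
  }, character(1))
  writeLines(c("DATASET_BINARY", "SEPARATOR TAB",
               "DATASET_LABEL\tpathogen response",
               paste0("FIELD_LABELS\t", paste(panel, collapse = "\t")),
               "DATA", lines), binf)

  heat <- file.path(dir, "itol_baseline_heatmap.txt")
  v <- bins$values[bins$values$gene_id %in% tree_leaves, , drop = FALSE]
  organs <- sort(unique(v$organ))
  wide <- do.call(rbind, lapply(split(v, v$gene_id), function(d)
    d$tpm[match(organs, d$organ)]))
  lines <- paste(rownames(wide),
                 apply(wide, 1, function(r) paste(signif(r, 4), collapse = "\t")),
                 sep = "\t")
  writeLines(c("DATASET_HEATMAP", "SEPARATOR TAB",
               "DATASET_LABEL\tbaseline tpm",
               paste0("FIELD_LABELS\t", paste(organs, collapse = "\t")),
               "DATA", lines), heat)
  c(strip = strip, binary = binf, heatmap = heat)
}
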