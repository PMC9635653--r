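#' Percent identity between two protein sequences
#'
#' Global (Needleman-Wunsch) alignment under a fixed, documented scoring
#' scheme (BLOSUM62, gap opening 10, gap extension 0.5); identity is the
#' number of identical residue pairs divided by the number of aligned
#' columns after terminal-gap columns are stripped, times 100.
#'
#' @param seq1,seq2 amino-acid strings.
#' @return percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(seq1, seq2) {
  if (!nzchar(seq1) || !nzchar(seq2))
    stop_input("pairwise_identity(): empty sequence")
  # canonical argument order: alignments with tied scores can differ in gap
  # placement, so the pair is ordered lexicographically to keep the measure
  # symmetric
  if (seq2 < seq1) { tmp <- seq1; seq1 <- seq2; seq2 <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- p == "-" | s == "-"
  # strip terminal-gap columns: leading/trailing runs that are gaps in either
  n <- length(p)
  first <- 1L
  while (first <= n && gap[first]) first <- first + 1L
  last <- n
  while (last >= 1L && gap[last]) last <- last - 1L
  if (first > last) return(0)
  keep <- first:last
  100 * sum(p[keep] == s[keep] & p[keep] != "-") / length(keep)
}

# Resolve a gene with several candidate ortholog anchors to a single one.
# Rule: if all candidates lie on the same rice chromosome, take the first
# by position rank (the "first NAC identified on the chromosome"); else
# prefer the anchor leaf at smallest patristic distance in the tree; else
# the lexicographically smallest anchor.
resolve_anchor <- function(gene, candidates, anchor_meta = NULL, tree = NULL,
                           patristic = NULL) {
  candidates <- sort(unique(candidates))
  if (length(candidates) == 1L) return(candidates)
  if (!is.null(anchor_meta)) {
    m <- anchor_meta[match(candidates, anchor_meta$anchor_name), , drop = FALSE]
    if (!anyNA(m$anchor_name) && length(unique(m$rice_chromosome)) == 1L)
      return(m$anchor_name[order(m$rice_rank)][1])
  }
  if (!is.null(tree) && !is.null(patristic) && gene %in% rownames(patristic)) {
    in_tree <- candidates[candidates %in% colnames(patristic)]
    if (length(in_tree))
      return(in_tree[order(patristic[gene, in_tree])][1])
  }
  candidates[1]
}

# memoized pairwise identity within one grouping run
pid_between <- function(sequences, a, b, cache = NULL) {
  if (is.null(cache)) return(pairwise_identity(sequences[[a]], sequences[[b]]))
  key <- paste(sort(c(a, b)), collapse = "|")
  val <- cache[[key]]
  if (is.null(val)) {
    val <- pairwise_identity(sequences[[a]], sequences[[b]])
    cache[[key]] <- val
  }
  val
}

chrom_key <- function(chrom_map) {
  paste0(chrom_map$chromosome, chrom_map$subgenome)
}

# Same-chromosome genes with identity >= threshold are merged into inparalog
# units (connected components of the identity graph). Returns a list of
# character vectors, each ordered by position rank (ties by id).
inparalog_units <- function(genes, chrom_map, sequences, identity_threshold,
                            cache = NULL) {
  info <- chrom_map[match(genes, chrom_map$gene_id), , drop = FALSE]
  key <- chrom_key(info)
  parent <- stats::setNames(seq_along(genes), genes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
      gi <- genes[idx[a]]; gj <- genes[idx[b]]
      if (pid_between(sequences, gi, gj, cache) >= identity_threshold) {
        ra <- find(idx[a]); rb <- find(idx[b])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_along(genes), find, numeric(1))
  units <- split(genes, roots)
  lapply(unname(units), function(u) {
    inf <- chrom_map[match(u, chrom_map$gene_id), , drop = FALSE]
    u[order(inf$position_rank, u)]
  })
}

unit_subgenome <- function(unit, chrom_map) {
  chrom_map$subgenome[match(unit[1], chrom_map$gene_id)]
}

units_valid <- function(units, chrom_map) {
  sg <- vapply(units, unit_subgenome, character(1), chrom_map = chrom_map)
  !anyDuplicated(sg)
}

# All cross-subgenome unit pairs must look like homoeologs (identity >=
# threshold between unit representatives) before a clade is accepted as one
# homoeologous group.
homoeolog_identity_ok <- function(units, sequences, identity_threshold,
                                  cache = NULL) {
  if (length(units) < 2) return(TRUE)
  reps <- vapply(units, `[[`, character(1), 1)
  for (a in seq_along(reps)[-length(reps)]) for (b in (a + 1):length(reps)) {
    if (pid_between(sequences, reps[a], reps[b], cache) <
        identity_threshold) return(FALSE)
  }
  TRUE
}

units_coherent <- function(units, chrom_map, sequences, identity_threshold,
                           cache = NULL) {
  units_valid(units, chrom_map) &&
    homoeolog_identity_ok(units, sequences, identity_threshold, cache)
}

# Deterministic packing of units into groups when the tree cannot resolve
# them (support below threshold): units ordered by chromosome, position
# rank, then id, and dealt round-robin into groups with at most one unit
# per subgenome.
fallback_pack <- function(units, chrom_map) {
  info <- lapply(units, function(u) chrom_map[match(u[1], chrom_map$gene_id), ])
  ord <- order(vapply(info, function(i) i$chromosome, numeric(1)),
               vapply(info, function(i) i$position_rank, numeric(1)),
               vapply(units, `[[`, character(1), 1))
  units <- units[ord]
  groups <- list()
  for (u in units) {
    sg <- unit_subgenome(u, chrom_map)
    placed <- FALSE
    for (gi in seq_along(groups)) {
      sgs <- vapply(groups[[gi]], unit_subgenome, character(1), chrom_map = chrom_map)
      if (!(sg %in% sgs)) { groups[[gi]] <- c(groups[[gi]], list(u)); placed <- TRUE; break }
    }
    if (!placed) groups[[length(groups) + 1L]] <- list(u)
  }
  groups
}

# Recursive tree-guided split of a set of units into homoeolog groups.
split_units_by_tree <- function(units, tree, sup, tips_by_node, chrom_map,
                                support_threshold, sequences,
                                identity_threshold, node = NULL,
                                cache = NULL) {
  if (length(units) == 0) return(list())
  if (units_coherent(units, chrom_map, sequences, identity_threshold, cache))
    return(list(units))
  genes <- unlist(units)
  ntip <- length(tree$tip.label)
  idx <- match(genes, tree$tip.label)
  if (anyNA(idx)) return(fallback_pack(units, chrom_map))
  node <- node %||% ape::getMRCA(tree, genes)
  if (is.null(node) || node <= ntip) return(fallback_pack(units, chrom_map))
  children <- tree$edge[tree$edge[, 1] == node, 2]
  # assign each unit to the child subtree holding (a majority of) its genes
  assign_child <- vapply(units, function(u) {
    ui <- match(u, tree$tip.label)
    hits <- vapply(children, function(ch) {
      tips <- if (ch <= ntip) ch else tips_by_node[[ch]]
      sum(ui %in% tips)
    }, numeric(1))
    children[which.max(hits)]
  }, numeric(1))
  if (length(unique(assign_child)) == 1L) {
    ch <- unique(assign_child)
    if (ch <= ntip) return(fallback_pack(units, chrom_map))
    if (sup[ch - ntip] < support_threshold) return(fallback_pack(units, chrom_map))
    return(split_units_by_tree(units, tree, sup, tips_by_node, chrom_map,
                               support_threshold, sequences,
                               identity_threshold, node = ch, cache = cache))
  }
  out <- list()
  for (ch in unique(assign_child)) {
    sub <- units[assign_child == ch]
    if (length(sub) == 1L || ch <= ntip) {
      if (units_coherent(sub, chrom_map, sequences, identity_threshold, cache))
        out <- c(out, list(sub))
      else out <- c(out, fallback_pack(sub, chrom_map))
    } else if (sup[ch - ntip] < support_threshold) {
      out <- c(out, fallback_pack(sub, chrom_map))
    } else {
      out <- c(out, split_units_by_tree(sub, tree, sup, tips_by_node, chrom_map,
                                        support_threshold, sequences,
                                        identity_threshold, node = ch,
                                        cache = cache))
    }
  }
  out
}

#' Resolve homoeolog groups from the tree, chromosome metadata and anchors
#'
#' Implements the homoeolog-resolution rules of the naming system:
#' \itemize{
#'   \item genes sharing an ortholog anchor form an orthologous cluster;
#'     same-chromosome members with protein identity at or above the
#'     threshold are merged into inparalog units ordered by position rank;
#'   \item a cluster is partitioned into homoeolog groups with at most one
#'     unit per subgenome (A, B, D, plus "unknown" U), using supported
#'     clades of the tree to split conflicting units; where the relevant
#'     nodes fall below the support threshold the partition falls back to a
#'     deterministic packing of the anchor table's genes;
#'   \item a chromosome-U gene clustering with putative homoeologs on other
#'     subgenomes joins their group;
#'   \item anchorless genes are grouped from maximal supported clades that
#'     contain only anchorless genes, requiring cross-subgenome protein
#'     identity at or above the threshold before genes are accepted as
#'     putative homoeologs of one group.
#' }
#'
#' @param tree `phylo` tree containing (at least) all genes as tips.
#' @param subfamily_assignment data.frame from [assign_subfamilies()]
#'   (used downstream for naming; accepted here for interface symmetry and
#'   validated for coverage).
#' @param chrom_map data.frame with `gene_id`, `subgenome` (A/B/D/U),
#'   `chromosome`, `position_rank`.
#' @param ortholog_table data.frame with `gene_id`, `anchor_name`; several
#'   rows per gene are allowed and resolved via `anchor_meta`/patristic
#'   distance.
#' @param sequences named character vector (or list) of protein sequences.
#' @param support_threshold bootstrap threshold for trusting a clade
#'   (default 70, inclusive).
#' @param identity_threshold percent-identity threshold for the inparalog
#'   and putative-homoeolog rules (default 80, inclusive).
#' @param anchor_meta optional data.frame `anchor_name`, `rice_chromosome`,
#'   `rice_rank` used to resolve genes orthologous to several anchors.
#' @return data.frame of class `homoeolog_groups` with one row per gene:
#'   `group_uid`, `anchor` (NA for anchorless groups), `gene_id`,
#'   `subgenome`, `chromosome`, `paralog_index` (NA when the gene is not an
#'   inparalog), `provenance` (`tree`, `fallback` or `orphan-tree`).
#' @export
group_homoeologs <- function(tree, subfamily_assignment, chrom_map,
                             ortholog_table, sequences,
                             support_threshold = 70, identity_threshold = 80,
                             anchor_meta = NULL) {
  genes <- chrom_map$gene_id
  miss <- setdiff(unique(ortholog_table$gene_id), genes)
  if (length(miss))
    stop_input("group_homoeologs(): genes missing from chrom_map: ",
               paste(utils::head(miss, 10), collapse = ", "))
  sequences <- as.list(sequences)
  cache <- new.env(parent = emptyenv())
  ntip <- length(tree$tip.label)
  sup <- node_supports(tree, quiet = TRUE)
  all_nodes <- seq_len(ntip + tree$Nnode)
  tips_by_node <- phangorn::Descendants(tree, all_nodes, type = "tips")
  patristic <- NULL
  anchors_by_gene <- split(ortholog_table$anchor_name, ortholog_table$gene_id)
  multi <- any(vapply(anchors_by_gene, function(a) length(unique(a)) > 1L, logical(1)))
  if (multi) patristic <- stats::cophenetic(tree)
  anchor_of <- vapply(genes, function(g) {
    cand <- anchors_by_gene[[g]]
    if (is.null(cand)) NA_character_
    else resolve_anchor(g, cand, anchor_meta, tree, patristic)
  }, character(1))

  out <- list()
  add_group <- function(units, anchor, provenance) {
    gid <- length(out) + 1L
    rows <- do.call(rbind, lapply(units, function(u) {
      inf <- chrom_map[match(u, chrom_map$gene_id), , drop = FALSE]
      data.frame(group_uid = NA_character_, anchor = anchor, gene_id = u,
                 subgenome = inf$subgenome, chromosome = inf$chromosome,
                 paralog_index = if (length(u) > 1) seq_along(u) else NA_integer_,
                 provenance = provenance, stringsAsFactors = FALSE)
    }))
    rows$group_uid <- sprintf("grp%04d", gid)
    out[[gid]] <<- rows
  }

  # --- anchored clusters ---------------------------------------------------
  for (anc in sort(unique(stats::na.omit(anchor_of)))) {
    cluster <- genes[!is.na(anchor_of) & anchor_of == anc]
    units <- inparalog_units(cluster, chrom_map, sequences, identity_threshold,
                             cache)
    if (units_coherent(units, chrom_map, sequences, identity_threshold, cache)) {
      add_group(units, anc, "tree")
    } else {
      parts <- split_units_by_tree(units, tree, sup, tips_by_node, chrom_map,
                                   support_threshold, sequences,
                                   identity_threshold, cache = cache)
      resolved_by_tree <- all(vapply(parts, units_valid, logical(1),
                                     chrom_map = chrom_map))
      for (p in parts)
        add_group(p, anc, if (resolved_by_tree) "tree" else "fallback")
    }
  }

  # --- anchorless (orphan) genes ------------------------------------------
  orphans <- genes[is.na(anchor_of)]
  if (length(orphans)) {
    orphan_set <- match(orphans, tree$tip.label)
    is_orphan_only <- vapply(all_nodes, function(nd) {
      tips <- if (nd <= ntip) nd else tips_by_node[[nd]]
      all(tips %in% orphan_set)
    }, logical(1))
    parents <- integer(ntip + tree$Nnode)
    parents[tree$edge[, 2]] <- tree$edge[, 1]
    parent_orphan <- parents > 0 & is_orphan_only[pmax(parents, 1L)]
    parent_orphan[parents == 0] <- FALSE
    maximal <- which(is_orphan_only & !parent_orphan)
    handled <- character(0)
    solve_orphan <- function(nd) {
      tips <- tree$tip.label[if (nd <= ntip) nd else tips_by_node[[nd]]]
      units <- inparalog_units(tips, chrom_map, sequences, identity_threshold,
                               cache)
      ok <- nd <= ntip ||
        (sup[nd - ntip] >= support_threshold &&
           units_coherent(units, chrom_map, sequences, identity_threshold, cache))
      if (ok) {
        add_group(units, NA_character_, "orphan-tree")
        handled <<- c(handled, tips)
      } else if (nd > ntip) {
        for (ch in tree$edge[tree$edge[, 1] == nd, 2]) solve_orphan(ch)
      } else {
        add_group(list(tips), NA_character_, "orphan-tree")
        handled <<- c(handled, tips)
      }
    }
    for (nd in maximal) solve_orphan(nd)
    for (g in setdiff(orphans, handled)) add_group(list(g), NA_character_, "orphan-tree")
  }

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("homoeolog_groups", class(res))
  res
}

# Leaf traversal positions used for numbering: the tree's stored (depicted)
# leaf order, rotated so that the first subfamily-"b" leaf comes first.
traversal_positions <- function(tree, subfamily_assignment) {
  tips <- tree$tip.label
  sf <- subfamily_assignment$subfamily[match(tips, subfamily_assignment$leaf)]
  start <- which(!is.na(sf) & sf == "b")[1]
  if (is.na(start)) start <- 1L
  ord <- if (start == 1L) seq_along(tips) else
    c(start:length(tips), 1:(start - 1L))
  stats::setNames(seq_along(tips), tips[ord])
}

#' Assign standardized gene names to homoeolog groups
#'
#' Names follow the grammar `<prefix><base>-<subgenome><group>(-<paralog>)`:
#' the base is the numeric part of the group's ortholog anchor (e.g.
#' `NAC048` -> `048`); groups sharing an anchor are numbered 1..k in tree
#' traversal order; anchorless groups receive consecutive bases starting at
#' `start_number` in traversal order beginning with subfamily "b"; inparalog
#' members carry their paralog index as a final suffix.
#'
#' @param groups a `homoeolog_groups` data.frame from [group_homoeologs()].
#' @param tree the `phylo` tree used for traversal order.
#' @param subfamily_assignment data.frame from [assign_subfamilies()].
#' @param start_number first base number for anchorless groups
#'   (default 153).
#' @param prefix name prefix (default `"TaNAC"`).
#' @return data.frame with `gene_id`, `assigned_name`, `anchor`, `base`,
#'   `group_number`, `subgenome`, `paralog_index`, `provenance`.
#' @export
assign_names <- function(groups, tree, subfamily_assignment,
                         start_number = 153, prefix = "TaNAC") {
  pos <- traversal_positions(tree, subfamily_assignment)
  by_group <- split(groups, groups$group_uid)
  gpos <- vapply(by_group, function(g) {
    p <- pos[g$gene_id]
    if (all(is.na(p))) Inf else min(p, na.rm = TRUE)
  }, numeric(1))
  uids <- names(by_group)
  anchor_of_group <- vapply(by_group, function(g) g$anchor[1], character(1))

  base_of_group <- stats::setNames(rep(NA_character_, length(uids)), uids)
  number_of_group <- stats::setNames(rep(NA_integer_, length(uids)), uids)
  # anchored: base from the anchor, group numbers 1..k in traversal order
  for (anc in sort(unique(stats::na.omit(anchor_of_group)))) {
    g_uids <- uids[!is.na(anchor_of_group) & anchor_of_group == anc]
    g_uids <- g_uids[order(gpos[g_uids])]
    base <- sub("^[A-Za-z]+", "", anc)
    base_of_group[g_uids] <- base
    number_of_group[g_uids] <- seq_along(g_uids)
  }
  # anchorless: consecutive bases from start_number in traversal order
  orphan_uids <- uids[is.na(anchor_of_group)]
  orphan_uids <- orphan_uids[order(gpos[orphan_uids])]
  base_of_group[orphan_uids] <- as.character(start_number + seq_along(orphan_uids) - 1L)
  number_of_group[orphan_uids] <- 1L

  res <- do.call(rbind, lapply(uids, function(u) {
    g <- by_group[[u]]
    nm <- paste0(prefix, base_of_group[u], "-", g$subgenome, number_of_group[u],
                 ifelse(is.na(g$paralog_index), "",
                        paste0("-", g$paralog_index)))
    data.frame(gene_id = g$gene_id, assigned_name = unname(nm),
               anchor = g$anchor, base = unname(base_of_group[u]),
               group_number = unname(number_of_group[u]), subgenome = g$subgenome,
               paralog_index = g$paralog_index, provenance = g$provenance,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  if (anyDuplicated(res$assigned_name))
    stop("assign_names(): internal error - duplicate names generated: ",
         paste(res$assigned_name[duplicated(res$assigned_name)], collapse = ", "))
  res[order(match(res$gene_id, groups$gene_id)), , drop = FALSE]
}
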