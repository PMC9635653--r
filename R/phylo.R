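#' Read a newick tree with bootstrap supports on internal nodes
#'
#' Internal node labels are interpreted as integer bootstrap supports in
#' \[0, 100\] (the UFBoot convention). Topology, branch lengths and labels
#' are preserved as an `ape` `phylo` object.
#'
#' @param path path to a newick file, or a newick string when `text` is used.
#' @param text optional newick string (overrides `path`).
#' @return a `phylo` tree.
#' @export
read_support_tree <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tr)) stop_input("read_support_tree(): unparsable newick input")
  tr
}

#' @rdname read_support_tree
#' @param tree a `phylo` tree.
#' @export
write_support_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Numeric node supports of a tree
#'
#' Missing or non-numeric internal-node labels are treated as support 0
#' (failing any threshold) with a warning.
#'
#' @param tree a `phylo` tree.
#' @param quiet suppress the missing-support warning.
#' @return numeric vector of length `tree$Nnode`, indexed by internal node
#'   (node number minus the number of tips).
#' @export
node_supports <- function(tree, quiet = FALSE) {
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  sup <- suppressWarnings(as.numeric(lab))
  bad <- is.na(sup)
  if (any(bad)) {
    if (!quiet)
      warning(sum(bad), " internal node(s) lack a numeric support; treated as 0",
              call. = FALSE)
    sup[bad] <- 0
  }
  sup
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}

#' Reroot a tree on the branch subtending a clade
#'
#' Places the root on the branch subtending the given leaves (which must
#' form a clade of the unrooted tree). The bipartition set is unchanged;
#' support labels stay attached to their bipartitions.
#'
#' @param tree a `phylo` tree.
#' @param clade_leaves tip labels of the clade to root on.
#' @return the rerooted `phylo` tree.
#' @export
reroot_on_clade <- function(tree, clade_leaves) {
  miss <- setdiff(clade_leaves, tree$tip.label)
  if (length(miss))
    stop_input("reroot_on_clade(): leaves not in tree: ", paste(miss, collapse = ", "))
  comp <- setdiff(tree$tip.label, clade_leaves)
  if (!length(comp)) return(tree)
  ok <- ape::is.monophyletic(tree, clade_leaves) ||
    ape::is.monophyletic(tree, comp)
  if (!ok)
    stop_input("reroot_on_clade(): leaves do not form a clade of the unrooted tree: ",
               paste(utils::head(clade_leaves, 5), collapse = ", "),
               if (length(clade_leaves) > 5) ", ...")
  # if the tree is already rooted on the requested split, keep it unchanged
  root_children <- tree$edge[tree$edge[, 1] == length(tree$tip.label) + 1L, 2]
  for (ch in root_children) {
    if (setequal(clade_tips(tree, ch), clade_leaves)) return(tree)
  }
  ape::root(tree, outgroup = clade_leaves, resolve.root = TRUE, edgelabel = TRUE)
}

#' Assign tree leaves to subfamilies using labeled reference leaves
#'
#' Each query leaf receives label `L` iff the smallest clade whose defining
#' node has bootstrap support at or above the threshold and which contains
#' the query together with at least one reference leaf contains reference
#' leaves of exactly one subfamily `L`; otherwise the leaf is
#' `"unclassified"`. Reference leaves keep their input label.
#'
#' @param tree a `phylo` tree with supports as internal node labels.
#' @param reference_labels named character vector: reference leaf ->
#'   subfamily label.
#' @param support_threshold minimum support for a clade to count
#'   (default 70; a node at exactly 70 qualifies).
#' @param provenance provenance string recorded for query leaves.
#' @return data.frame with `leaf`, `subfamily`, `provenance`,
#'   `support_used` (NA for reference leaves and unclassified leaves that
#'   never met a supported reference-containing clade).
#' @export
assign_subfamilies <- function(tree, reference_labels, support_threshold = 70,
                               provenance = "joined-tree") {
  if (!length(reference_labels))
    stop_input("assign_subfamilies(): no reference leaves supplied")
  refs <- intersect(names(reference_labels), tree$tip.label)
  if (!length(refs))
    stop_input("assign_subfamilies(): none of the reference leaves are in the tree")
  ntip <- length(tree$tip.label)
  sup <- node_supports(tree)
  tips_by_node <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), type = "tips")
  ref_idx <- match(refs, tree$tip.label)
  ref_lab <- unname(reference_labels[refs])
  queries <- setdiff(tree$tip.label, refs)
  res <- lapply(queries, function(q) {
    qi <- match(q, tree$tip.label)
    anc <- phangorn::Ancestors(tree, qi, type = "all")
    for (node in anc) {
      if (sup[node - ntip] < support_threshold) next
      in_clade <- ref_idx %in% tips_by_node[[node]]
      if (!any(in_clade)) next
      labs <- unique(ref_lab[in_clade])
      lab <- if (length(labs) == 1L) labs else "unclassified"
      return(data.frame(leaf = q, subfamily = lab, provenance = provenance,
                        support_used = sup[node - ntip], stringsAsFactors = FALSE))
    }
    data.frame(leaf = q, subfamily = "unclassified", provenance = provenance,
               support_used = NA_real_, stringsAsFactors = FALSE)
  })
  out <- rbind(
    do.call(rbind, res),
    data.frame(leaf = refs, subfamily = ref_lab, provenance = "reference",
               support_used = NA_real_, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Find maximal subclades enriched in responsive genes
#'
#' Reports clades with at least `min_size` member genes of which a fraction
#' of at least `min_fraction` is responsive; a clade nested inside another
#' reported clade is suppressed (maximality). Order is deterministic by
#' tree traversal.
#'
#' @param tree a `phylo` tree.
#' @param responsive character vector of responsive leaf ids (subset of the
#'   gene universe).
#' @param min_fraction minimum responsive fraction (default 0.6; a clade at
#'   exactly 0.6 is reported).
#' @param min_size minimum number of member genes (default 5).
#' @param universe leaves counted as genes (default: all leaves). Reference
#'   or ortholog leaves can be excluded here.
#' @param assignment optional subfamily assignment data.frame (columns
#'   `leaf`, `subfamily`) used to label subclades, e.g. `"e1"`.
#' @return data.frame with `node`, `label`, `subfamily`, `n_members`,
#'   `n_responsive`, `fraction`, `members` (comma-joined leaf ids).
#' @export
find_enriched_subclades <- function(tree, responsive, min_fraction = 0.6,
                                    min_size = 5, universe = NULL,
                                    assignment = NULL) {
  universe <- universe %||% tree$tip.label
  bad <- setdiff(responsive, tree$tip.label)
  if (length(bad))
    stop_input("find_enriched_subclades(): responsive leaves not in tree: ",
               paste(utils::head(bad, 5), collapse = ", "))
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  tips_by_node <- phangorn::Descendants(tree, nodes, type = "tips")
  stats <- lapply(seq_along(nodes), function(i) {
    mem <- intersect(tree$tip.label[tips_by_node[[i]]], universe)
    n <- length(mem)
    r <- length(intersect(mem, responsive))
    list(node = nodes[i], mem = mem, n = n, r = r,
         frac = if (n > 0) r / n else 0)
  })
  qualifies <- vapply(stats, function(s) s$n >= min_size && s$frac >= min_fraction,
                      logical(1))
  qnodes <- nodes[qualifies]
  keep <- vapply(qnodes, function(nd) {
    anc <- phangorn::Ancestors(tree, nd, type = "all")
    !any(anc %in% qnodes)
  }, logical(1))
  sel <- stats[match(qnodes[keep], nodes)]
  if (!length(sel))
    return(data.frame(node = integer(0), label = character(0),
                      subfamily = character(0), n_members = integer(0),
                      n_responsive = integer(0), fraction = numeric(0),
                      members = character(0), stringsAsFactors = FALSE))
  sf <- vapply(sel, function(s) {
    if (is.null(assignment)) return(NA_character_)
    labs <- assignment$subfamily[match(s$mem, assignment$leaf)]
    labs <- labs[!is.na(labs) & labs != "unclassified"]
    if (!length(labs)) return("unclassified")
    names(sort(table(labs), decreasing = TRUE))[1]
  }, character(1))
  grp <- ifelse(is.na(sf), "clade", sf)
  idx <- stats::ave(seq_along(grp), grp, FUN = seq_along)
  label <- paste0(grp, idx)
  data.frame(node = vapply(sel, `[[`, integer(1), "node"),
             label = label, subfamily = sf,
             n_members = vapply(sel, `[[`, integer(1), "n"),
             n_responsive = vapply(sel, `[[`, integer(1), "r"),
             fraction = vapply(sel, `[[`, numeric(1), "frac"),
             members = vapply(sel, function(s) join_csv_field(s$mem), character(1)),
             stringsAsFactors = FALSE)
}
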