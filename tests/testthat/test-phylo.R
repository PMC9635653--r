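test_that("newick supports are read from internal node labels", {
  tr <- read_support_tree(text = "((A:1,B:1)95:1,C:2);")
  expect_equal(tr$Nnode, 2L)
  expect_true("95" %in% tr$node.label)
  sup <- suppressWarnings(node_supports(tr))
  expect_true(95 %in% sup)
})

test_that("write/read round trip preserves the bipartition set", {
  tr <- read_support_tree(text = "((A:1,B:1)90:1,((C:1,D:1)80:1,E:1)70:1)100;")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_support_tree(tr, path)
  back <- read_support_tree(path)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_identical(sort(back$tip.label), sort(tr$tip.label))
})

test_that("missing supports are treated as zero with a warning", {
  tr <- read_support_tree(text = "((A:1,B:1):1,C:2);")
  expect_warning(sup <- node_supports(tr), "treated as 0")
  expect_true(all(sup == 0))
})

test_that("rerooting on a clade keeps bipartitions and is idempotent", {
  tr <- read_support_tree(text = "((A:1,B:1)90:1,(C:1,D:1)80:1)100;")
  r1 <- reroot_on_clade(tr, c("A", "B"))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(r1)), 0,
               ignore_attr = TRUE)
  r2 <- reroot_on_clade(r1, c("A", "B"))
  expect_identical(ape::write.tree(r2), ape::write.tree(r1))
  expect_error(reroot_on_clade(tr, c("A", "C")), "clade")
})

test_that("subfamily assignment follows the smallest supported clade rule", {
  refs <- c(ref_a = "a")
  tr98 <- read_support_tree(text = "((q:1,ref_a:1)98:1,(x:1,y:1)99:1)100;")
  asn <- assign_subfamilies(tr98, refs)
  expect_equal(asn$subfamily[asn$leaf == "q"], "a")
  # same topology, support 69: below the threshold, walk fails -> unclassified
  tr69 <- read_support_tree(text = "((q:1,ref_a:1)69:1,(x:1,y:1)99:1)65;")
  asn69 <- assign_subfamilies(tr69, refs)
  expect_equal(asn69$subfamily[asn69$leaf == "q"], "unclassified")
  # support exactly 70 qualifies (inclusive threshold)
  tr70 <- read_support_tree(text = "((q:1,ref_a:1)70:1,(x:1,y:1)99:1)65;")
  expect_equal(assign_subfamilies(tr70, refs)$subfamily[1], "a")
})

test_that("mixed-subfamily supported clades leave queries unclassified", {
  refs <- c(ref_a = "a", ref_b = "b")
  tr <- read_support_tree(text = "((q:1,(ref_a:1,ref_b:1)100:1)100:1,z:1)100;")
  asn <- assign_subfamilies(tr, refs)
  expect_equal(asn$subfamily[asn$leaf == "q"], "unclassified")
  expect_error(assign_subfamilies(tr, c(missing_leaf = "a")), "reference")
})

test_that("assignment is invariant to rerooting on a subfamily clade", {
  fam <- small_family(31)
  tr <- generate_tree(fam$truth, noise = 0, seed = 31)
  asn1 <- assign_subfamilies(tr$tree, tr$reference_labels)
  # reroot on the subfamily-"h" clade (genes plus its reference leaves)
  clade_leaves <- c(fam$truth$gene_id[fam$truth$true_subfamily == "h"],
                    names(tr$reference_labels)[tr$reference_labels == "h"])
  clade_leaves <- intersect(clade_leaves, tr$tree$tip.label)
  rt <- reroot_on_clade(tr$tree, clade_leaves)
  expect_equal(ape::dist.topo(ape::unroot(tr$tree), ape::unroot(rt)), 0,
               ignore_attr = TRUE)
  asn2 <- suppressWarnings(assign_subfamilies(rt, tr$reference_labels))
  m <- match(asn1$leaf, asn2$leaf)
  expect_identical(asn1$subfamily, asn2$subfamily[m])
})

# independent clade enumeration from the edge matrix
clades_oracle <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips <- function(nd) {
    if (nd <= ntip) return(tree$tip.label[nd])
    unlist(lapply(kids[[as.character(nd)]], tips))
  }
  lapply((ntip + 1):(ntip + tree$Nnode), tips)
}

test_that("enriched subclades match brute-force clade enumeration", {
  set.seed(17)
  for (i in 1:5) {
    tree <- ape::rtree(30)
    tree$node.label <- rep("100", tree$Nnode)
    responsive <- sample(tree$tip.label, 12)
    out <- find_enriched_subclades(tree, responsive, min_fraction = 0.6,
                                   min_size = 4)
    all_clades <- clades_oracle(tree)
    qual <- Filter(function(cl) length(cl) >= 4 &&
                     mean(cl %in% responsive) >= 0.6, all_clades)
    maximal <- Filter(function(cl) !any(vapply(qual, function(o)
      length(o) > length(cl) && all(cl %in% o), logical(1))), qual)
    got <- lapply(strsplit(out$members, ","), sort)
    expect_equal(length(got), length(maximal))
    expect_true(all(vapply(maximal, function(cl)
      any(vapply(got, identical, logical(1), sort(cl))), logical(1))))
  }
})

test_that("the 60% enrichment boundary is inclusive and clades are maximal", {
  # clade of 10 tips, 6 responsive -> fraction 0.6 reported
  nwk <- paste0("(((", paste(sprintf("t%d:1", 1:10), collapse = ","),
                ")100:1,o1:1)100:1,(o2:1,o3:1)100:1)100;")
  tree <- read_support_tree(text = nwk)
  out6 <- find_enriched_subclades(tree, sprintf("t%d", 1:6),
                                  min_fraction = 0.6, min_size = 5)
  expect_equal(nrow(out6), 1L)
  expect_equal(out6$fraction, 0.6)
  out5 <- find_enriched_subclades(tree, sprintf("t%d", 1:5),
                                  min_fraction = 0.6, min_size = 5)
  expect_equal(nrow(out5), 0L)
  # no reported clade may nest inside another reported clade
  fam <- small_family(33)
  tr <- generate_tree(fam$truth, noise = 0, seed = 33)
  resp <- fam$truth$gene_id[nzchar(fam$truth$responsive_pathogens)]
  sub <- find_enriched_subclades(tr$tree, resp, universe = fam$truth$gene_id)
  if (nrow(sub) > 1) {
    mem <- strsplit(sub$members, ",")
    for (i in seq_along(mem)) for (j in seq_along(mem)) {
      if (i != j) expect_false(all(mem[[i]] %in% mem[[j]]))
    }
  }
})
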