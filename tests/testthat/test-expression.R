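de_row <- function(gene, pathogen, lfc, padj, tp = "T1") {
  data.frame(gene_id = gene, pathogen = pathogen, genotype = "S",
             timepoint = tp, log2fc = lfc, padj = padj,
             stringsAsFactors = FALSE)
}

test_that("responsiveness thresholds are strict at both boundaries", {
  de <- rbind(de_row("g1", "Fg", 1.0, 0.01),     # |lfc| not > 1 -> fails
              de_row("g2", "Fg", 1.01, 0.05),    # padj not < 0.05 -> fails
              de_row("g3", "Fg", 1.01, 0.049),   # passes
              de_row("g4", "Fg", -1.5, 0.001))   # down-regulation passes
  prof <- classify_responsiveness(de)$profiles
  expect_equal(prof$n_pathogens[match(c("g1", "g2", "g3", "g4"),
                                      prof$gene_id)], c(0L, 0L, 1L, 1L))
  dirs <- classify_responsiveness(de)$directions
  expect_identical(dirs$direction[dirs$gene_id == "g4"], "down")
  expect_error(classify_responsiveness(de_row("g", "Unknown", 2, 0.01)),
               "panel")
})

test_that("lifestyle categories and the universal flag follow the pathogen sets", {
  de <- rbind(de_row("g1", "Fg", 2, 0.01), de_row("g1", "Zt", 2, 0.01),
              de_row("g2", "Bg", 2, 0.01),
              de_row("g3", "Fg", 2, 0.01), de_row("g3", "Ps", -2, 0.01))
  prof <- classify_responsiveness(de)$profiles
  expect_identical(prof$lifestyle_category,
                   c("hemibiotroph-only", "biotroph-only", "both"))
  expect_identical(prof$universal, c(TRUE, FALSE, TRUE))
})

test_that("classification equals a brute-force reimplementation", {
  set.seed(3)
  de <- do.call(rbind, lapply(1:60, function(i)
    de_row(sprintf("g%d", sample(3, 1)), sample(c("Fg", "Bg", "Xt"), 1),
           stats::runif(1, -3, 3), stats::runif(1), sample(c("T1", "T2"), 1))))
  prof <- classify_responsiveness(de)$profiles
  for (g in unique(de$gene_id)) {
    expected <- sort(unique(de$pathogen[de$gene_id == g &
                                          abs(de$log2fc) > 1 & de$padj < 0.05]))
    got <- sort(strsplit(prof$responsive_pathogens[prof$gene_id == g], ",")[[1]])
    expect_identical(got, expected)
  }
})

test_that("lifestyle summary counts specific vs shared responders", {
  de <- rbind(
    do.call(rbind, lapply(1:10, function(i) de_row(sprintf("h%d", i), "Fg", 2, 0.01))),
    do.call(rbind, lapply(1:5, function(i)
      rbind(de_row(sprintf("b%d", i), "Fg", 2, 0.01),
            de_row(sprintf("b%d", i), "Bg", 2, 0.01)))))
  ls <- lifestyle_summary(classify_responsiveness(de))
  cats <- ls$categories
  expect_equal(cats$n[cats$category == "hemibiotroph-only"], 10L)
  expect_equal(cats$n[cats$category == "both"], 5L)
  expect_equal(cats$fraction_of_responsive[cats$category == "hemibiotroph-only"],
               10 / 15)
  expect_equal(sum(cats$fraction_of_responsive[1:3]), 1)
  expect_equal(ls$per_pathogen$n_responsive[ls$per_pathogen$pathogen == "Fg"], 15L)
  empty <- lifestyle_summary(classify_responsiveness(de_row("g", "Fg", 0.1, 0.9)))
  expect_true(all(empty$categories$n[1:3] == 0L))
})

test_that("baseline bins follow the fixed quartile edges", {
  tpm <- data.frame(gene_id = rep(c("g1", "g2", "g3", "g4"), each = 1),
                    organ = "leaf", tpm = c(0.2, 1.0, 5.0, 0.05),
                    stringsAsFactors = FALSE)
  bp <- baseline_bins(tpm, bin_edges = c(0.3, 3.7))
  expect_identical(bp$values$bin[match(c("g1", "g2", "g3", "g4"),
                                       bp$values$gene_id)],
                   c("low", "moderate", "high", "not-expressed"))
  # edge values fall in the moderate band
  edgecase <- baseline_bins(data.frame(gene_id = c("a", "b"), organ = "leaf",
                                       tpm = c(0.3, 3.7)),
                            bin_edges = c(0.3, 3.7))
  expect_identical(edgecase$values$bin, c("moderate", "moderate"))
  expect_error(baseline_bins(data.frame(gene_id = "a", organ = "leaf",
                                        tpm = -1)), "negative")
})

test_that("automatic bin edges equal independently computed quartiles", {
  set.seed(9)
  tpm <- data.frame(gene_id = sprintf("g%03d", 1:200), organ = "root",
                    tpm = stats::rlnorm(200, 0, 1.5), stringsAsFactors = FALSE)
  bp <- baseline_bins(tpm, bin_edges = "auto")
  x <- sort(tpm$tpm[tpm$tpm >= 0.1])
  # type-7 order-statistic interpolation, computed from scratch
  q <- function(p) {
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(bp$edges, c(q(0.25), q(0.75)))
})

test_that("subfamily enrichment p-values equal hypergeometric enumeration", {
  asn <- data.frame(
    leaf = sprintf("g%03d", 1:100),
    subfamily = rep(c("a", "b"), c(10, 90)), stringsAsFactors = FALSE)
  responsive <- c(sprintf("g%03d", 1:8), sprintf("g%03d", 11:20))
  out <- subfamily_enrichment(asn, responsive)
  # subfamily a: table (8, 2, 10, 80)
  expect_equal(out$p.value[out$subfamily == "a"],
               fisher_p_enum(8, 2, 10, 80), tolerance = 1e-9)
  # all genes responsive -> degenerate, p = 1
  all_resp <- subfamily_enrichment(asn, asn$leaf)
  expect_true(all(all_resp$p.value == 1))
  expect_error(subfamily_enrichment(asn, "ghost"), "without assignment")
})

test_that("family-vs-genome chi-square matches the Pearson formula", {
  res <- family_vs_genome_chisq(64, 460, 11000, 110000)
  o <- c(64, 460 - 64, 11000, 110000 - 11000)
  tot <- sum(o)
  e <- c((o[1] + o[2]) * (o[1] + o[3]) / tot,
         (o[1] + o[2]) * (o[2] + o[4]) / tot,
         (o[3] + o[4]) * (o[1] + o[3]) / tot,
         (o[3] + o[4]) * (o[2] + o[4]) / tot)
  expect_equal(res$statistic, sum((o - e)^2 / e), tolerance = 1e-12)
  expect_equal(res$df, 1)
  # equal proportions -> statistic 0, p 1
  null <- family_vs_genome_chisq(10, 100, 100, 1000)
  expect_equal(null$statistic, 0)
  expect_equal(null$p.value, 1)
  # swapping the two rows leaves the statistic unchanged
  swap <- family_vs_genome_chisq(11000, 110000, 64, 460)
  expect_equal(swap$statistic, res$statistic)
  expect_error(family_vs_genome_chisq(0, 10, 0, 10), "expected")
})

test_that("Kruskal-Wallis H matches the textbook formula on a hand example", {
  groups <- list(g1 = c(1, 5, 8, 11), g2 = c(2, 6, 9, 12), g3 = c(3, 7, 10, 13))
  res <- kruskal_wallis_stepdown(groups)
  x <- unlist(groups); r <- rank(x); N <- length(x)
  Rj <- tapply(r, rep(names(groups), each = 4), sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / 4) - 3 * (N + 1)
  expect_equal(res$H, H, tolerance = 1e-12)
  expect_equal(res$df, 2)
})

test_that("step-down subsets separate shifted groups and merge identical ones", {
  same <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  expect_equal(unique(kruskal_wallis_stepdown(same)$subsets$subset), 1L)
  set.seed(12)
  shifted <- list(lo = stats::rnorm(12, 0), mid = stats::rnorm(12, 10),
                  hi = stats::rnorm(12, 20))
  out <- kruskal_wallis_stepdown(shifted)
  expect_equal(sort(unique(out$subsets$subset)), 1:3)
  expect_error(kruskal_wallis_stepdown(list(a = 1:3)), ">= 2 groups")
})

test_that("Moses exact p equals full enumeration for small samples", {
  cases <- list(
    list(ctrl = c(1, 2, 3, 4), exp = c(10, 11, 12, 13), h = 0),
    list(ctrl = c(5, 6, 7, 8), exp = c(1, 2, 11, 12), h = 0),
    list(ctrl = c(2, 5, 7, 9, 12, 14), exp = c(1, 3, 16, 18, 20, 22), h = 1),
    list(ctrl = c(3, 8, 10, 15, 21), exp = c(1, 2, 25, 30, 31, 33, 35), h = 1))
  for (cs in cases) {
    got <- moses_test(cs$ctrl, cs$exp, trim_h = cs$h)
    expect_equal(got$p.value, moses_p_enum(cs$ctrl, cs$exp, cs$h),
                 tolerance = 1e-12)
  }
})

test_that("Moses statistic behaves directionally and ranks drive the p-value", {
  # experimental strictly inside the control range -> maximal span, p near 1
  inside <- moses_test(c(1, 2, 13, 14), c(5, 6, 7, 8), trim_h = 0)
  expect_equal(inside$span, 8L)
  expect_equal(inside$p.value, 1)
  # extreme experimental reactions -> minimal span, small p
  extreme <- moses_test(c(5, 6, 7, 8), c(1, 2, 20, 21), trim_h = 0)
  expect_equal(extreme$span, 4L)
  expect_equal(extreme$p.value, 5 / 70)   # 5 consecutive windows of C(8,4)
  # invariance under a strictly monotone transform
  t1 <- moses_test(c(2, 5, 7, 9, 12, 14), c(1, 3, 16, 18, 20, 22), trim_h = 1)
  t2 <- moses_test(exp(c(2, 5, 7, 9, 12, 14) / 3),
                   exp(c(1, 3, 16, 18, 20, 22) / 3), trim_h = 1)
  expect_equal(t1$p.value, t2$p.value)
  expect_equal(t1$span, t2$span)
  expect_error(moses_test(c(1, 2, 3), c(1, 2, 3), trim_h = 1), "observations")
})

test_that("hierarchical clustering order is deterministic and groups duplicates", {
  mat <- rbind(g1 = c(0, 0), g2 = c(0.1, 0), g3 = c(10, 10), g4 = c(10.2, 10))
  o1 <- hclust_order(mat)
  o2 <- hclust_order(mat)
  expect_identical(o1, o2)
  expect_equal(abs(diff(match(c("g1", "g2"), o1))), 1)
  expect_equal(abs(diff(match(c("g3", "g4"), o1))), 1)
  dup <- rbind(a = c(1, 2, 3), b = c(9, 9, 9), c = c(1, 2, 3))
  od <- hclust_order(dup)
  expect_equal(abs(diff(match(c("a", "c"), od))), 1)
  expect_message(hclust_order(rbind(a = c(1, NA), b = c(0, 0))), "imputing")
  expect_error(hclust_order(matrix(numeric(0), 0, 2)), "empty")
})
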