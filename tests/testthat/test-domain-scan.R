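# independent per-cell profile oracle: log2(((count+pc)/(n+20*pc))/bg)
profile_cell_oracle <- function(rows, col, residue, pc = 1) {
  m <- do.call(rbind, strsplit(rows, ""))
  all_res <- m[m != "-"]
  bg <- (sum(all_res == residue) + pc) / (length(all_res) + 20 * pc)
  colres <- m[, col][m[, col] != "-"]
  p <- (sum(colres == residue) + pc) / (length(colres) + 20 * pc)
  log2(p / bg)
}

test_that("profile cells follow the pseudocounted log-odds formula", {
  rows <- c("ACD", "AGD")
  prof <- build_profile(rows, pseudocount = 1)
  expect_equal(prof$width, 3L)
  for (col in 1:3) for (res in c("A", "C", "G", "D", "W")) {
    expect_equal(unname(prof$scores[res, col]),
                 profile_cell_oracle(rows, col, res),
                 tolerance = 1e-12)
  }
})

test_that("identical training sequences score their consensus positively", {
  rows <- c("MKVLW", "MKVLW")
  prof <- build_profile(rows, pseudocount = 1)
  for (i in 1:5)
    expect_gt(prof$scores[substr(rows[1], i, i), i], 0)
  # the consensus string achieves the maximum achievable window score
  cons_score <- sum(vapply(1:5, function(i)
    prof$scores[substr(prof$consensus, i, i), i], numeric(1)))
  expect_equal(cons_score, sum(apply(prof$scores, 2, max)))
})

test_that("columns with half or more gaps are dropped", {
  rows <- c("A-C", "A-C", "AGC", "A--")
  prof <- build_profile(rows)
  expect_equal(prof$kept_columns, c(1L, 3L))
})

test_that("scan_sequence equals exhaustive window scoring", {
  fam <- small_family(13)
  prof <- build_profile(substr(unname(fam$nam_alignment), 1, 40))
  set.seed(99)
  for (i in 1:8) {
    seq <- paste(sample(AA20, sample(60:200, 1), replace = TRUE), collapse = "")
    for (thr in c(-20, 0, 10)) {
      hits <- scan_sequence(prof, seq, score_threshold = thr)
      expect_identical(hits$env_start, scan_oracle(prof, seq, thr))
    }
  }
})

test_that("planted NAM cores give one covering hit, shuffles give none", {
  fam <- generate_family(family_config(seed = 21, n_anchor_orthologs = 8,
                                       decoy_count = 200))
  prof <- build_profile(unname(fam$nam_alignment))
  genes <- fam$truth$gene_id
  decoys <- setdiff(names(fam$sequences), genes)
  nam <- fam$architecture$nam_range
  for (g in genes[1:10]) {
    h <- scan_sequence(prof, fam$sequences[[g]], 30, id = g)
    expect_equal(nrow(h), 1L)
    expect_lte(h$env_start, nam[1])
    expect_gte(h$env_end, nam[2] - 5L)
  }
  rejected <- vapply(decoys, function(d)
    nrow(scan_sequence(prof, fam$sequences[[d]], 30)) == 0L, logical(1))
  expect_gte(mean(rejected), 0.95)
  # and every planted gene is retained at the default threshold
  retained <- vapply(genes, function(g)
    nrow(scan_sequence(prof, fam$sequences[[g]], 30)) >= 1L, logical(1))
  expect_true(all(retained))
})

test_that("a sequence with two planted cores yields two indexed hits", {
  fam <- small_family(22)
  g <- fam$truth$gene_id[1]
  core <- substr(fam$sequences[[g]], fam$architecture$nam_range[1],
                 fam$architecture$nam_range[2])
  linker <- strrep("G", 15)
  double <- paste0("MSS", core, linker, core, strrep("A", 10))
  prof <- build_profile(unname(fam$nam_alignment))
  h <- scan_sequence(prof, double, 30, id = "double")
  expect_equal(nrow(h), 2L)
  expect_identical(h$domain_index, 1:2)
  expect_lt(h$env_end[1], h$env_start[2])
})

test_that("domtbl parsing echoes envelope coordinates and skips comments", {
  path <- withr::local_tempfile(fileext = ".domtbl")
  writeLines(c(
    "# comment line",
    "protA - 150 NAM - 128 1e-20 80.1 0.0 1 1 1e-18 1e-18 80.1 0.0 1 128 8 130 10 120 0.9 -",
    "protB - 200 NAM - 128 2e-05 35.0 0.0 1 2 1e-04 1e-04 20.0 0.0 1 128 5 120 5 121 0.9 -",
    "protB - 200 NAM - 128 2e-05 35.0 0.0 2 2 5e-03 5e-03 12.0 0.0 1 128 130 190 129 195 0.9 -"),
    path)
  hits <- read_domtbl(path)
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$env_start[1], 10L)
  expect_equal(hits$env_end[1], 120L)
  expect_equal(hits$full_seq_evalue[2], 2e-05)
  expect_error(read_domtbl({
    p2 <- withr::local_tempfile(); writeLines("too few fields", p2); p2
  }), "line 1")
})

test_that("domtbl writing and re-reading preserves the hit list", {
  fam <- small_family(23)
  prof <- build_profile(unname(fam$nam_alignment))
  hits <- do.call(rbind, lapply(fam$truth$gene_id[1:5], function(id)
    scan_sequence(prof, fam$sequences[[id]], 30, id = id)))
  path <- withr::local_tempfile(fileext = ".domtbl")
  write_domtbl(hits, path)
  back <- read_domtbl(path)
  expect_identical(back$protein_id, hits$protein_id)
  expect_identical(back$env_start, hits$env_start)
  expect_identical(back$env_end, hits$env_end)
  expect_equal(back$bit_score, hits$bit_score, tolerance = 0.05)
})

test_that("the E-value retention rule is strict at the cutoff", {
  hits <- data.frame(protein_id = c("p1", "p2", "p2", "p3"),
                     profile_name = "NAM",
                     full_seq_evalue = c(0.01, 1e-5, 0.5, 0.5),
                     bit_score = 10, domain_index = 1L,
                     domain_cond_evalue = c(0.01, 1e-5, 0.5, 0.5),
                     env_start = 1L, env_end = 10L, stringsAsFactors = FALSE)
  expect_identical(filter_hits(hits, 0.01), "p2")   # 0.01 exactly is excluded
  expect_identical(filter_hits(hits, 0.6), c("p1", "p2", "p3"))
  expect_identical(filter_hits(hits[hits$full_seq_evalue >= 0.01, ], 0.01),
                   character(0))
})

test_that("NT/CT partitioning follows the envelope rule", {
  seq300 <- strrep("A", 300)
  h1 <- data.frame(protein_id = "p", profile_name = "NAM",
                   full_seq_evalue = 1e-9, bit_score = 50, domain_index = 1L,
                   domain_cond_evalue = 1e-9, env_start = 5L, env_end = 160L)
  p <- split_nt_ct(seq300, h1, id = "p")
  expect_equal(unname(p$nt_region), c(1L, 160L))
  expect_equal(unname(p$ct_region), c(161L, 300L))

  h2 <- h1; h2$env_end <- 300L
  p2 <- split_nt_ct(seq300, h2, id = "p")
  expect_gt(p2$ct_region[1], p2$ct_region[2])   # empty CT allowed

  h3 <- rbind(h1, h1)
  h3$env_start <- c(5L, 160L); h3$env_end <- c(150L, 290L)
  h3$domain_index <- 1:2
  p3 <- split_nt_ct(strrep("A", 320), h3, id = "p")
  expect_equal(unname(p3$nt_region), c(1L, 290L))
  expect_equal(unname(p3$ct_region), c(291L, 320L))

  h4 <- h1; h4$env_end <- 500L
  expect_error(split_nt_ct(seq300, h4, id = "p"), "exceed")
})

test_that("subdomain anchors are located by exact match", {
  fam <- small_family(24)
  g <- fam$truth$gene_id[1]
  sd <- locate_subdomains(fam$sequences[[g]])
  expect_setequal(names(sd), c("A", "B", "C", "D", "E"))
  arch <- fam$architecture
  expect_equal(unname(sd$A["start"]), arch$leader_len + arch$anchor_at[["A"]])
})
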