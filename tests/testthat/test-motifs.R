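test_that("exact-match scanning finds planted motifs in the right regions", {
  seqs <- c(p1 = "AAAWDDYKWPHQEAAAHHH", p2 = "CCCCCCCCCCCCCCCCCCC")
  lib <- c("CT-10" = "WDDYKWPHQE", "NT-9" = "HHH")
  occ <- find_motif_occurrences(seqs, lib)
  expect_equal(nrow(occ), 2L)
  expect_equal(occ$start[occ$motif == "CT-10"], 4L)
  expect_identical(occ$region, c("CT", "NT"))
  # with region boundaries, coordinates are region-relative
  regions <- data.frame(protein_id = "p1", nt_start = 1L, nt_end = 3L,
                        ct_start = 4L, ct_end = 19L, stringsAsFactors = FALSE)
  occ2 <- find_motif_occurrences(seqs["p1"], lib["CT-10"], regions)
  expect_equal(occ2$start, 1L)
  expect_equal(occ2$abs_start, 4L)
})

test_that("MEME-dialect files round-trip and enforce the zoops contract", {
  seqs <- c(p1 = "AAKWDDYKWPHQEKKWDDYKWPHQEKK", p2 = "KWDDYKWPHQEK")
  occ <- find_motif_occurrences(seqs, c("CT-5" = "WDDYKWPHQE"))
  expect_equal(nrow(occ), 3L)
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme_text(occ, path)
  back <- read_meme(path)
  expect_identical(back[, c("motif", "protein_id", "start", "end", "region")],
                   occ[, c("motif", "protein_id", "start", "end", "region")])
  expect_warning(read_meme(path, mode = "zoops"), "zero-or-one")
  expect_error(read_meme(path, mode = "zoops", strict = TRUE), "zero-or-one")
  bad <- withr::local_tempfile()
  writeLines(c("MOTIF X width=5", "p1 notanumber 0"), bad)
  expect_error(read_meme(bad), "line 2")
})

test_that("presence matrix is binary with retained all-zero rows", {
  seqs <- c(p1 = "AAKWDDYKWPHQEKKWDDYKWPHQEKK", p2 = "KAAAK", p3 = "KWDDYKWPHQEK")
  lib <- c("CT-5" = "WDDYKWPHQE", "CT-6" = "YYYYYYY")
  occ <- find_motif_occurrences(seqs, lib)
  pm <- presence_matrix(occ, names(seqs), motifs = names(lib))
  expect_identical(pm["CT-5", ], c(p1 = 1L, p2 = 0L, p3 = 1L))
  expect_identical(sum(pm["CT-6", ]), 0L)   # motif with no sites kept
  # row sums equal distinct-protein recounts from the occurrence list
  for (m in rownames(pm))
    expect_equal(sum(pm[m, ]),
                 length(unique(occ$protein_id[occ$motif == m])))
  expect_error(presence_matrix(occ, c("p1", "p2")), "unknown")
})

test_that("motif classes respect the 10/50/90 percent boundaries exactly", {
  prots <- sprintf("p%02d", 1:20)
  asn <- data.frame(leaf = prots, subfamily = rep(c("a", "b"), each = 10),
                    stringsAsFactors = FALSE)
  pm <- matrix(0L, nrow = 4, ncol = 20,
               dimnames = list(c("m_sig", "m_low", "m_hi", "m_abs"), prots))
  pm["m_sig", 1:10] <- 1L                      # 100% in a -> signature
  pm["m_low", 1] <- 1L                         # exactly 10% in a -> present
  pm["m_hi", 1:9] <- 1L                        # exactly 90% in a -> present
  pm["m_abs", 11] <- 1L                        # 0% in a, 10% in b
  cls <- classify_motifs(pm, asn)
  expect_equal(cls$class["m_sig", "a"], "signature")
  expect_equal(cls$class["m_low", "a"], "present")
  expect_equal(cls$class["m_hi", "a"], "present")
  expect_equal(cls$class["m_sig", "b"], "absent")
  # specificity: reaches 10% in exactly one subfamily
  expect_equal(unname(cls$specific_to["m_low"]), "a")
  expect_equal(unname(cls$specific_to["m_abs"]), "b")
  expect_true(is.na(cls$specific_to["m_sig"]) ||
                cls$specific_to["m_sig"] == "a")
  # conserved: overall presence strictly above 50%
  pm2 <- rbind(m55 = c(rep(1L, 11), rep(0L, 9)),
               m50 = c(rep(1L, 10), rep(0L, 10)))
  colnames(pm2) <- prots
  cls2 <- classify_motifs(pm2, asn)
  expect_true(cls2$conserved["m55"])
  expect_false(cls2$conserved["m50"])
})

test_that("fraction 0.98 in one subfamily is a signature there", {
  prots <- sprintf("p%02d", 1:50)
  asn <- data.frame(leaf = prots, subfamily = "h", stringsAsFactors = FALSE)
  pm <- matrix(c(rep(1L, 49), 0L), nrow = 1,
               dimnames = list("NT-7", prots))
  cls <- classify_motifs(pm, asn)
  expect_equal(cls$class["NT-7", "h"], "signature")
})

test_that("motif occurrences map to subdomains by majority overlap", {
  sd <- list(p1 = list(B = c(start = 20L, end = 31L), C = c(start = 50L, end = 61L)))
  occ_on <- data.frame(motif = "NT-3", protein_id = "p1", region = "NT",
                       start = 50L, end = 61L, abs_start = 50L, abs_end = 61L,
                       score = 12, stringsAsFactors = FALSE)
  out <- map_to_subdomains(occ_on, sd)
  expect_equal(out$per_motif$subdomain, "C")
  occ_gap <- occ_on
  occ_gap$abs_start <- 37L; occ_gap$abs_end <- 46L   # centred between B and C
  expect_equal(map_to_subdomains(occ_gap, sd)$per_motif$subdomain,
               "between-subdomain")
  # majority over occurrences matches a per-occurrence recount
  occ_many <- do.call(rbind, lapply(1:10, function(i) {
    o <- occ_on
    if (i <= 4) { o$abs_start <- 37L; o$abs_end <- 46L }
    o
  }))
  mapped <- map_to_subdomains(occ_many, sd)
  recount <- names(sort(table(mapped$per_occurrence$subdomain),
                        decreasing = TRUE))[1]
  expect_equal(mapped$per_motif$subdomain, recount)
  # occurrences without coordinates are skipped with a warning
  occ_miss <- occ_on; occ_miss$protein_id <- "p9"
  expect_warning(map_to_subdomains(rbind(occ_on, occ_miss), sd), "skipped")
})

test_that("motif-trait association matches enumeration and its degenerate case", {
  prots <- sprintf("p%02d", 1:20)
  trait <- stats::setNames(rep(c(TRUE, FALSE), each = 10), prots)
  pm <- rbind(perfect = rep(c(1L, 0L), each = 10),
              everywhere = rep(1L, 20))
  colnames(pm) <- prots
  out <- associate_motif(pm, trait)
  expect_equal(out$p.value[out$motif == "perfect"],
               fisher_p_enum(10, 0, 0, 10), tolerance = 1e-9)
  expect_equal(out$p.value[out$motif == "everywhere"], 1)
  expect_error(associate_motif(pm, trait[1:5]), "undefined")
})

test_that("planted motif-trait associations are recovered across seeds", {
  for (sd in c(61, 62, 63)) {
    fam <- small_family(sd)
    occ <- find_motif_occurrences(fam$sequences[fam$truth$gene_id],
                                  fam$motif_library)
    pm <- presence_matrix(occ, fam$truth$gene_id,
                          motifs = names(fam$motif_library))
    trait <- stats::setNames(nzchar(fam$truth$responsive_pathogens),
                             fam$truth$gene_id)
    out <- associate_motif(pm, trait)
    expect_lt(out$q.value[out$motif == "CT-27"], 0.05)
  }
})
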