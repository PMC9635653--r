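#' Configuration for the synthetic hexaploid gene-family generator
#'
#' The generator emulates the structure of a NAC-like transcription-factor
#' family in an allohexaploid genome: homoeolog groups with members on
#' subgenomes A/B/D (occasionally an "unknown" chromosome U), tandem
#' inparalog duplicates on one chromosome, ortholog anchors to a diploid
#' reference nomenclature, eight phylogenetic subfamilies (a-h), and
#' shuffled-composition decoy proteins. Sequences are produced by mutating
#' a fixed planted NAM-consensus protein at per-site substitution counts
#' calibrated to the configured identities, with subdomain anchor motifs
#' kept intact so that identity, not alignment detail, carries the signal
#' the downstream rules consume.
#'
#' @param n_subfamilies number of subfamilies, labeled `a`.. (default 8).
#' @param n_anchor_orthologs number of anchored ortholog groups
#'   (default 60).
#' @param triad_rate probability a group is a full A/B/D triad
#'   (default 0.6).
#' @param inparalog_rate probability a group carries a tandem duplicate
#'   unit (default 0.15).
#' @param orphan_rate probability a group lacks an ortholog anchor
#'   (default 0.2).
#' @param identity_inparalog target percent identity of planted inparalog
#'   pairs; must exceed 80 (default 90).
#' @param identity_cross_group target percent identity between groups of a
#'   subfamily; must stay below 80 (default 60).
#' @param decoy_count number of shuffled non-NAC decoy sequences
#'   (default 20).
#' @param u_rate probability that one member of a multi-gene group sits on
#'   the "unknown" chromosome U (default 0.05).
#' @param responsive_rate probability a gene is planted
#'   pathogen-responsive (default 0.35).
#' @param grain_rate probability a gene is planted grain-specific
#'   (default 0.05).
#' @param seed integer seed; a fixed seed makes every output byte
#'   reproducible.
#' @return a validated `family_config` list.
#' @export
family_config <- function(n_subfamilies = 8, n_anchor_orthologs = 60,
                          triad_rate = 0.6, inparalog_rate = 0.15,
                          orphan_rate = 0.2, identity_inparalog = 90,
                          identity_cross_group = 60, decoy_count = 20,
                          u_rate = 0.05, responsive_rate = 0.35,
                          grain_rate = 0.05, seed = 1) {
  cfg <- list(n_subfamilies = as.integer(n_subfamilies),
              n_anchor_orthologs = as.integer(n_anchor_orthologs),
              triad_rate = triad_rate, inparalog_rate = inparalog_rate,
              orphan_rate = orphan_rate,
              identity_inparalog = identity_inparalog,
              identity_cross_group = identity_cross_group,
              decoy_count = as.integer(decoy_count), u_rate = u_rate,
              responsive_rate = responsive_rate, grain_rate = grain_rate,
              seed = as.integer(seed))
  probs <- c(triad_rate, inparalog_rate, orphan_rate, u_rate,
             responsive_rate, grain_rate)
  if (any(probs < 0 | probs > 1))
    stop_input("family_config(): rates must be probabilities in [0, 1]")
  if (!(identity_inparalog > 80))
    stop_input("family_config(): identity_inparalog must exceed 80")
  if (!(identity_cross_group < 80))
    stop_input("family_config(): identity_cross_group must be below 80")
  if (cfg$n_subfamilies < 1 || cfg$n_subfamilies > 8)
    stop_input("family_config(): n_subfamilies must be in 1..8")
  if (cfg$n_anchor_orthologs < 1 || cfg$decoy_count < 0)
    stop_input("family_config(): invalid counts")
  class(cfg) <- "family_config"
  cfg
}

# Subfamily labels in tree order: "b" is the root subfamily, the rest
# follow alphabetically.
subfamily_order <- function(n) {
  sf <- letters[seq_len(n)]
  c(intersect("b", sf), setdiff(sf, "b"))
}

# Fixed synthetic NAC protein architecture: a 12-aa leader, a 160-aa NAC
# core carrying the five subdomain anchors (A-D form the NAM region,
# positions 1..128 of the core; E opens the TAR side), and a 100-aa tail.
nac_architecture <- function() {
  anchors <- nac_subdomain_anchors()
  filler <- rep_len(strsplit("GKSEALRDTVNIQPFYHWMC", "")[[1]], 160)
  core <- filler
  at <- c(A = 5L, B = 36L, C = 64L, D = 100L, E = 135L)
  for (nm in names(at)) {
    a <- strsplit(anchors[[nm]], "")[[1]]
    core[at[nm]:(at[nm] + length(a) - 1L)] <- a
  }
  leader <- strsplit("MGSSSGGGDEVL", "")[[1]]
  tail <- rep_len(strsplit("QNPSTAYDGLEHKRVFWMIC", "")[[1]], 100)
  seq <- c(leader, core, tail)
  prot <- integer(0)
  for (nm in names(at))
    prot <- c(prot, (length(leader) + at[nm]):(length(leader) + at[nm] +
                                                 nchar(anchors[[nm]]) - 1L))
  list(sequence = seq, length = length(seq),
       leader_len = length(leader), core_len = 160L, nam_len = 128L,
       anchor_at = at, protected = prot,
       nam_range = c(length(leader) + 1L, length(leader) + 128L),
       ct_motif_offsets = c(sig = 181L, resp = 201L, grain = 221L))
}

# The planted motif library: the five subdomain anchors as conserved
# motifs, one CT signature 10-mer per subfamily, one CT motif tied to
# pathogen responsiveness and one tied to grain-specific expression.
planted_motif_library <- function(n_subfamilies = 8) {
  anchors <- nac_subdomain_anchors()
  sig <- c(a = "WDDYKWPHQE", b = "MQRTLDNEYK", c = "FPGHWSYVTR",
           d = "KENDLCWQYM", e = "RYHTPGWDFK", f = "QWMKEDHYPS",
           g = "TDFYHWKMRC", h = "PYEWKQHDTN")[seq_len(n_subfamilies)]
  lib <- c("NT-1" = unname(anchors["A"]), "NT-2" = unname(anchors["B"]),
           "NT-3" = unname(anchors["C"]), "NT-4" = unname(anchors["D"]),
           "CT-1" = unname(anchors["E"]),
           stats::setNames(unname(sig), paste0("CT-1", seq_along(sig) - 1L)),
           "CT-27" = "HQWDYKEMRT", "CT-23" = "GWYFHKQDEN")
  attr(lib, "subfamily_of") <- stats::setNames(names(sig),
                                               paste0("CT-1", seq_along(sig) - 1L))
  lib
}

# sample() guard: sample(x) on a length-1 integer samples 1:x
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1)

mutate_count <- function(chars, k, protected) {
  mutable <- setdiff(seq_along(chars), protected)
  k <- min(k, length(mutable))
  if (k <= 0) return(chars)
  aa <- aa_alphabet()
  pos <- sample(mutable, k)
  for (p in pos) chars[p] <- sample(setdiff(aa, chars[p]), 1)
  chars
}

#' Generate a synthetic hexaploid gene family with recorded ground truth
#'
#' See [family_config()] for the emulated structure. Every downstream
#' stage of the pipeline can be checked against the returned truth table.
#'
#' @param config a [family_config()].
#' @return list of class `nac_family_sim` with elements
#'   `sequences` (named character vector: genes then decoys),
#'   `nam_alignment` (NAM-region training alignment, one ungapped row per
#'   subfamily ancestor), `chrom_map`, `ortholog_table`, `anchor_meta`,
#'   `truth` (per gene: `gene_id`, `true_subfamily`, `true_group_id`,
#'   `true_subgenome`, `true_paralog_index`, `true_name`,
#'   `responsive_pathogens`, `grain_specific`, `planted_motifs`),
#'   `motif_library`, `config`.
#' @export
generate_family <- function(config = family_config()) {
  if (!inherits(config, "family_config"))
    stop_input("generate_family(): config must come from family_config()")
  arch <- nac_architecture()
  lib <- planted_motif_library(config$n_subfamilies)
  sig_of_sf <- attr(lib, "subfamily_of")
  panel <- nac_pathogen_panel()
  with_seed(config$seed, {
    sf_order <- subfamily_order(config$n_subfamilies)
    G <- max(config$n_subfamilies,
             round(config$n_anchor_orthologs / max(1 - config$orphan_rate, 0.05)))
    # every subfamily gets at least one group, the rest are spread uniformly
    sf_of_group <- c(sf_order, sample(sf_order, G - length(sf_order), replace = TRUE))
    sf_of_group <- sf_of_group[order(match(sf_of_group, sf_order))]
    anchor_pool <- sprintf("ONAC%03d", sample(setdiff(1:149, c(20, 26))))
    n_anchor_used <- 0L
    k_sf <- round(0.125 * arch$length)
    k_grp <- round((1 - config$identity_cross_group / 100) / 2 * arch$length)
    k_hom <- round(0.04 * arch$length)
    # per-copy branch length: every within-unit pair then stays at or above
    # the configured inparalog identity
    k_inp <- round((1 - config$identity_inparalog / 100) / 2 * arch$length)

    sf_ancestor <- list()
    for (sf in sf_order)
      sf_ancestor[[sf]] <- mutate_count(arch$sequence, k_sf, arch$protected)

    genes <- list()      # per-gene records
    groups <- list()     # per-group records (for the tree and truth)
    orphan_base <- 153L
    gene_counter <- 0L
    sf_group_index <- stats::setNames(rep(0L, length(sf_order)), sf_order)
    prev <- list(sf = NA_character_, anchor = NA_character_, shared = FALSE)

    for (gi in seq_len(G)) {
      sf <- sf_of_group[gi]
      sf_group_index[sf] <- sf_group_index[sf] + 1L
      group_id <- sprintf("%s.%03d", sf, sf_group_index[sf])
      orphan <- stats::runif(1) < config$orphan_rate
      if (orphan) {
        anchor <- NA_character_
        base <- as.character(orphan_base)
        orphan_base <- orphan_base + 1L
        group_number <- 1L
        prev <- list(sf = sf, anchor = NA_character_, shared = FALSE)
      } else {
        share <- !is.na(prev$anchor) && prev$sf == sf && !prev$shared &&
          stats::runif(1) < 0.15
        if (share) {
          anchor <- prev$anchor
          group_number <- 2L
          prev <- list(sf = sf, anchor = anchor, shared = TRUE)
        } else {
          n_anchor_used <- n_anchor_used + 1L
          anchor <- anchor_pool[n_anchor_used]
          group_number <- 1L
          prev <- list(sf = sf, anchor = anchor, shared = FALSE)
        }
        base <- sub("^ONAC", "", anchor)
      }
      triad <- stats::runif(1) < config$triad_rate
      sgs <- if (triad) c("A", "B", "D") else
        sort(sample(c("A", "B", "D"), sample(1:2, 1)))
      u_member <- length(sgs) >= 2 && stats::runif(1) < config$u_rate
      u_slot <- if (u_member) sample_one(seq_along(sgs)) else 0L
      inp <- stats::runif(1) < config$inparalog_rate
      inp_slot <- if (inp) sample_one(setdiff(seq_along(sgs), u_slot)) else 0L
      chrom <- sample(1:7, 1)
      grp_ancestor <- mutate_count(sf_ancestor[[sf]], k_grp, arch$protected)
      members <- list()
      for (si in seq_along(sgs)) {
        n_copies <- if (inp_slot > 0 && si == inp_slot) sample(2:3, 1) else 1L
        first_seq <- mutate_count(grp_ancestor, k_hom, arch$protected)
        for (ci in seq_len(n_copies)) {
          gene_counter <- gene_counter + 1L
          sg_eff <- if (si == u_slot) "U" else sgs[si]
          chars <- if (ci == 1L) first_seq else
            mutate_count(first_seq, k_inp, arch$protected)
          members[[length(members) + 1L]] <- list(
            gene_id = sprintf("g%04d%s", gene_counter, sg_eff),
            subgenome = sg_eff,
            chromosome = if (sg_eff == "U") 0L else chrom,
            paralog_index = if (n_copies > 1L) ci else NA_integer_,
            chars = chars)
        }
      }
      groups[[length(groups) + 1L]] <- list(
        group_id = group_id, subfamily = sf, anchor = anchor, base = base,
        group_number = group_number, members = members)
    }

    # names, responsiveness, motif planting, X noise --------------------
    truth_rows <- list()
    sequences <- character(0)
    off <- arch$ct_motif_offsets
    for (grp in groups) {
      for (mem in grp$members) {
        name <- paste0("TaNAC", grp$base, "-", mem$subgenome, grp$group_number,
                       if (!is.na(mem$paralog_index))
                         paste0("-", mem$paralog_index) else "")
        responsive <- character(0)
        if (stats::runif(1) < config$responsive_rate) {
          w <- c(0.5, 0.4, 0.4, 0.3, 0.3, 0.3)
          pick <- stats::runif(6) < w
          if (!any(pick)) pick[sample(6, 1, prob = w)] <- TRUE
          responsive <- panel$pathogen[pick]
        }
        grain <- stats::runif(1) < config$grain_rate
        chars <- mem$chars
        # a touch of missing data so alignment completeness is exercised
        nx <- stats::rbinom(1, 3, 0.08)
        if (nx > 0) {
          spots <- setdiff(seq_along(chars), arch$protected)
          spots <- setdiff(spots, off["sig"]:(off["grain"] + 9L))
          chars[sample(spots, nx)] <- "X"
        }
        plant <- function(chars, at, motif) {
          m <- strsplit(motif, "")[[1]]
          chars[at:(at + length(m) - 1L)] <- m
          chars
        }
        planted <- c("NT-1", "NT-2", "NT-3", "NT-4", "CT-1")
        sig_id <- names(sig_of_sf)[sig_of_sf == grp$subfamily]
        chars <- plant(chars, off["sig"], lib[[sig_id]])
        planted <- c(planted, sig_id)
        if (length(responsive) > 0 || stats::runif(1) < 0.02) {
          chars <- plant(chars, off["resp"], lib[["CT-27"]])
          planted <- c(planted, "CT-27")
        }
        if (grain || stats::runif(1) < 0.02) {
          chars <- plant(chars, off["grain"], lib[["CT-23"]])
          planted <- c(planted, "CT-23")
        }
        sequences[mem$gene_id] <- paste(chars, collapse = "")
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          gene_id = mem$gene_id, true_subfamily = grp$subfamily,
          true_group_id = grp$group_id, true_subgenome = mem$subgenome,
          true_paralog_index = mem$paralog_index, true_name = name,
          responsive_pathogens = join_csv_field(responsive),
          grain_specific = grain,
          planted_motifs = join_csv_field(planted),
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth_rows)

    # chromosome positions: per chromosome arm, a shuffled order of units
    # with inparalogs kept consecutive
    chrom_map <- do.call(rbind, lapply(groups, function(grp) {
      do.call(rbind, lapply(grp$members, function(mem) {
        data.frame(gene_id = mem$gene_id, subgenome = mem$subgenome,
                   chromosome = mem$chromosome,
                   position_rank = NA_integer_, stringsAsFactors = FALSE)
      }))
    }))
    unit_of <- paste0(truth$true_group_id, ".",
                      chrom_map$subgenome[match(truth$gene_id, chrom_map$gene_id)])
    for (key in unique(paste0(chrom_map$chromosome, chrom_map$subgenome))) {
      idx <- which(paste0(chrom_map$chromosome, chrom_map$subgenome) == key)
      units <- split(idx, unit_of[match(chrom_map$gene_id[idx], truth$gene_id)])
      units <- units[sample(length(units))]
      ordered <- unlist(lapply(units, function(u)
        u[order(truth$true_paralog_index[match(chrom_map$gene_id[u], truth$gene_id)],
                chrom_map$gene_id[u])]), use.names = FALSE)
      chrom_map$position_rank[ordered] <- seq_along(ordered)
    }

    ortholog_table <- do.call(rbind, lapply(groups, function(grp) {
      if (is.na(grp$anchor)) return(NULL)
      data.frame(gene_id = vapply(grp$members, `[[`, character(1), "gene_id"),
                 anchor_name = grp$anchor, stringsAsFactors = FALSE)
    }))
    anchors_used <- unique(ortholog_table$anchor_name)
    anchor_meta <- data.frame(anchor_name = anchors_used,
                              rice_chromosome = sample(1:12, length(anchors_used),
                                                       replace = TRUE),
                              stringsAsFactors = FALSE)
    anchor_meta$rice_rank <- stats::ave(seq_len(nrow(anchor_meta)),
                                        anchor_meta$rice_chromosome,
                                        FUN = seq_along)

    # decoys: shuffled real sequences (same residue composition, no domain)
    if (config$decoy_count > 0) {
      src <- sample(names(sequences), config$decoy_count, replace = TRUE)
      for (i in seq_len(config$decoy_count)) {
        ch <- strsplit(sequences[[src[i]]], "")[[1]]
        sequences[sprintf("DECOY%03d", i)] <- paste(sample(ch), collapse = "")
      }
    }

    nam_alignment <- vapply(sf_order, function(sf)
      paste(sf_ancestor[[sf]][arch$nam_range[1]:arch$nam_range[2]],
            collapse = ""), character(1))
    names(nam_alignment) <- paste0("SFANC_", sf_order)

    structure(list(sequences = sequences, nam_alignment = nam_alignment,
                   chrom_map = chrom_map, ortholog_table = ortholog_table,
                   anchor_meta = anchor_meta, truth = truth,
                   motif_library = lib, config = config,
                   architecture = arch),
              class = "nac_family_sim")
  })
}

#' @export
print.nac_family_sim <- function(x, ...) {
  cat("<nac_family_sim>", nrow(x$truth), "genes +", x$config$decoy_count,
      "decoys;", length(unique(x$truth$true_group_id)), "groups;",
      x$config$n_subfamilies, "subfamilies; seed", x$config$seed, "\n")
  invisible(x)
}

# base number encoded in a true name; bases >= `start` mark anchorless groups
name_base <- function(true_name) sub("^TaNAC(\\d+)-.*$", "\\1", true_name)

#' Generate the family tree implied by a synthetic truth table
#'
#' Rebuilds the canonical topology (subfamily "b" rooted first, groups as
#' monophyletic clades, inparalog units nested, one ortholog-anchor leaf
#' per anchored base and one `REF_<subfamily>` reference leaf per
#' subfamily) and attaches bootstrap supports: 100 everywhere at
#' `noise = 0`; with noise, each internal node is independently degraded
#' to a support below 70 with probability `noise`. Degradation draws are
#' made per node regardless of the noise level, so for a fixed seed the
#' set of degraded nodes is nested as noise increases.
#'
#' @param truth truth data.frame from [generate_family()].
#' @param noise support-degradation probability in \[0, 1\].
#' @param seed integer seed for the degradation draws.
#' @param reference_leaves include `REF_*` and anchor leaves
#'   (default TRUE).
#' @param start_number first anchorless base number used by the truth
#'   (default 153).
#' @return list with `tree` (a `phylo`), `reference_labels` (named vector
#'   leaf -> subfamily covering REF and anchor leaves).
#' @export
generate_tree <- function(truth, noise = 0, seed = 1, reference_leaves = TRUE,
                          start_number = 153) {
  if (!nrow(truth)) stop_input("generate_tree(): empty truth")
  if (noise < 0 || noise > 1) stop_input("generate_tree(): noise must be in [0, 1]")
  sf_order <- subfamily_order(length(unique(truth$true_subfamily)))
  sf_order <- intersect(sf_order, unique(truth$true_subfamily))
  with_seed(seed, {
    next_support <- function() {
      u <- stats::runif(1); v <- stats::runif(1)
      if (u < noise) as.character(30L + floor(40 * v)) else "100"
    }
    clade <- function(parts) {
      if (length(parts) == 1L) return(parts)
      # caterpillar, labeled with a freshly drawn support at each node
      out <- parts[length(parts)]
      for (i in rev(seq_len(length(parts) - 1L))) {
        out <- paste0("(", parts[i], ":1,", out, ":1)", next_support())
      }
      out
    }
    ref_labels <- character(0)
    sf_clades <- character(0)
    for (sf in sf_order) {
      tsub <- truth[truth$true_subfamily == sf, , drop = FALSE]
      base_clades <- character(0)
      for (b in unique(name_base(tsub$true_name))) {
        gsub_ <- tsub[name_base(tsub$true_name) == b, , drop = FALSE]
        grp_clades <- character(0)
        for (g in sort(unique(gsub_$true_group_id))) {
          mem <- gsub_[gsub_$true_group_id == g, , drop = FALSE]
          unit_clades <- character(0)
          for (sg in intersect(c("A", "B", "D", "U"), mem$true_subgenome)) {
            u <- mem[mem$true_subgenome == sg, , drop = FALSE]
            u <- u[order(u$true_paralog_index, u$gene_id), , drop = FALSE]
            unit_clades <- c(unit_clades, clade(u$gene_id))
          }
          grp_clades <- c(grp_clades, clade(unit_clades))
        }
        sub_clade <- clade(grp_clades)
        if (as.integer(b) < start_number && reference_leaves) {
          anchor_leaf <- paste0("ONAC", b)
          ref_labels[anchor_leaf] <- sf
          sub_clade <- paste0("(", anchor_leaf, ":1,", sub_clade, ":1)",
                              next_support())
        }
        base_clades <- c(base_clades, sub_clade)
      }
      body <- clade(base_clades)
      if (reference_leaves) {
        ref <- paste0("REF_", sf)
        ref_labels[ref] <- sf
        body <- paste0("(", ref, ":1,", body, ":1)", next_support())
      }
      sf_clades <- c(sf_clades, body)
    }
    body <- clade(sf_clades)
    if (!startsWith(body, "(")) body <- paste0("(", body, ");")
    nwk <- paste0(body, ";")
    nwk <- sub(";;$", ";", nwk)
    tree <- read_support_tree(text = nwk)
    list(tree = tree, reference_labels = ref_labels)
  })
}

#' Generate differential-expression and baseline tables for planted truth
#'
#' For every gene planted responsive to a pathogen, exactly one condition
#' (genotype x timepoint) receives `|log2fc| = effect + U(0, 0.5)` and an
#' adjusted p below 0.05; all other rows are drawn so they never pass both
#' thresholds (no leakage). Baseline tpm values are drawn so that planted
#' grain-specific genes are expressed (>= 0.1 tpm) only in grain;
#' responsive genes get higher baseline expression, a small fraction of
#' genes is not expressed in any organ.
#'
#' @param truth truth data.frame from [generate_family()].
#' @param pathogens pathogen/lifestyle panel (default
#'   [nac_pathogen_panel()]).
#' @param timepoints condition timepoints (default `T1`-`T3`).
#' @param genotypes genotypes (default `"S"`).
#' @param effect planted log2 fold-change magnitude; must exceed 1 for the
#'   planted responders to be recoverable (default 2.5).
#' @param seed integer seed.
#' @return list with `de_table` (`gene_id`, `pathogen`, `genotype`,
#'   `timepoint`, `log2fc`, `padj`) and `baseline_tpm` (`gene_id`,
#'   `organ`, `tpm`).
#' @export
generate_expression <- function(truth, pathogens = nac_pathogen_panel(),
                                timepoints = c("T1", "T2", "T3"),
                                genotypes = "S", effect = 2.5, seed = 1) {
  organs <- c("grain", "leaf", "root", "spike", "stem")
  with_seed(seed, {
    conds <- expand.grid(genotype = genotypes, timepoint = timepoints,
                         stringsAsFactors = FALSE)
    de <- list()
    for (i in seq_len(nrow(truth))) {
      g <- truth$gene_id[i]
      resp <- split_csv_field(truth$responsive_pathogens[i])
      for (p in pathogens$pathogen) {
        hot <- if (p %in% resp) sample(nrow(conds), 1) else 0L
        for (ci in seq_len(nrow(conds))) {
          if (ci == hot) {
            lfc <- sample(c(1, -1), 1, prob = c(0.7, 0.3)) *
              (effect + stats::runif(1, 0, 0.5))
            padj <- stats::runif(1, 1e-6, 0.049)
          } else if (stats::runif(1) < 0.2) {
            lfc <- sample(c(1, -1), 1) * stats::runif(1, 1.05, 3)
            padj <- stats::runif(1, 0.051, 1)
          } else {
            lfc <- stats::runif(1, -0.95, 0.95)
            padj <- stats::runif(1, 0, 1)
          }
          de[[length(de) + 1L]] <- data.frame(
            gene_id = g, pathogen = p, genotype = conds$genotype[ci],
            timepoint = conds$timepoint[ci], log2fc = lfc, padj = padj,
            stringsAsFactors = FALSE)
        }
      }
    }
    de_table <- do.call(rbind, de)
    base <- list()
    for (i in seq_len(nrow(truth))) {
      g <- truth$gene_id[i]
      responsive <- nzchar(truth$responsive_pathogens[i])
      if (truth$grain_specific[i]) {
        tpm <- stats::setNames(stats::runif(5, 0, 0.09), organs)
        tpm["grain"] <- max(0.15, stats::rlnorm(1, log(3), 0.5))
      } else if (stats::runif(1) < 0.02) {
        tpm <- stats::setNames(stats::runif(5, 0, 0.09), organs)
      } else {
        tpm <- stats::setNames(
          stats::rlnorm(5, meanlog = if (responsive) 1.2 else 0, sdlog = 1),
          organs)
      }
      base[[length(base) + 1L]] <- data.frame(
        gene_id = g, organ = organs, tpm = unname(tpm),
        stringsAsFactors = FALSE)
    }
    list(de_table = de_table, baseline_tpm = do.call(rbind, base))
  })
}
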