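# Shared fixture builders: tiny hand-built families for the naming rules
# and sequence helpers with exact, countable identities.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

base_protein <- function(len = 100) {
  paste(rep_len(AA20, len), collapse = "")
}

# substitute the residues at `at` with the next letter of the alphabet;
# each substitution changes the residue, so identity drops by length(at)
sub_at <- function(seq, at) {
  ch <- strsplit(seq, "")[[1]]
  for (p in at) ch[p] <- AA20[(match(ch[p], AA20) %% 20) + 1L]
  paste(ch, collapse = "")
}

ref_assignment <- function(tree, refs) {
  suppressWarnings(assign_subfamilies(tree, refs, support_threshold = 70))
}

# A/B/D triad anchored to one ortholog: expects names <prefix>048-A1/B1/D1
fixture_triad <- function() {
  b <- base_protein()
  seqs <- c(gA = b, gB = sub_at(b, 1:8), gD = sub_at(b, 9:16))
  tree <- read_support_tree(
    text = "((ONAC048:1,(gA:1,(gB:1,gD:1)100:1)100:1)100:1,REF_a:1)100;")
  list(
    tree = tree,
    assignment = ref_assignment(tree, c(ONAC048 = "a", REF_a = "a")),
    chrom_map = data.frame(gene_id = c("gA", "gB", "gD"),
                           subgenome = c("A", "B", "D"),
                           chromosome = 3L, position_rank = 1L,
                           stringsAsFactors = FALSE),
    ortholog_table = data.frame(gene_id = c("gA", "gB", "gD"),
                                anchor_name = "ONAC048",
                                stringsAsFactors = FALSE),
    sequences = seqs)
}

# singleton B gene plus a same-chromosome inparalog cluster sharing one
# anchor: expects <prefix>066-B1 and <prefix>066-A2-1..3
fixture_inparalog_cluster <- function() {
  b <- base_protein()
  b2 <- sub_at(b, seq(1, 69, by = 2))          # ~65% identity to b
  seqs <- c(gB1 = b, gA21 = b2, gA22 = sub_at(b2, seq(2, 16, by = 2)),
            gA23 = sub_at(b2, seq(18, 32, by = 2)))
  tree <- read_support_tree(
    text = "((ONAC066:1,(gB1:1,(gA21:1,(gA22:1,gA23:1)100:1)100:1)100:1)100:1,REF_e:1)100;")
  list(
    tree = tree,
    assignment = ref_assignment(tree, c(ONAC066 = "e", REF_e = "e")),
    chrom_map = data.frame(gene_id = c("gB1", "gA21", "gA22", "gA23"),
                           subgenome = c("B", "A", "A", "A"),
                           chromosome = c(4L, 5L, 5L, 5L),
                           position_rank = c(1L, 1L, 2L, 3L),
                           stringsAsFactors = FALSE),
    ortholog_table = data.frame(gene_id = c("gB1", "gA21", "gA22", "gA23"),
                                anchor_name = "ONAC066",
                                stringsAsFactors = FALSE),
    sequences = seqs)
}

# anchorless B+D pair joined by a chromosome-U gene: with start_number 158
# expects <prefix>158-U1 / -B1 / -D1
fixture_u_rule <- function() {
  b <- base_protein()
  seqs <- c(gB = b, gD = sub_at(b, 1:8), gU = sub_at(b, 9:16))
  tree <- read_support_tree(
    text = "((gU:1,(gB:1,gD:1)100:1)100:1,REF_d:1)100;")
  list(
    tree = tree,
    assignment = ref_assignment(tree, c(REF_d = "d")),
    chrom_map = data.frame(gene_id = c("gB", "gD", "gU"),
                           subgenome = c("B", "D", "U"),
                           chromosome = c(5L, 5L, 0L),
                           position_rank = 1L, stringsAsFactors = FALSE),
    ortholog_table = data.frame(gene_id = character(0),
                                anchor_name = character(0),
                                stringsAsFactors = FALSE),
    sequences = seqs)
}

run_naming <- function(fx, start_number = 153) {
  groups <- group_homoeologs(fx$tree, fx$assignment, fx$chrom_map,
                             fx$ortholog_table, fx$sequences,
                             support_threshold = 70, identity_threshold = 80,
                             anchor_meta = fx$anchor_meta)
  assign_names(groups, fx$tree, fx$assignment, start_number = start_number)
}

# small fast generator configuration for repeated tests
small_family <- function(seed, ...) {
  generate_family(family_config(seed = seed, n_anchor_orthologs = 12,
                                decoy_count = 5, ...))
}

# independent two-sided Fisher p by hypergeometric enumeration
fisher_p_enum <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# brute-force window scan reimplementation used as the oracle
scan_oracle <- function(prof, seq, thr) {
  W <- prof$width
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  sc <- vapply(seq_len(L - W + 1L), function(s) {
    sum(vapply(seq_len(W), function(k) {
      r <- ch[s + k - 1L]
      if (r %in% rownames(prof$scores)) prof$scores[r, k] else 0
    }, numeric(1)))
  }, numeric(1))
  cand <- order(sc, decreasing = TRUE)
  cand <- cand[sc[cand] >= thr]
  taken <- rep(FALSE, L); starts <- integer(0)
  for (s in cand) {
    if (!any(taken[s:(s + W - 1L)])) { taken[s:(s + W - 1L)] <- TRUE
      starts <- c(starts, s) }
  }
  sort(starts)
}

# exact Moses null by full enumeration over all rank assignments
moses_p_enum <- function(control, experimental, trim_h) {
  nC <- length(control); N <- nC + length(experimental)
  pooled <- c(control, experimental)
  pos <- order(order(pooled))
  cpos <- sort(pos[seq_len(nC)])
  keep <- cpos[(trim_h + 1):(nC - trim_h)]
  obs <- max(keep) - min(keep) + 1L
  spans <- apply(utils::combn(N, nC), 2, function(s) {
    s <- sort(s)[(trim_h + 1):(nC - trim_h)]
    max(s) - min(s) + 1L
  })
  mean(spans <= obs)
}

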