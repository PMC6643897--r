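# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately naive (per-column loops, all-pairs enumeration):
# they must stay independent of the vectorized implementation paths.

# Build a gene_alignment from named sequence strings.
make_aln <- function(seqs, gene_id = "toy") {
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(seqs)
  orthopop:::new_gene_alignment(gene_id, orthopop::normalize_residues(mat))
}

# Write sequences to a temporary FASTA file; returns the path.
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]])))
  writeLines(lines, path)
  path
}

# Random complete-data alignment for one or more species.
random_aln <- function(n_seq, L, gene_id = "rnd",
                       prefix = "acc", p_var = 0.2) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(anc, each = n_seq), nrow = n_seq)
  nvar <- rbinom(1, L, p_var)
  for (j in sample.int(L, nvar)) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), anc[j]), 1)
    carriers <- sample.int(n_seq, sample.int(n_seq - 1L, 1))
    mat[carriers, j] <- alt
  }
  rownames(mat) <- sprintf("%s%02d", prefix, seq_len(n_seq))
  orthopop:::new_gene_alignment(gene_id, mat)
}

# ---- oracles -------------------------------------------------------------

# pi via brute-force mean pairwise Hamming distance per site (complete data).
oracle_pi_allpairs <- function(mat) {
  n <- nrow(mat); L <- ncol(mat)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(mat[i, ] != mat[j, ]) / L
    np <- np + 1
  }
  tot / np
}

# S and L for one species by naive per-column recount.
oracle_site_counts <- function(mat, accs) {
  S <- 0L; L <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[accs, j]
    if (any(col == "-")) next
    calls <- col[col %in% c("A", "C", "G", "T")]
    if (length(calls) < 2) next
    L <- L + 1L
    if (length(unique(calls)) >= 2) S <- S + 1L
  }
  list(S = S, L = L)
}

# Exhaustive per-column trans-specific enumeration.
oracle_trans_specific <- function(mat, panel) {
  hits <- list()
  for (j in seq_len(ncol(mat))) {
    pairs <- list()
    for (s in unique(panel$species)) {
      col <- mat[intersect(panel$accession[panel$species == s], rownames(mat)), j]
      if (any(col == "-")) next
      calls <- col[col %in% c("A", "C", "G", "T")]
      if (length(calls) < 2) next
      u <- sort(unique(calls))
      if (length(u) == 2) pairs[[s]] <- paste(u, collapse = "/")
    }
    tab <- table(unlist(pairs))
    for (pr in names(tab)[tab >= 2]) {
      sp <- sort(names(pairs)[unlist(pairs) == pr])
      hits[[length(hits) + 1L]] <- list(column = j - 1L, pair = pr, species = sp)
    }
  }
  hits
}

# Step-by-step Tajima-Nei evaluation (spreadsheet style, scalar loops).
oracle_tajima_nei <- function(s1, s2) {
  B <- c("A", "C", "G", "T")
  keep <- s1 %in% B & s2 %in% B
  s1 <- s1[keep]; s2 <- s2[keep]
  n <- length(s1)
  p <- sum(s1 != s2) / n
  g <- sapply(B, function(b) (sum(s1 == b) + sum(s2 == b)) / (2 * n))
  if (p == 0) return(list(p = 0, g = g, b = NA, d = 0))
  h <- 0
  x <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    xij <- sum((s1 == B[i] & s2 == B[j]) | (s1 == B[j] & s2 == B[i])) / n
    x[paste(B[i], B[j], sep = "/")] <- xij
    if (xij > 0) h <- h + unname(xij^2 / (2 * g[i] * g[j]))
  }
  b <- 0.5 * (1 - sum(g^2) + p^2 / h)
  list(p = p, g = g, x = x, h = h, b = b,
       d = if (p < b) -b * log(1 - p / b) else NA_real_)
}

# Two-species, two-population summary simulation helper for HKA tests:
# builds an hka_input from simulated gene alignments at a split time tau.
sim_hka_dataset <- function(seed, n_loci = 10L, n = 10L, theta = 0.003,
                            L = 1000L, tau = 5) {
  cfg <- sim_config(species = c("A", "B"), n = c(n, n),
                    theta = c(theta, theta),
                    tree = sprintf("(A:%g,B:%g);", tau, tau),
                    n_genes = n_loci, gene_length = rep(L, n_loci),
                    theta_ref = theta, theta_anc = theta,
                    missing_gene_prob = 0, mask_prob = 0, seed = seed)
  panel <- species_panel(c(sprintf("A_%02d", 1:n), sprintf("B_%02d", 1:n)),
                        rep(c("A", "B"), each = n))
  obs <- lapply(seq_len(n_loci), function(i) {
    g <- simulate_gene(cfg, i)$aln
    prof <- profile_sites(g, panel)
    sA <- species_site_table(prof, "A")
    sB <- species_site_table(prof, "B")
    cA <- prof$counts[["A"]]; cB <- prof$counts[["B"]]
    D <- sum(1 - colSums(cA * cB) / (prof$n_acc[["A"]] * prof$n_acc[["B"]]))
    c(sA$S, sB$S, D, g$length)
  })
  m <- do.call(rbind, obs)
  hka_input(S_A = m[, 1], S_B = m[, 2], D = m[, 3], L = m[, 4],
            n_A = n, n_B = n)
}

toy_panel_abc <- function() {
  species_panel(
    c("a1", "a2", "a3", "b1", "b2", "b3", "c1", "c2", "c3"),
    rep(c("spA", "spB", "spC"), each = 3))
}
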