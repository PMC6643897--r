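# Fixed 60-bp toy pair used for the formula-walkthrough comparison: composed
# so base composition is skewed and all mismatch classes appear.
tn_fixture <- function() {
  s1 <- strsplit("AAAAACCCCCGGGGGTTTTTAAAAACCCCCGGGGGTTTTTAAAAACCCCCGGGGGTTTTT", "")[[1]]
  s2 <- strsplit("AAAAGCCCCAGGGGCTTTTGAAAATCCCCTGGGGATTTACAAAAACCCCCGGGGGTTTTT", "")[[1]]
  list(s1 = s1, s2 = s2)
}

test_that("tajima_nei_pair matches the step-by-step walkthrough oracle", {
  fx <- tn_fixture()
  tn <- tajima_nei_pair(fx$s1, fx$s2)
  orc <- oracle_tajima_nei(fx$s1, fx$s2)
  expect_equal(tn$p, orc$p, tolerance = 1e-15)
  expect_equal(unname(tn$g), unname(orc$g), tolerance = 1e-15)
  expect_equal(unname(tn$x), unname(orc$x), tolerance = 1e-15)
  expect_equal(tn$h, orc$h, tolerance = 1e-15)
  expect_equal(tn$b, orc$b, tolerance = 1e-15)
  expect_equal(tn$d, orc$d, tolerance = 1e-15)
  expect_true(tn$defined)
  expect_gte(tn$d, tn$p)  # correction never shrinks below p

  # and on random pairs with missing data (pairwise deletion)
  set.seed(51)
  for (rep in 1:10) {
    a <- sample(c("A", "C", "G", "T", "N", "-"), 200, replace = TRUE,
                prob = c(0.3, 0.25, 0.2, 0.15, 0.05, 0.05))
    b <- a
    flip <- runif(200) < 0.08
    b[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
    tn <- tajima_nei_pair(a, b)
    orc <- oracle_tajima_nei(a, b)
    expect_equal(tn$d, orc$d, tolerance = 1e-13)
    # symmetry
    expect_equal(tajima_nei_pair(b, a)$d, tn$d, tolerance = 1e-13)
  }
})

test_that("tajima_nei_pair handles identity, JC limit and degenerate input", {
  s <- strsplit(strrep("ACGT", 15), "")[[1]]
  expect_equal(tajima_nei_pair(s, s)$d, 0)

  # uniform composition + uniform mismatch spectrum reduces to Jukes-Cantor:
  # 12 mismatch sites covering all ordered base pairs + 12 matched sites
  b4 <- c("A", "C", "G", "T")
  mm <- expand.grid(i = b4, j = b4, stringsAsFactors = FALSE)
  mm <- mm[mm$i != mm$j, ]
  s1 <- c(mm$i, rep(b4, 3))
  s2 <- c(mm$j, rep(b4, 3))
  tn <- tajima_nei_pair(s1, s2)
  p <- tn$p
  expect_equal(p, 0.5)
  expect_equal(tn$b, 0.75, tolerance = 1e-12)
  expect_equal(tn$d, -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)

  # all-N columns: no comparable site -> undefined flag, not an exception
  und <- tajima_nei_pair(rep("N", 10), rep("A", 10))
  expect_false(und$defined)
  expect_true(is.na(und$d))
  # saturated pair (p >= b) -> flagged undefined, never clamped
  sat <- tajima_nei_pair(rep(c("A", "C", "G", "T"), 10),
                         rep(c("C", "A", "T", "G"), 10))
  expect_false(sat$defined)
})

test_that("d is monotone in p at fixed composition", {
  set.seed(52)
  base <- rep(c("A", "C", "G", "T"), each = 30)
  ds <- vapply(c(4, 8, 16, 24), function(k) {
    other <- base
    # balanced complementary swaps keep composition roughly fixed
    idx <- seq_len(k)
    other[idx] <- chartr("ACGT", "GTAC", base[idx])
    tajima_nei_pair(base, other)$d
  }, 0)
  expect_true(all(diff(ds) > 0))
})

test_that("between-group distance averages pairs and ignores labels", {
  panel <- species_panel(c("a1", "a2", "b1", "b2"),
                         c("spA", "spA", "spB", "spB"))
  # two species of one identical accession each -> 0
  p1 <- species_panel(c("a1", "b1"), c("spA", "spB"))
  aln1 <- make_aln(c(a1 = strrep("ACGT", 10), b1 = strrep("ACGT", 10)))
  expect_equal(between_group_distance(aln1, p1, "spA", "spB")$d, 0)

  set.seed(53)
  aln <- random_aln(4, 120)
  rownames(aln$matrix) <- panel$accession
  aln$accessions <- panel$accession
  bg <- between_group_distance(aln, panel, "spA", "spB")
  expect_equal(bg$n_pairs, 4L)
  manual <- mean(c(
    tajima_nei_pair(aln$matrix["a1", ], aln$matrix["b1", ])$d,
    tajima_nei_pair(aln$matrix["a1", ], aln$matrix["b2", ])$d,
    tajima_nei_pair(aln$matrix["a2", ], aln$matrix["b1", ])$d,
    tajima_nei_pair(aln$matrix["a2", ], aln$matrix["b2", ])$d))
  expect_equal(bg$d, manual, tolerance = 1e-14)

  # relabeling accessions does not change the between-group mean
  m2 <- aln$matrix
  rownames(m2) <- c("a2", "a1", "b2", "b1")
  aln2 <- orthopop:::new_gene_alignment("r", m2)
  expect_equal(between_group_distance(aln2, panel, "spA", "spB")$d, bg$d)
})

test_that("distance_matrix is symmetric, zero-diagonal, order invariant", {
  set.seed(54)
  panel <- toy_panel_abc()
  aln <- random_aln(9, 150)
  rownames(aln$matrix) <- panel$accession
  aln$accessions <- panel$accession
  dm <- distance_matrix(aln, panel, level = "species")
  expect_equal(dm$d, t(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, 3))
  # permuting input accession order leaves the species matrix unchanged
  perm <- sample(9)
  alnp <- orthopop:::new_gene_alignment("p", aln$matrix[perm, , drop = FALSE])
  dmp <- distance_matrix(alnp, panel, level = "species")
  expect_equal(dmp$d, dm$d)
  # accession-level has matching labels
  dma <- distance_matrix(aln, panel, level = "accession")
  expect_equal(dma$labels, aln$accessions)
  # single species -> 1x1 zero matrix
  p1 <- species_panel(c("a1", "a2", "a3"), rep("spA", 3))
  sub <- orthopop:::new_gene_alignment("s", aln$matrix[1:3, , drop = FALSE])
  dm1 <- distance_matrix(sub, p1, level = "species")
  expect_equal(dim(dm1$d), c(1L, 1L))
  expect_equal(unname(dm1$d[1, 1]), 0)
})

test_that("nj_tree recovers additive 4-taxon matrices exactly", {
  # tree ((A:2,B:3):1,(C:4,D:5)): additive distances
  dAB <- 5; dCD <- 9
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- dAB
  d["C", "D"] <- d["D", "C"] <- dCD
  d["A", "C"] <- d["C", "A"] <- 2 + 1 + 4
  d["A", "D"] <- d["D", "A"] <- 2 + 1 + 5
  d["B", "C"] <- d["C", "B"] <- 3 + 1 + 4
  d["B", "D"] <- d["D", "B"] <- 3 + 1 + 5
  nwk <- nj_tree(d)
  ph <- attr(nwk, "phylo")
  # patristic distances reproduce the additive input exactly
  cp <- ape::cophenetic.phylo(ph)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cp, d, tolerance = 1e-12)
  # topology: A,B are sisters (split AB|CD)
  expect_true(ape::is.monophyletic(ape::unroot(ph), c("A", "B")))

  # ultrametric matrix with clear structure: correct sister pairing
  u <- matrix(c(0, 2, 8, 8,
                2, 0, 8, 8,
                8, 8, 0, 4,
                8, 8, 4, 0), 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  ph2 <- attr(nj_tree(u), "phylo")
  expect_true(ape::is.monophyletic(ape::unroot(ph2), c("A", "B")))
  expect_true(ape::is.monophyletic(ape::unroot(ph2), c("C", "D")))

  # 3 taxa: the unique unrooted topology, branch lengths solve the system
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  ph3 <- attr(nj_tree(d3), "phylo")
  cp3 <- ape::cophenetic.phylo(ph3)[c("X", "Y", "Z"), c("X", "Y", "Z")]
  expect_equal(cp3, d3, tolerance = 1e-12)

  # undefined entries error names the offending pair
  dm <- structure(list(labels = LETTERS[1:4], d = d,
                       undefined = matrix(FALSE, 4, 4, dimnames = dimnames(d)),
                       level = "species"), class = "distance_matrix")
  dm$undefined["A", "C"] <- dm$undefined["C", "A"] <- TRUE
  expect_error(nj_tree(dm), "A vs C", class = "orthopop_domain_error")
  expect_error(nj_tree(d[1:2, 1:2]), class = "orthopop_input_error")
})

test_that("simulated divergence rank order follows split-time order", {
  set.seed(55)
  cfg <- sim_config(species = c("A", "B", "C"), n = c(6L, 6L, 6L),
                    theta = rep(0.003, 3),
                    tree = "((A:2,B:2):8,C:10);",
                    n_genes = 12L, gene_length = rep(800L, 12),
                    theta_ref = 0.003, missing_gene_prob = 0, mask_prob = 0,
                    seed = 77L)
  sim <- simulate_panel(cfg)
  cc <- concatenate(sim$genes, sim$panel, min_presence = 2L)
  dm <- distance_matrix(cc, sim$panel, level = "species")
  expect_lt(dm$d["A", "B"], dm$d["A", "C"])
  expect_lt(dm$d["A", "B"], dm$d["B", "C"])
})
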