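test_that("sim_config validates and stores the stated world", {
  cfg <- sim_config(n_genes = 3L, seed = 5L)
  expect_s3_class(cfg, "sim_config")
  expect_equal(length(cfg$species), 8L)
  expect_true(all(cfg$theta >= 0.0011 & cfg$theta <= 0.004))
  expect_error(sim_config(species = c("A", "B"), n = c(2L, 2L),
                          theta = c(-0.1, 0.1), tree = "(A:1,B:1);"),
               class = "orthopop_domain_error")
  expect_error(sim_config(species = c("A", "B"), n = c(2L, 2L),
                          theta = c(0.001, 0.001), tree = "(A:1,C:1);"),
               class = "orthopop_input_error")
  expect_error(sim_config(species = "A", n = 2L, theta = 0.001,
                          missing_gene_prob = 1.5),
               class = "orthopop_domain_error")
})

test_that("theta = 0 everywhere yields identical sequences", {
  cfg <- sim_config(species = c("A", "B"), n = c(4L, 4L), theta = c(0, 0),
                    tree = "(A:2,B:2);", n_genes = 2L,
                    gene_length = rep(100L, 2), theta_anc = 0,
                    missing_gene_prob = 0, mask_prob = 0, seed = 81L)
  g <- simulate_gene(cfg, 1L)
  expect_equal(nrow(unique(g$aln$matrix)), 1L)
  expect_equal(nrow(g$truth$mutations), 0L)
})

test_that("same seed gives byte-identical outputs; gene streams are independent", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- sim_config(n_genes = 2L, seed = 11L)
  simulate_panel(cfg, d1)
  simulate_panel(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # per-gene streams: gene 2 alone reproduces gene 2 of the full run,
  # so one gene's stream never alters another's output
  full <- simulate_panel(cfg)
  solo <- simulate_gene(cfg, 2L)
  expect_identical(solo$aln$matrix, full$genes[[2]]$matrix)
})

test_that("masking rate 1 yields all-N rows and downstream empty-data errors", {
  cfg <- sim_config(species = "A", n = 4L, theta = 0.003, n_genes = 1L,
                    gene_length = c(60L, 60L), theta_ref = 0.003,
                    missing_gene_prob = 0, mask_prob = 1, seed = 82L)
  g <- simulate_gene(cfg, 1L)
  expect_true(any(g$aln$matrix == "N"))
  # fully masked alignment exercises the empty-data path
  aln <- g$aln
  aln$matrix[] <- "N"
  panel <- species_panel(rownames(aln$matrix), rep("A", 4))
  expect_error(nucleotide_diversity_pi(profile_sites(aln, panel), "A"),
               class = "orthopop_empty_error")
})

test_that("missing-gene process drops accessions that concatenate re-pads", {
  cfg <- sim_config(species = c("A", "B"), n = c(6L, 6L), theta = c(0.002, 0.002),
                    tree = "(A:3,B:3);", n_genes = 8L, gene_length = rep(200L, 8),
                    missing_gene_prob = 0.4, mask_prob = 0, seed = 83L)
  sim <- simulate_panel(cfg)
  n_rows <- vapply(sim$genes, function(g) length(g$accessions), 0L)
  expect_true(any(n_rows < 12L))
  dropped_total <- sum(vapply(sim$truths, function(tr)
    length(tr$missing_accessions), 0L))
  expect_equal(sum(n_rows) + dropped_total, 12L * 8L)
  cc <- concatenate(sim$genes, sim$panel, min_presence = 1L)
  expect_equal(nrow(cc$matrix), 12L)
})

test_that("simulator matches Watterson's closed form E[S] = theta a_n L", {
  # single species, n=10, L=1000, theta=0.003/bp; 300 replicate genes
  n_rep <- 300L
  cfg <- sim_config(species = "A", n = 10L, theta = 0.003,
                    n_genes = n_rep, gene_length = rep(1000L, n_rep),
                    theta_ref = 0.003, missing_gene_prob = 0, mask_prob = 0,
                    seed = 84L)
  panel <- species_panel(sprintf("A_%02d", 1:10), rep("A", 10))
  S <- vapply(seq_len(n_rep), function(i) {
    g <- simulate_gene(cfg, i)$aln
    species_site_table(profile_sites(g, panel), "A")$S
  }, 0L)
  expected <- 0.003 * harmonic_numbers(10)$a * 1000
  se <- sd(S) / sqrt(n_rep)
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("cross-species divergence matches E[d] = theta (tau + 1)", {
  # two species at tau = 2, one lineage each: 200 replicate genes
  n_rep <- 200L
  cfg <- sim_config(species = c("A", "B"), n = c(2L, 2L), theta = c(0.003, 0.003),
                    tree = "(A:2,B:2);", n_genes = n_rep,
                    gene_length = rep(1000L, n_rep), theta_ref = 0.003,
                    missing_gene_prob = 0, mask_prob = 0, seed = 85L)
  d <- vapply(seq_len(n_rep), function(i) {
    g <- simulate_gene(cfg, i)$aln
    mean(g$matrix[startsWith(rownames(g$matrix), "A"), ][1, ] !=
           g$matrix[startsWith(rownames(g$matrix), "B"), ][1, ])
  }, 0)
  expected <- 0.003 * (2 + 1)
  se <- sd(d) / sqrt(n_rep)
  expect_lt(abs(mean(d) - expected), 3 * se)
})

test_that("ancestral_sharing_mode rescales splits and tags shared truth", {
  cfg <- sim_config(n_genes = 3L, seed = 86L)
  expect_identical(ancestral_sharing_mode(cfg, enabled = FALSE), cfg)
  cfg2 <- ancestral_sharing_mode(cfg, split_time = 0.05, theta_anc_factor = 3)
  ntip <- length(cfg2$tree$tip.label)
  internal <- cfg2$node_times[(ntip + 1):length(cfg2$node_times)]
  expect_equal(min(internal[internal > 0]), 0.05, tolerance = 1e-9)
  expect_equal(cfg2$theta_anc, 3 * cfg$theta_ref)

  # truth-tagged recovery: detection finds >= 80% of truth-marked shared sites
  sim <- simulate_panel(cfg2)
  profs <- lapply(sim$genes, profile_sites, panel = sim$panel)
  loci <- detect_trans_specific(profs, sim$panel)
  truth <- do.call(rbind, lapply(sim$truths, function(tr) {
    m <- tr$mutations[tr$mutations$shared, , drop = FALSE]
    if (nrow(m)) data.frame(gene_id = tr$gene_id, column = m$column) else NULL
  }))
  expect_gt(nrow(truth), 0L)
  found <- paste(loci$gene_id, loci$column)
  hit <- mean(paste(truth$gene_id, truth$column) %in% found)
  expect_gte(hit, 0.8)
})

test_that("jc mode produces usable alignments under recurrent substitution", {
  cfg <- sim_config(species = c("A", "B"), n = c(5L, 5L), theta = c(0.01, 0.01),
                    tree = "(A:8,B:8);", n_genes = 2L, gene_length = rep(400L, 2),
                    theta_ref = 0.01, sites = "jc",
                    missing_gene_prob = 0, mask_prob = 0, seed = 87L)
  g <- simulate_gene(cfg, 1L)
  expect_equal(ncol(g$aln$matrix), 400L)
  panel <- species_panel(rownames(g$aln$matrix),
                         sub("_.*", "", rownames(g$aln$matrix)))
  bg <- between_group_distance(g$aln, panel, "A", "B")
  expect_true(bg$d > 0)
})
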