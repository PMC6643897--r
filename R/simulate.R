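## synthetic_data: multispecies-coalescent simulator with known truth.
## Time is measured in coalescent units of 2N_ref generations; theta per bp
## is 4*N*mu. Species s has relative population size theta[s]/theta_ref, so
## its within-species expected segregating sites follow E[S] = theta_s a_n L
## while mutations are placed at rate theta_ref/2 per site per unit time on
## every branch. Expected cross-species pairwise divergence for a split at
## tau (with ancestral relative size 1) is theta_ref (tau + 1) per site.

default_species <- c("Gcanescens", "Gcyrtoloba", "Gfalcata", "Gmax",
                     "Gsoja", "Gstenophita", "Gsyndetika", "Gtomentella")

## Ultrametric default species tree (coalescent units). Split depths chosen
## so expected pairwise divergences theta_ref*(tau+1) with theta_ref=0.003
## span ~0.008-0.048 per bp: sister annuals split at 1.7, the deepest
## annual/perennial split at 15.
default_species_tree <- function() {
  paste0("((Gmax:1.7,Gsoja:1.7):13.3,",
         "((((Gcanescens:5.3,Gsyndetika:5.3):2.0,Gtomentella:7.3):3.0,",
         "(Gcyrtoloba:10.3,Gstenophita:10.3):0.3):3.4,Gfalcata:14.0):1.0);")
}

#' Simulation configuration for the multispecies coalescent generator
#'
#' Defaults describe an eight-species panel patterned on a multi-accession
#' legume ortholog study: 10-15 accessions per species, per-species theta
#' between 0.0011 and 0.0040 per bp, an ultrametric species tree whose
#' expected between-species divergences span roughly 0.008-0.048 per bp,
#' 52 genes of 500-1500 bp, and light missing-data structure (3% chance an
#' accession lacks a gene entirely, 5% chance of an N-masked segment).
#'
#' @param species character vector of species names.
#' @param n integer vector of accession counts per species.
#' @param theta per-species theta per bp (drives relative population sizes).
#' @param tree Newick string or `ape` `phylo`, ultrametric, tips = species;
#'   branch lengths in coalescent units of `2N_ref` generations.
#' @param n_genes number of loci.
#' @param gene_length either a length-2 range (per-gene lengths drawn
#'   uniformly) or a vector of `n_genes` lengths.
#' @param theta_ref reference theta per bp: the mutation-rate scale
#'   (default 0.003).
#' @param theta_anc theta of every ancestral population (default
#'   `theta_ref`).
#' @param missing_gene_prob per accession-gene probability the accession is
#'   absent from the gene's FASTA (default 0.03).
#' @param mask_prob per accession-gene probability of an N-masked contiguous
#'   segment covering 5-30% of the gene (default 0.05).
#' @param sites `"infinite"` (default; each mutation a fresh column, clean
#'   truth bookkeeping) or `"jc"` (finite-sites Jukes-Cantor, exercises the
#'   distance module under recurrent substitution).
#' @param base_freq ancestral base frequencies (default uniform).
#' @param seed RNG seed; all randomness derives from it.
#' @return a `sim_config` list (with the parsed tree and node split times).
#' @export
sim_config <- function(species = default_species,
                       n = c(15L, 12L, 12L, 15L, 12L, 12L, 10L, 12L),
                       theta = c(0.0040, 0.0032, 0.0027, 0.0011,
                                 0.0022, 0.0033, 0.0031, 0.0016),
                       tree = default_species_tree(),
                       n_genes = 52L,
                       gene_length = c(500L, 1500L),
                       theta_ref = 0.003,
                       theta_anc = theta_ref,
                       missing_gene_prob = 0.03,
                       mask_prob = 0.05,
                       sites = c("infinite", "jc"),
                       base_freq = rep(0.25, 4),
                       seed = 1L) {
  sites <- match.arg(sites)
  if (length(n) != length(species) || length(theta) != length(species)) {
    op_input_error("species, n and theta must have equal lengths")
  }
  if (any(theta < 0) || theta_ref <= 0 || theta_anc < 0) {
    op_domain_error("theta values must be non-negative (theta_ref > 0)")
  }
  if (any(n < 1) || n_genes < 1) op_domain_error("n and n_genes must be >= 1")
  if (missing_gene_prob < 0 || missing_gene_prob > 1 ||
        mask_prob < 0 || mask_prob > 1) {
    op_domain_error("probabilities must lie in [0, 1]")
  }
  if (abs(sum(base_freq) - 1) > 1e-8 || any(base_freq < 0)) {
    op_domain_error("base_freq must be a probability vector of length 4")
  }
  if (length(species) == 1L) {
    ph <- NULL
    node_times <- NULL
  } else {
    ph <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
    if (!setequal(ph$tip.label, species)) {
      op_input_error("tree tip labels must match the species vector")
    }
    depths <- ape::node.depth.edgelength(ph)
    node_times <- max(depths[seq_len(length(ph$tip.label))]) - depths
    node_times[node_times < 1e-12] <- 0
    if (any(node_times < 0)) op_domain_error("tree must be ultrametric (times >= 0)")
  }
  names(n) <- names(theta) <- species
  structure(
    list(species = species, n = n, theta = theta, tree = ph,
         node_times = node_times, n_genes = as.integer(n_genes),
         gene_length = gene_length, theta_ref = theta_ref,
         theta_anc = theta_anc, missing_gene_prob = missing_gene_prob,
         mask_prob = mask_prob, sites = sites, base_freq = base_freq,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Tune a configuration toward retained ancestral polymorphism
#'
#' When enabled, rescales the species tree so its shallowest split occurs at
#' `split_time` coalescent units and raises the ancestral theta by
#' `theta_anc_factor`, so that shared ancestral polymorphisms survive into
#' two or more descendant species (incomplete lineage sorting). When
#' disabled, returns the configuration unchanged.
#'
#' @param cfg a `sim_config`.
#' @param enabled logical flag.
#' @param split_time target time of the shallowest split (default 0.05).
#' @param theta_anc_factor multiplier on `theta_ref` for ancestral
#'   populations (default 3).
#' @return a `sim_config`.
#' @export
ancestral_sharing_mode <- function(cfg, enabled = TRUE, split_time = 0.05,
                                   theta_anc_factor = 3) {
  if (!enabled) return(cfg)
  ntip <- length(cfg$tree$tip.label)
  internal_times <- cfg$node_times[(ntip + 1L):length(cfg$node_times)]
  t_min <- min(internal_times[internal_times > 0])
  ph <- cfg$tree
  ph$edge.length <- ph$edge.length * (split_time / t_min)
  sim_config(species = cfg$species, n = cfg$n, theta = cfg$theta, tree = ph,
             n_genes = cfg$n_genes, gene_length = cfg$gene_length,
             theta_ref = cfg$theta_ref,
             theta_anc = theta_anc_factor * cfg$theta_ref,
             missing_gene_prob = cfg$missing_gene_prob,
             mask_prob = cfg$mask_prob, sites = cfg$sites,
             base_freq = cfg$base_freq, seed = cfg$seed)
}

## Deterministic per-gene sub-seeds and gene lengths derived from the master
## seed, so gene i's output is independent of whether other genes are drawn.
sim_gene_plan <- function(cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  if (length(cfg$gene_length) == cfg$n_genes && cfg$n_genes != 2L) {
    lens <- as.integer(cfg$gene_length)
  } else if (length(cfg$gene_length) == 2L) {
    lens <- as.integer(round(runif(cfg$n_genes, cfg$gene_length[1L],
                                   cfg$gene_length[2L])))
  } else {
    lens <- rep_len(as.integer(cfg$gene_length), cfg$n_genes)
  }
  seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_genes)
  list(lengths = lens, seeds = seeds)
}

## Mutation rate per site per coalescent time unit. theta = 0 everywhere
## (including ancestral populations) means "no mutation at all", matching
## the intuition that theta = 4 N mu = 0 implies mu = 0.
mutation_rate <- function(cfg) {
  if (all(cfg$theta == 0) && cfg$theta_anc == 0) 0 else cfg$theta_ref / 2
}

## Kingman coalescent within populations merged at species-tree node times.
## Returns parent pointers, node times, leaf labels and leaf species.
sim_genealogy <- function(cfg) {
  if (is.null(cfg$tree)) return(sim_genealogy_single(cfg))
  ph <- cfg$tree
  ntip <- length(ph$tip.label)
  n_nodes_tree <- ntip + ph$Nnode
  f_pop <- numeric(n_nodes_tree)
  f_pop[seq_len(ntip)] <- cfg$theta[ph$tip.label] / cfg$theta_ref
  f_pop[(ntip + 1L):n_nodes_tree] <- cfg$theta_anc / cfg$theta_ref
  f_pop[f_pop <= 0] <- 1e-12   # theta 0: effectively instant coalescence

  n_leaves <- sum(cfg$n[ph$tip.label])
  max_nodes <- 2L * n_leaves
  parent <- integer(max_nodes); ntime <- numeric(max_nodes)
  labels <- character(n_leaves); leaf_sp <- character(n_leaves)
  lin <- vector("list", n_nodes_tree)
  k <- 0L
  for (tip in seq_len(ntip)) {
    sp <- ph$tip.label[tip]
    ids <- k + seq_len(cfg$n[sp])
    labels[ids] <- sprintf("%s_%02d", sp, seq_len(cfg$n[sp]))
    leaf_sp[ids] <- sp
    lin[[tip]] <- ids
    k <- k + cfg$n[sp]
  }
  nid <- n_leaves

  internal <- (ntip + 1L):n_nodes_tree
  ev_ord <- internal[order(cfg$node_times[internal])]
  children <- lapply(seq_len(n_nodes_tree), function(v)
    ph$edge[ph$edge[, 1L] == v, 2L])

  t <- 0
  active <- seq_len(ntip)
  coalesce_until <- function(t, t_end) {
    repeat {
      ks <- lengths(lin[active])
      rates <- ks * (ks - 1) / 2 / f_pop[active]
      R <- sum(rates)
      if (R <= 0) return(t_end)
      tn <- t + rexp(1L, R)
      if (tn > t_end) return(t_end)
      t <- tn
      pop <- active[sample.int(length(active), 1L, prob = rates)]
      pick <- lin[[pop]][sample.int(length(lin[[pop]]), 2L)]
      nid <<- nid + 1L
      parent[pick] <<- nid
      ntime[nid] <<- t
      lin[[pop]] <<- c(setdiff(lin[[pop]], pick), nid)
    }
  }
  for (v in ev_ord) {
    t <- coalesce_until(t, cfg$node_times[v])
    ch <- children[[v]]
    lin[[v]] <- unlist(lin[ch])
    active <- c(setdiff(active, ch), v)
  }
  # ancestral population of the root: coalesce to a single lineage
  root <- ev_ord[length(ev_ord)]
  while (length(lin[[root]]) > 1L) {
    kk <- length(lin[[root]])
    t <- t + rexp(1L, kk * (kk - 1) / 2 / f_pop[root])
    pick <- lin[[root]][sample.int(kk, 2L)]
    nid <- nid + 1L
    parent[pick] <- nid
    ntime[nid] <- t
    lin[[root]] <- c(setdiff(lin[[root]], pick), nid)
  }
  list(parent = parent[seq_len(nid)], time = ntime[seq_len(nid)],
       n_leaves = n_leaves, labels = labels, leaf_species = leaf_sp,
       root = nid)
}

## Single-population coalescent (one species, no species tree).
sim_genealogy_single <- function(cfg) {
  sp <- cfg$species[1L]
  n <- cfg$n[[sp]]
  f <- cfg$theta[[sp]] / cfg$theta_ref
  if (f <= 0) f <- 1e-12
  parent <- integer(2L * n); ntime <- numeric(2L * n)
  labels <- sprintf("%s_%02d", sp, seq_len(n))
  lin <- seq_len(n); nid <- n; t <- 0
  while (length(lin) > 1L) {
    kk <- length(lin)
    t <- t + rexp(1L, kk * (kk - 1) / 2 / f)
    pick <- lin[sample.int(kk, 2L)]
    nid <- nid + 1L
    parent[pick] <- nid
    ntime[nid] <- t
    lin <- c(setdiff(lin, pick), nid)
  }
  list(parent = parent[seq_len(nid)], time = ntime[seq_len(nid)],
       n_leaves = n, labels = labels, leaf_species = rep(sp, n), root = nid)
}

## Leaf sets below every node (list of integer vectors of leaf indices).
descendant_leaves <- function(gen) {
  desc <- vector("list", length(gen$parent))
  for (v in seq_len(gen$n_leaves)) desc[[v]] <- v
  ord <- order(gen$time)   # leaves (t=0) first, then internal by time
  for (v in ord) {
    p <- gen$parent[v]
    if (p > 0L) desc[[p]] <- c(desc[[p]], desc[[v]])
  }
  desc
}

## Place infinite-sites mutations; returns data.frame(column0, node, derived)
## plus the ancestral sequence.
place_mutations <- function(gen, L, cfg) {
  non_root <- setdiff(seq_along(gen$parent), gen$root)
  blen <- gen$time[gen$parent[non_root]] - gen$time[non_root]
  nmut <- rpois(length(non_root), L * mutation_rate(cfg) * blen)
  total <- sum(nmut)
  if (total > L) {
    op_domain_error(sprintf(
      "infinite-sites overflow: %d mutations for %d columns; lower theta or use sites='jc'",
      total, L))
  }
  anc <- sample(BASES, L, replace = TRUE, prob = cfg$base_freq)
  if (total == 0L) {
    return(list(anc = anc,
                mutations = data.frame(column = integer(0), node = integer(0),
                                       derived = character(0),
                                       stringsAsFactors = FALSE)))
  }
  cols <- sample.int(L, total)
  nodes <- rep(non_root, nmut)
  derived <- vapply(cols, function(j) {
    alt <- BASES[BASES != anc[j]]
    alt[sample.int(3L, 1L)]
  }, character(1))
  list(anc = anc,
       mutations = data.frame(column = cols - 1L, node = nodes,
                              derived = derived, stringsAsFactors = FALSE))
}

## Finite-sites Jukes-Cantor evolution down the genealogy.
evolve_jc <- function(gen, L, cfg) {
  anc <- sample(BASES, L, replace = TRUE, prob = cfg$base_freq)
  seqs <- vector("list", length(gen$parent))
  ord <- order(gen$time, decreasing = TRUE)  # root first
  seqs[[gen$root]] <- anc
  for (v in ord) {
    if (v == gen$root) next
    p <- gen$parent[v]
    s <- seqs[[p]]
    nsub <- rpois(1L, L * mutation_rate(cfg) * (gen$time[p] - gen$time[v]))
    if (nsub > 0L) {
      pos <- sample.int(L, nsub, replace = TRUE)
      for (j in pos) s[j] <- BASES[BASES != s[j]][sample.int(3L, 1L)]
    }
    seqs[[v]] <- s
  }
  do.call(rbind, seqs[seq_len(gen$n_leaves)])
}

#' Simulate one gene under the multispecies coalescent
#'
#' Samples a genealogy (Kingman coalescent within populations, lineages
#' merged at species-tree split times, final coalescence in the root
#' population), places Poisson mutations at rate `theta_ref/2` per site per
#' unit of `2N_ref` generations on every branch (infinite-sites by default),
#' then applies the missing-data processes: whole-accession gene dropout and
#' contiguous N-mask segments. Each gene uses its own RNG sub-stream derived
#' from the master seed, so genes are mutually independent and individually
#' reproducible.
#'
#' @param cfg a `sim_config`.
#' @param gene_index gene number in `1..cfg$n_genes`.
#' @return list with `aln` (a `gene_alignment`; dropped accessions removed)
#'   and `truth`: `gene_id`, `length`, `mutations` (0-based column, node,
#'   derived base, per-mutation `shared` flag and `shared_species` for
#'   mutations polymorphic within >= 2 species), `missing_accessions`,
#'   `masked_accessions`, `genealogy`.
#' @export
simulate_gene <- function(cfg, gene_index) {
  if (gene_index < 1L || gene_index > cfg$n_genes) {
    op_input_error(sprintf("gene_index must be in 1..%d", cfg$n_genes))
  }
  plan <- sim_gene_plan(cfg)
  L <- plan$lengths[gene_index]
  set.seed(plan$seeds[gene_index])
  gene_id <- sprintf("gene%03d", gene_index)

  gen <- sim_genealogy(cfg)
  if (cfg$sites == "infinite") {
    pm <- place_mutations(gen, L, cfg)
    mat <- matrix(rep(pm$anc, each = gen$n_leaves), nrow = gen$n_leaves)
    mut <- pm$mutations
    shared <- logical(nrow(mut)); shared_sp <- character(nrow(mut))
    if (nrow(mut) > 0L) {
      desc <- descendant_leaves(gen)
      n_by_sp <- table(gen$leaf_species)
      for (m in seq_len(nrow(mut))) {
        leaves <- desc[[mut$node[m]]]
        mat[leaves, mut$column[m] + 1L] <- mut$derived[m]
        dcnt <- table(factor(gen$leaf_species[leaves],
                             levels = names(n_by_sp)))
        poly <- names(dcnt)[dcnt > 0 & dcnt < n_by_sp]
        shared[m] <- length(poly) >= 2L
        shared_sp[m] <- paste(sort(poly), collapse = ",")
      }
    }
    mut$shared <- shared
    mut$shared_species <- shared_sp
  } else {
    mat <- evolve_jc(gen, L, cfg)
    mut <- data.frame(column = integer(0), node = integer(0),
                      derived = character(0), shared = logical(0),
                      shared_species = character(0), stringsAsFactors = FALSE)
  }
  rownames(mat) <- gen$labels

  miss <- runif(gen$n_leaves) < cfg$missing_gene_prob
  # never drop every accession of the whole panel
  if (all(miss)) miss[1L] <- FALSE
  masked <- character(0)
  for (r in which(!miss)) {
    if (runif(1L) < cfg$mask_prob) {
      seg <- max(1L, as.integer(round(L * runif(1L, 0.05, 0.30))))
      start <- sample.int(L - seg + 1L, 1L)
      mat[r, start:(start + seg - 1L)] <- "N"
      masked <- c(masked, gen$labels[r])
    }
  }
  aln <- new_gene_alignment(gene_id, mat[!miss, , drop = FALSE])
  list(aln = aln,
       truth = list(gene_id = gene_id, length = L, mutations = mut,
                    missing_accessions = gen$labels[miss],
                    masked_accessions = masked, genealogy = gen))
}

#' Simulate a full multi-gene, multi-species panel
#'
#' Runs [simulate_gene()] for every locus; optionally writes the exact input
#' formats consumed by the analysis stages — one `<gene_id>.fasta` per gene,
#' a `samples.tsv` sheet, and truth sidecars (`truth_mutations.tsv`,
#' `truth_params.json`) — so a simulated panel is indistinguishable from a
#' real one to the pipeline. Byte-identical across runs at the same seed.
#'
#' @param cfg a `sim_config`.
#' @param out_dir optional output directory (created if needed).
#' @return invisibly, list with `genes` (named list of `gene_alignment`),
#'   `truths`, `panel` (a `species_panel`), and `paths` when written.
#' @export
simulate_panel <- function(cfg, out_dir = NULL) {
  sims <- lapply(seq_len(cfg$n_genes), function(i) simulate_gene(cfg, i))
  genes <- lapply(sims, `[[`, "aln")
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  truths <- lapply(sims, `[[`, "truth")
  names(truths) <- names(genes)

  acc <- unlist(lapply(cfg$species, function(s)
    sprintf("%s_%02d", s, seq_len(cfg$n[s]))))
  sp <- rep(cfg$species, cfg$n[cfg$species])
  panel <- species_panel(acc, sp)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in genes) {
      seqs <- apply(g$matrix, 1L, paste, collapse = "")
      set <- Biostrings::BStringSet(seqs)
      names(set) <- rownames(g$matrix)
      Biostrings::writeXStringSet(set, file.path(out_dir, paste0(g$gene_id, ".fasta")))
    }
    sheet <- file.path(out_dir, "samples.tsv")
    write.table(panel, sheet, sep = "\t", quote = FALSE, row.names = FALSE)
    mut_all <- do.call(rbind, lapply(truths, function(tr) {
      if (nrow(tr$mutations) == 0L) return(NULL)
      data.frame(gene_id = tr$gene_id,
                 tr$mutations[, c("column", "derived", "shared", "shared_species")],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(mut_all)) {
      mut_all <- data.frame(gene_id = character(0), column = integer(0),
                            derived = character(0), shared = logical(0),
                            shared_species = character(0))
    }
    mut_path <- file.path(out_dir, "truth_mutations.tsv")
    write.table(mut_all, mut_path, sep = "\t", quote = FALSE, row.names = FALSE)
    par_path <- file.path(out_dir, "truth_params.json")
    jsonlite::write_json(
      list(species = cfg$species, n = unname(cfg$n), theta = unname(cfg$theta),
           theta_ref = cfg$theta_ref, theta_anc = cfg$theta_anc,
           tree = ape::write.tree(cfg$tree), n_genes = cfg$n_genes,
           seed = cfg$seed, sites = cfg$sites),
      par_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- list(dir = out_dir, sample_sheet = sheet,
                  truth_mutations = mut_path, truth_params = par_path)
  }
  invisible(list(genes = genes, truths = truths, panel = panel, paths = paths))
}
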