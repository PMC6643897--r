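## trans_specific: sites segregating for the same allele pair within two or
## more species (shared ancestral variation / incomplete lineage sorting).

#' Classify a segregating base pair
#'
#' Folds complementary pairs: A/G with T/C (the transitions), A/C with T/G;
#' A/T and C/G are self-complementary. Classes: `AG_TC` (transition),
#' `AC_TG`, `AT_TA`, `CG_GC` (transversions).
#'
#' @param pair two distinct bases, as `c("A","G")` or `"A/G"`.
#' @return list with `class` and logical `transition`.
#' @export
classify_mutation <- function(pair) {
  if (length(pair) == 1L) pair <- strsplit(pair, "/", fixed = TRUE)[[1L]]
  if (length(pair) != 2L || !all(pair %in% BASES)) {
    op_domain_error("pair must be two bases among A,C,G,T")
  }
  if (pair[1L] == pair[2L]) op_domain_error("pair must contain two distinct bases")
  key <- paste(sort(pair), collapse = "")
  cls <- switch(key,
                AG = "AG_TC", CT = "AG_TC",
                AC = "AC_TG", GT = "AC_TG",
                AT = "AT_TA",
                CG = "CG_GC")
  list(class = cls, transition = cls == "AG_TC")
}

## Per-column allele-pair code for one species, NA where the species does
## not qualify. Qualification: no gap in the species, n_s >= 2, exactly two
## distinct bases each observed at least once (singletons admitted; a third
## allele disqualifies that species only, not the column).
species_pair_codes <- function(profiles, species) {
  cnt <- profiles$counts[[species]]
  present <- cnt > 0
  nb <- colSums(present)
  qual <- profiles$gaps[[species]] == 0 & profiles$n_s[[species]] >= 2 & nb == 2
  codes <- rep(NA_character_, profiles$length)
  for (j in which(qual)) {
    codes[j] <- paste(BASES[present[, j]], collapse = "/")
  }
  codes
}

#' Detect trans-specific polymorphisms
#'
#' A column yields a trans-specific locus for an unordered allele pair when
#' two or more species are each internally polymorphic at that column for
#' exactly that pair (biallelic within the species, sample size >= 2, no gap
#' call in the species). One locus is emitted per (gene, column, allele
#' pair); column indices are 0-based.
#'
#' @param profiles a `site_profiles` object or a list of them (one per gene).
#' @param panel a `species_panel` (used only for validation that at least
#'   two species are represented).
#' @return data.frame of class `trans_specific_loci` with columns `gene_id`,
#'   `column`, `pair`, `k`, `species` (comma-separated), `class`,
#'   `transition`.
#' @export
detect_trans_specific <- function(profiles, panel) {
  if (inherits(profiles, "site_profiles")) profiles <- list(profiles)
  if (length(unique(panel$species)) < 2L) {
    op_input_error("trans-specific detection needs at least two species")
  }
  rows <- list()
  for (p in profiles) {
    if (length(p$species) < 2L) next
    codes <- vapply(p$species, function(s) species_pair_codes(p, s),
                    character(p$length))
    if (p$length == 1L) codes <- matrix(codes, nrow = 1L,
                                        dimnames = list(NULL, p$species))
    n_qual <- rowSums(!is.na(codes))
    for (j in which(n_qual >= 2)) {
      tab <- table(codes[j, ])
      for (pr in names(tab)[tab >= 2]) {
        sp <- sort(p$species[!is.na(codes[j, ]) & codes[j, ] == pr])
        cl <- classify_mutation(pr)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = p$gene_id, column = j - 1L, pair = pr,
          k = length(sp), species = paste(sp, collapse = ","),
          class = cl$class, transition = cl$transition,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), column = integer(0),
               pair = character(0), k = integer(0), species = character(0),
               class = character(0), transition = logical(0),
               stringsAsFactors = FALSE)
  class(out) <- c("trans_specific_loci", "data.frame")
  out
}

#' Summary tables for trans-specific loci
#'
#' Produces (i) per-gene locus counts and the genes-per-count histogram,
#' (ii) counts by sharing-set size `k`, (iii) counts by mutation class, and
#' (iv) per species-pair counts. With `attribution = "combinatorial"`
#' (default) a locus shared by `k` species contributes to all `choose(k,2)`
#' unordered pairs, so the per-pair total exceeds the locus count whenever
#' any `k > 2` (noted in the output); with `"primary"` each locus counts
#' once, for the lexicographically first pair of its sharing set.
#'
#' @param loci output of [detect_trans_specific()].
#' @param attribution `"combinatorial"` or `"primary"`.
#' @return list with data.frames `per_gene`, `gene_histogram`, `by_k`,
#'   `by_class`, `by_pair`, and scalar `total`.
#' @export
summarize_trans_specific <- function(loci, attribution = c("combinatorial", "primary")) {
  attribution <- match.arg(attribution)
  empty <- list(
    per_gene = data.frame(gene_id = character(0), n_loci = integer(0)),
    gene_histogram = data.frame(n_loci = integer(0), n_genes = integer(0)),
    by_k = data.frame(k = integer(0), count = integer(0)),
    by_class = data.frame(class = character(0), count = integer(0)),
    by_pair = data.frame(pair = character(0), count = integer(0)),
    total = 0L, attribution = attribution)
  if (nrow(loci) == 0L) return(empty)

  per_gene <- aggregate(list(n_loci = loci$column), by = list(gene_id = loci$gene_id), FUN = length)
  per_gene <- per_gene[order(per_gene$gene_id), , drop = FALSE]
  ht <- table(per_gene$n_loci)
  gene_histogram <- data.frame(n_loci = as.integer(names(ht)),
                               n_genes = as.integer(ht))
  kt <- table(loci$k)
  by_k <- data.frame(k = as.integer(names(kt)), count = as.integer(kt))
  ct <- table(factor(loci$class, levels = c("AG_TC", "AC_TG", "AT_TA", "CG_GC")))
  by_class <- data.frame(class = names(ct), count = as.integer(ct))

  pair_rows <- lapply(seq_len(nrow(loci)), function(i) {
    sp <- sort(strsplit(loci$species[i], ",", fixed = TRUE)[[1L]])
    if (attribution == "combinatorial") {
      cb <- combn(sp, 2L)
      paste(cb[1L, ], cb[2L, ], sep = "/")
    } else {
      paste(sp[1L], sp[2L], sep = "/")
    }
  })
  pt <- sort(table(unlist(pair_rows)), decreasing = TRUE)
  by_pair <- data.frame(pair = names(pt), count = as.integer(pt))
  rownames(per_gene) <- NULL

  list(per_gene = per_gene, gene_histogram = gene_histogram, by_k = by_k,
       by_class = by_class, by_pair = by_pair, total = nrow(loci),
       attribution = attribution)
}
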