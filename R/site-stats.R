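## site_stats: per-column allele counts within and across species; the shared
## substrate for diversity, trans-specific and HKA computations.

#' Profile every alignment column by species
#'
#' For each species with accessions in the alignment, tallies per-column
#' counts of the four bases, gaps and missing calls. Bases are counted only
#' for non-gap, non-N calls. Also assigns each column an overall
#' classification across all accessions: `missing` (all calls N), `indel`
#' (any gap present), else `monomorphic` / `biallelic_snp` /
#' `multiallelic_snp` by the number of distinct bases observed.
#'
#' @param aln a `gene_alignment`.
#' @param panel a `species_panel` covering every accession in `aln`.
#' @return a `site_profiles` object: list with `gene_id`, `length`,
#'   `species`, per-species `counts` (4 x L integer matrix, rows A,C,G,T),
#'   `gaps`, `missing`, `n_s` (non-missing non-gap sample size per column),
#'   `n_acc` (accessions per species in the alignment), and `classification`.
#' @export
profile_sites <- function(aln, panel) {
  check_accessions_in_panel(aln, panel)
  mat <- aln$matrix
  L <- ncol(mat)
  sp_of <- setNames(panel$species, panel$accession)
  species <- sort(unique(unname(sp_of[rownames(mat)])))

  counts <- list(); gaps <- list(); missing <- list(); n_s <- list()
  n_acc <- integer(0)
  for (s in species) {
    accs <- rownames(mat)[sp_of[rownames(mat)] == s]
    sub <- mat[accs, , drop = FALSE]
    cnt <- t(vapply(BASES, function(b) colSums(sub == b), numeric(L)))
    if (L == 1L) cnt <- matrix(cnt, nrow = 4L, dimnames = list(BASES, NULL))
    rownames(cnt) <- BASES
    counts[[s]] <- cnt
    gaps[[s]] <- colSums(sub == "-")
    missing[[s]] <- colSums(sub == "N")
    n_s[[s]] <- colSums(cnt)
    n_acc[s] <- length(accs)
  }

  tot_cnt <- Reduce(`+`, counts)
  tot_gap <- Reduce(`+`, gaps)
  tot_n <- colSums(tot_cnt)
  nb <- colSums(tot_cnt > 0)
  cls <- rep("monomorphic", L)
  cls[nb == 2] <- "biallelic_snp"
  cls[nb >= 3] <- "multiallelic_snp"
  cls[tot_gap > 0] <- "indel"
  cls[tot_n == 0 & tot_gap == 0] <- "missing"

  structure(
    list(gene_id = aln$gene_id, length = L, species = species,
         counts = counts, gaps = gaps, missing = missing, n_s = n_s,
         n_acc = n_acc, classification = cls),
    class = "site_profiles"
  )
}

#' @export
print.site_profiles <- function(x, ...) {
  cat(sprintf("site profiles '%s': %d columns, %d species\n",
              x$gene_id, x$length, length(x$species)))
  print(table(x$classification))
  invisible(x)
}

#' Long-format per-site table (for TSV dumps and inspection)
#'
#' One row per (column, species). Column indices are 1-based in this
#' human-readable output; everything internal is 0-based.
#'
#' @param profiles a `site_profiles` object.
#' @return data.frame with gene, column, species, n, gap, missing, alleles,
#'   classification.
#' @export
site_profile_table <- function(profiles) {
  rows <- lapply(profiles$species, function(s) {
    cnt <- profiles$counts[[s]]
    alleles <- apply(cnt, 2L, function(v) {
      p <- v > 0
      if (!any(p)) return("")
      paste(sprintf("%s:%d", BASES[p], v[p]), collapse = ",")
    })
    data.frame(gene = profiles$gene_id, column = seq_len(profiles$length),
               species = s, n = profiles$n_s[[s]], gap = profiles$gaps[[s]],
               missing = profiles$missing[[s]], alleles = alleles,
               classification = profiles$classification,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-species segregating-site and evaluable-length table
#'
#' A column is evaluable for a species when its within-species sample size
#' is at least 2 (a singleton cannot segregate) and the species has no gap
#' call there (columns touched by indels are excluded from SNP statistics;
#' indels are tallied separately by [count_indel_events()]). Among evaluable
#' columns, a column segregates when two or more distinct bases are observed;
#' multiallelic columns count once toward `S` (Watterson convention).
#'
#' @param profiles a `site_profiles` object.
#' @param species species name.
#' @return a `species_site_table`: list with `species`, `gene_id`, `S`, `L`,
#'   logical vectors `evaluable` and `segregating`, and `n_acc`.
#' @export
species_site_table <- function(profiles, species) {
  if (!(species %in% profiles$species)) {
    op_metadata_error(sprintf("species '%s' absent from profiles of gene '%s'",
                              species, profiles$gene_id))
  }
  cnt <- profiles$counts[[species]]
  evaluable <- profiles$n_s[[species]] >= 2 & profiles$gaps[[species]] == 0
  nb <- colSums(cnt > 0)
  seg <- evaluable & nb >= 2
  structure(
    list(species = species, gene_id = profiles$gene_id,
         S = sum(seg), L = sum(evaluable),
         evaluable = evaluable, segregating = seg,
         n_acc = profiles$n_acc[[species]]),
    class = "species_site_table"
  )
}

#' Count indel events per species
#'
#' A maximal run of consecutive gap columns within one sequence is one indel
#' event; events with identical (start, end) shared by several accessions of
#' the same species are deduplicated to a single event.
#'
#' @param aln a `gene_alignment`.
#' @param panel a `species_panel`.
#' @return named integer vector: indel event count per species present in
#'   the alignment.
#' @export
count_indel_events <- function(aln, panel) {
  check_accessions_in_panel(aln, panel)
  sp_of <- setNames(panel$species, panel$accession)
  species <- sort(unique(unname(sp_of[aln$accessions])))
  out <- setNames(integer(length(species)), species)
  for (s in species) {
    accs <- aln$accessions[sp_of[aln$accessions] == s]
    runs <- list()
    for (a in accs) {
      r <- rle(aln$matrix[a, ] == "-")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      gap <- r$values
      if (any(gap)) {
        runs[[a]] <- paste(starts[gap], ends[gap], sep = "-")
      }
    }
    out[s] <- length(unique(unlist(runs)))
  }
  out
}
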