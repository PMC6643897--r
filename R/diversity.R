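## diversity: Watterson's theta and nucleotide diversity pi per species over
## a gene set, with missing data handled per site.

#' Partial harmonic sums used by Watterson's estimator and the HKA variances
#'
#' Returns `a = sum(1/i)` and `b = sum(1/i^2)` for `i = 1 .. n-1`.
#'
#' @param n sample size (number of sequences), `n >= 2`.
#' @return list with elements `a` and `b`.
#' @export
harmonic_numbers <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 2) {
    op_domain_error("harmonic_numbers requires a single sample size n >= 2")
  }
  i <- seq_len(n - 1)
  list(a = sum(1 / i), b = sum(1 / i^2))
}

#' Watterson's theta per base pair
#'
#' `theta = S / (a_n * L)` where `S` is the number of segregating sites,
#' `L` the evaluable length and `a_n` the partial harmonic sum for the
#' sample size.
#'
#' @param table a `species_site_table`, or a list with elements `S` and `L`.
#' @param n_eff sample size used for `a_n`; defaults to the table's
#'   accession count.
#' @return theta per bp (numeric scalar).
#' @export
watterson_theta <- function(table, n_eff = table$n_acc) {
  if (is.null(table$L) || table$L < 1) op_empty_error("no evaluable sites (L = 0)")
  if (is.null(n_eff) || n_eff < 2) op_domain_error("n_eff must be >= 2")
  table$S / (harmonic_numbers(n_eff)$a * table$L)
}

## Per-column unbiased heterozygosity for one species: h_s =
## [n/(n-1)] * (1 - sum((c/n)^2)) over evaluable columns; NA elsewhere.
site_heterozygosity <- function(profiles, species) {
  cnt <- profiles$counts[[species]]
  n <- profiles$n_s[[species]]
  evaluable <- n >= 2 & profiles$gaps[[species]] == 0
  h <- rep(NA_real_, profiles$length)
  if (any(evaluable)) {
    ne <- n[evaluable]
    freq2 <- colSums((cnt[, evaluable, drop = FALSE] /
                        rep(ne, each = 4L))^2)
    h[evaluable] <- ne / (ne - 1) * (1 - freq2)
  }
  list(h = h, evaluable = evaluable)
}

#' Nucleotide diversity pi per base pair for one species
#'
#' Per evaluable column with allele counts `c_a` and sample size
#' `n_s = sum(c_a)`, the unbiased site heterozygosity is
#' `h = n_s/(n_s-1) * (1 - sum((c_a/n_s)^2))`; pi is `sum(h) / L` with `L`
#' the evaluable-column count. With complete data this equals the mean
#' pairwise Hamming distance per site over all sequence pairs.
#'
#' @param profiles a `site_profiles` object (or list of them, pooled).
#' @param species species name.
#' @return pi per bp (numeric scalar).
#' @export
nucleotide_diversity_pi <- function(profiles, species) {
  if (inherits(profiles, "site_profiles")) profiles <- list(profiles)
  num <- 0; L <- 0L
  for (p in profiles) {
    if (!(species %in% p$species)) next
    sh <- site_heterozygosity(p, species)
    num <- num + sum(sh$h[sh$evaluable])
    L <- L + sum(sh$evaluable)
  }
  if (L == 0L) op_empty_error(sprintf("species '%s': no evaluable sites", species))
  num / L
}

#' Per-species diversity report over a gene set
#'
#' One row per species, pooling segregating sites and evaluable length over
#' the genes counted for that species. A gene is counted for a species when
#' at least `min_accessions` (default 2) of its accessions carry at least
#' `coverage` (default 50%) non-missing columns. Theta uses the species'
#' nominal panel accession count for `a_n` by default (`n_policy =
#' "nominal"`, matching the usual one-`n`-per-species reporting); with
#' `n_policy = "mean_site"` it uses the mean per-site sample size over
#' evaluable columns instead.
#'
#' @param genes list of `gene_alignment` objects.
#' @param panel a `species_panel`.
#' @param coverage presence threshold per accession (default 0.5).
#' @param min_accessions minimum covered accessions for a gene to count
#'   (default 2).
#' @param n_policy `"nominal"` or `"mean_site"`.
#' @return data.frame with columns species, n, n_genes, L, S, theta, pi.
#'   Species with fewer than 2 accessions in the panel are skipped with a
#'   warning.
#' @export
diversity_report <- function(genes, panel, coverage = 0.5,
                             min_accessions = 2L,
                             n_policy = c("nominal", "mean_site")) {
  n_policy <- match.arg(n_policy)
  if (length(genes) == 0L) op_input_error("gene list is empty")
  profiles <- lapply(genes, profile_sites, panel = panel)
  sp_all <- panel_species(panel)
  rows <- list()
  for (s in sp_all) {
    n_nom <- length(panel_accessions(panel, s))
    if (n_nom < 2L) {
      warning(sprintf("species '%s' has < 2 accessions; skipped", s))
      next
    }
    S <- 0L; L <- 0L; n_genes <- 0L; pi_num <- 0; nsum <- 0
    for (k in seq_along(genes)) {
      g <- genes[[k]]; p <- profiles[[k]]
      if (!(s %in% p$species)) next
      accs <- intersect(panel_accessions(panel, s), g$accessions)
      cov <- rowMeans(g$matrix[accs, , drop = FALSE] != "N")
      if (sum(cov >= coverage) < min_accessions) next
      st <- species_site_table(p, s)
      sh <- site_heterozygosity(p, s)
      S <- S + st$S; L <- L + st$L; n_genes <- n_genes + 1L
      pi_num <- pi_num + sum(sh$h[sh$evaluable])
      nsum <- nsum + sum(p$n_s[[s]][sh$evaluable])
    }
    if (n_genes == 0L || L == 0L) {
      warning(sprintf("species '%s': no genes passed the per-gene filter; skipped", s))
      next
    }
    n_eff <- if (n_policy == "nominal") n_nom else max(2, nsum / L)
    theta <- if (S == 0L) 0 else S / (harmonic_numbers(ceiling(n_eff))$a * L)
    rows[[s]] <- data.frame(
      species = s, n = n_nom, n_genes = n_genes, L = L, S = S,
      theta = theta, pi = pi_num / L, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) op_empty_error("no species with usable data")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
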