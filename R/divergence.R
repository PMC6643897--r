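## divergence: Tajima-Nei ("equal input") distances between accession pairs,
## between-species means, full distance matrices, neighbor-joining tree.

#' Tajima-Nei distance between two aligned sequences
#'
#' The "equal input" distance assumes equal substitution rates among sites
#' and between transitions and transversions but corrects for unequal base
#' composition. Comparison is restricted to columns where both calls are in
#' `{A,C,G,T}` (pairwise deletion). With `p` the mismatch proportion, `g_i`
#' the base frequencies averaged over the two sequences, `x_ij` the relative
#' frequencies of the six unordered mismatch types, and
#' `h = sum_{i<j} x_ij^2 / (2 g_i g_j)`, the distance is
#' `d = -b * log(1 - p/b)` with `b = (1 - sum(g_i^2) + p^2/h) / 2`.
#' Under uniform composition and a uniform mismatch spectrum `b = 3/4` and
#' `d` reduces to the Jukes-Cantor distance. When `p = 0`, `d = 0` by
#' convention (`h` undefined); when `p >= b` the distance is undefined and
#' flagged, never clamped.
#'
#' @param seq1,seq2 character vectors of equal length over the six-symbol
#'   alphabet (rows of a `gene_alignment` matrix).
#' @return a `tajima_nei` list: `p`, `g` (named length-4), `x` (named
#'   length-6), `h`, `b`, `d`, `n_sites` (compared columns), `defined`.
#' @export
tajima_nei_pair <- function(seq1, seq2) {
  if (length(seq1) != length(seq2)) op_input_error("sequences differ in length")
  ok <- seq1 %in% BASES & seq2 %in% BASES
  n <- sum(ok)
  empty <- structure(
    list(p = NA_real_, g = setNames(rep(NA_real_, 4), BASES),
         x = setNames(rep(NA_real_, 6), BASE_PAIRS), h = NA_real_,
         b = NA_real_, d = NA_real_, n_sites = n, defined = FALSE),
    class = "tajima_nei")
  if (n < 1L) return(empty)
  s1 <- seq1[ok]; s2 <- seq2[ok]
  diff <- s1 != s2
  p <- mean(diff)
  gc <- (tabulate(match(s1, BASES), 4L) + tabulate(match(s2, BASES), 4L)) / (2 * n)
  g <- setNames(gc, BASES)
  x <- setNames(numeric(6), BASE_PAIRS)
  if (p == 0) {
    out <- empty
    out[c("p", "h", "b", "d", "defined")] <- list(0, NA_real_, NA_real_, 0, TRUE)
    out$g <- g; out$x <- x
    return(out)
  }
  mm <- paste(pmin(s1[diff], s2[diff]), pmax(s1[diff], s2[diff]), sep = "/")
  x[] <- tabulate(match(mm, BASE_PAIRS), 6L) / n
  idx <- which(x > 0)
  pi1 <- match(substr(BASE_PAIRS[idx], 1, 1), BASES)
  pi2 <- match(substr(BASE_PAIRS[idx], 3, 3), BASES)
  h <- sum(x[idx]^2 / (2 * gc[pi1] * gc[pi2]))
  b <- (1 - sum(gc^2) + p^2 / h) / 2
  out <- empty
  out$p <- p; out$g <- g; out$x <- x; out$h <- h; out$b <- b
  if (p >= b) {
    out$d <- NA_real_; out$defined <- FALSE
  } else {
    out$d <- -b * log(1 - p / b); out$defined <- TRUE
  }
  out
}

#' Between-group mean Tajima-Nei distance
#'
#' Arithmetic mean of [tajima_nei_pair()] distances over all cross-species
#' accession pairs, each pair compared with pairwise deletion of missing
#' columns. Undefined pairs are excluded from the mean and counted.
#'
#' @param aln a `gene_alignment` or `concat_alignment`.
#' @param panel a `species_panel`.
#' @param species_a,species_b the two species.
#' @return list with `d` (mean, `NA` if all pairs undefined), `n_pairs`,
#'   `n_undefined`, `mean_sites`.
#' @export
between_group_distance <- function(aln, panel, species_a, species_b) {
  sp_of <- setNames(panel$species, panel$accession)
  accs_a <- aln$accessions[sp_of[aln$accessions] == species_a]
  accs_b <- aln$accessions[sp_of[aln$accessions] == species_b]
  if (length(accs_a) < 1L || length(accs_b) < 1L) {
    op_metadata_error(sprintf("species '%s' or '%s' has no accessions in alignment",
                              species_a, species_b))
  }
  ds <- numeric(0); sites <- numeric(0); undef <- 0L
  for (a in accs_a) {
    for (b in accs_b) {
      tn <- tajima_nei_pair(aln$matrix[a, ], aln$matrix[b, ])
      if (tn$defined) {
        ds <- c(ds, tn$d); sites <- c(sites, tn$n_sites)
      } else {
        undef <- undef + 1L
      }
    }
  }
  n_pairs <- length(accs_a) * length(accs_b)
  list(d = if (length(ds)) mean(ds) else NA_real_,
       n_pairs = n_pairs, n_undefined = undef,
       mean_sites = if (length(sites)) mean(sites) else NA_real_)
}

#' Tajima-Nei distance matrix at accession or species level
#'
#' Species-level entries are between-group means
#' ([between_group_distance()]); accession-level entries are pairwise
#' distances. Undefined entries are `NA` and flagged in `undefined`.
#'
#' @param aln a `gene_alignment` or `concat_alignment`.
#' @param panel a `species_panel`.
#' @param level `"species"` (default) or `"accession"`.
#' @return a `distance_matrix`: list with `labels`, symmetric numeric `d`
#'   (zero diagonal), `undefined` logical matrix, `level`.
#' @export
distance_matrix <- function(aln, panel, level = c("species", "accession")) {
  level <- match.arg(level)
  check_accessions_in_panel(aln, panel)
  if (level == "accession") {
    labels <- aln$accessions
    m <- length(labels)
    d <- matrix(0, m, m, dimnames = list(labels, labels))
    undef <- matrix(FALSE, m, m, dimnames = list(labels, labels))
    if (m > 1L) {
      for (i in seq_len(m - 1L)) {
        for (j in (i + 1L):m) {
          tn <- tajima_nei_pair(aln$matrix[i, ], aln$matrix[j, ])
          d[i, j] <- d[j, i] <- tn$d
          undef[i, j] <- undef[j, i] <- !tn$defined
        }
      }
    }
  } else {
    sp_of <- setNames(panel$species, panel$accession)
    labels <- sort(unique(unname(sp_of[aln$accessions])))
    m <- length(labels)
    d <- matrix(0, m, m, dimnames = list(labels, labels))
    undef <- matrix(FALSE, m, m, dimnames = list(labels, labels))
    if (m > 1L) {
      for (i in seq_len(m - 1L)) {
        for (j in (i + 1L):m) {
          bg <- between_group_distance(aln, panel, labels[i], labels[j])
          d[i, j] <- d[j, i] <- bg$d
          undef[i, j] <- undef[j, i] <- is.na(bg$d)
        }
      }
    }
  }
  structure(list(labels = labels, d = d, undefined = undef, level = level),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Tajima-Nei distance matrix (%s level, %d labels)\n",
              x$level, length(x$labels)))
  print(round(x$d, digits))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Unrooted Saitou-Nei neighbor-joining on a `distance_matrix`, returned as
#' Newick text. The agglomeration itself is delegated to [ape::nj()]
#' (deterministic given input order). Undefined entries are an error that
#' names the offending pairs.
#'
#' @param dm a `distance_matrix` (or plain symmetric matrix with dimnames)
#'   with at least 3 labels.
#' @return single Newick string; the `ape` `phylo` object is attached as
#'   attribute `"phylo"`.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "distance_matrix")) {
    m <- dm$d
    und <- dm$undefined
  } else {
    m <- as.matrix(dm)
    und <- is.na(m) & row(m) != col(m)
  }
  if (nrow(m) < 3L) op_input_error("neighbor-joining needs at least 3 labels")
  bad <- which(und & upper.tri(und), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    pairs <- apply(bad, 1L, function(ij)
      paste(rownames(m)[ij[1L]], colnames(m)[ij[2L]], sep = " vs "))
    op_domain_error(paste("undefined distances:", paste(pairs, collapse = "; ")))
  }
  tree <- ape::nj(m)
  nwk <- ape::write.tree(tree)
  attr(nwk, "phylo") <- tree
  nwk
}
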