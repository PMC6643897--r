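## hka: two-species multilocus Hudson-Kreitman-Aguade neutrality test.
## Observations per locus i: S_A_i, S_B_i (within-species segregating
## sites), D_i (mean pairwise between-species differences). Parameters:
## theta_i per locus, f (relative population size of B), T (scaled
## divergence time, units of 2N_A generations). Expectations:
##   E[S_A_i] = theta_i a(n_A),            Var = E + theta_i^2 b(n_A)
##   E[S_B_i] = f theta_i a(n_B),          Var = E + (f theta_i)^2 b(n_B)
##   E[D_i]   = theta_i (T + (1+f)/2),     Var = E + (theta_i (1+f)/2)^2
## X^2 sums the standardized squared deviations of all 3L observations;
## df = 2L - 2.

#' Assemble HKA observations for a species pair from gene alignments
#'
#' Per gene: within-species segregating sites from [species_site_table()]
#' computed on the gene restricted to that species' evaluable accessions
#' (those with at least `coverage` non-missing columns); `D` is the mean,
#' over all cross-species accession pairs, of the count of differing sites
#' among columns where both calls are bases; `L` counts columns with at
#' least one base call in both species. Loci are dropped (and logged in the
#' `dropped` attribute) when either species has fewer than 2 evaluable
#' accessions, there are no comparable sites, or the locus carries no
#' information (both species monomorphic and `D = 0`).
#'
#' @param genes list of `gene_alignment` objects.
#' @param panel a `species_panel`.
#' @param species_a,species_b the two species (A is the reference for
#'   population-size and time units).
#' @param coverage evaluable-accession threshold (default 0.5).
#' @return an `hka_input`: data.frame with columns `gene_id`, `S_A`, `S_B`,
#'   `D`, `L`, `n_A`, `n_B`; attribute `dropped` lists excluded loci.
#' @export
build_hka_input <- function(genes, panel, species_a, species_b, coverage = 0.5) {
  if (!all(c(species_a, species_b) %in% panel$species)) {
    op_metadata_error("both species must be present in the panel")
  }
  sp_of <- setNames(panel$species, panel$accession)
  rows <- list(); dropped <- list()
  drop <- function(g, why) dropped[[length(dropped) + 1L]] <<- data.frame(
    gene_id = g, reason = why, stringsAsFactors = FALSE)

  for (g in genes) {
    accs <- g$accessions
    eval_acc <- function(sp) {
      a <- accs[sp_of[accs] == sp]
      if (length(a) == 0L) return(character(0))
      a[rowMeans(g$matrix[a, , drop = FALSE] != "N") >= coverage]
    }
    aa <- eval_acc(species_a); bb <- eval_acc(species_b)
    if (length(aa) < 2L || length(bb) < 2L) {
      drop(g$gene_id, "fewer than 2 evaluable accessions in one species")
      next
    }
    sub <- new_gene_alignment(g$gene_id, g$matrix[c(aa, bb), , drop = FALSE])
    prof <- profile_sites(sub, panel)
    S_A <- species_site_table(prof, species_a)$S
    S_B <- species_site_table(prof, species_b)$S

    is_base_a <- prof$n_s[[species_a]] > 0
    is_base_b <- prof$n_s[[species_b]] > 0
    L <- sum(is_base_a & is_base_b)
    if (L == 0L) { drop(g$gene_id, "no comparable sites"); next }
    dsum <- 0
    for (a in aa) for (b in bb) {
      ok <- g$matrix[a, ] %in% BASES & g$matrix[b, ] %in% BASES
      dsum <- dsum + sum(g$matrix[a, ok] != g$matrix[b, ok])
    }
    D <- dsum / (length(aa) * length(bb))
    if (S_A == 0L && S_B == 0L && D == 0) {
      drop(g$gene_id, "zero-information locus"); next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, S_A = S_A, S_B = S_B, D = D, L = L,
      n_A = length(aa), n_B = length(bb), stringsAsFactors = FALSE)
  }
  if (length(rows) < 2L) {
    op_insufficient_error(sprintf(
      "HKA needs >= 2 usable loci for %s vs %s (got %d)",
      species_a, species_b, length(rows)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hka_input", "data.frame")
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(gene_id = character(0), reason = character(0))
  attr(out, "species") <- c(species_a, species_b)
  out
}

#' Construct HKA input directly from per-locus observations
#'
#' Convenience constructor for simulated or tabulated observations.
#'
#' @param S_A,S_B,D,L,n_A,n_B numeric vectors, one entry per locus
#'   (`n_A`/`n_B` recycle to the locus count).
#' @param gene_id optional locus labels.
#' @return an `hka_input` data.frame.
#' @export
hka_input <- function(S_A, S_B, D, L = 1, n_A, n_B,
                      gene_id = sprintf("locus%02d", seq_along(S_A))) {
  k <- length(S_A)
  out <- data.frame(gene_id = gene_id, S_A = S_A, S_B = S_B, D = D,
                    L = rep_len(L, k), n_A = rep_len(n_A, k),
                    n_B = rep_len(n_B, k), stringsAsFactors = FALSE)
  if (any(out$S_A < 0 | out$S_B < 0 | out$D < 0 | out$L < 1 |
            out$n_A < 2 | out$n_B < 2)) {
    op_domain_error("invalid HKA observations (negative counts or n < 2)")
  }
  class(out) <- c("hka_input", "data.frame")
  out
}

#' Fit the multilocus HKA model and compute the goodness-of-fit test
#'
#' Solves the moment estimating equations
#' `sum(S_A) = sum(theta_i a(n_A_i))`,
#' `sum(S_B) = f sum(theta_i a(n_B_i))`,
#' `sum(D) = (T + (1+f)/2) sum(theta_i)`, and per locus
#' `S_A_i + S_B_i + D_i = theta_i (a(n_A_i) + f a(n_B_i) + T + (1+f)/2)`
#' by fixed-point iteration: `f` is initialized from the ratio of summed
#' polymorphism, then theta_i, f and T are updated in turn until the maximum
#' relative parameter change falls below `tol`. The first aggregate equation
#' is implied by the others and serves as a conservation check.
#'
#' @param input an `hka_input` with at least 2 loci.
#' @param tol relative convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return an `hka_fit`: list with `loci` (per-locus data.frame including
#'   `theta_hat`, the three standardized components and their sum `X2_i`),
#'   `f`, `T`, `X2`, `df`, `p`, `n_iter`, `converged`.
#' @export
fit_hka <- function(input, tol = 1e-10, max_iter = 10000L) {
  if (nrow(input) < 2L) op_insufficient_error("HKA fit requires >= 2 loci")
  hA <- lapply(input$n_A, harmonic_numbers)
  hB <- lapply(input$n_B, harmonic_numbers)
  aA <- vapply(hA, `[[`, numeric(1), "a"); bA <- vapply(hA, `[[`, numeric(1), "b")
  aB <- vapply(hB, `[[`, numeric(1), "a"); bB <- vapply(hB, `[[`, numeric(1), "b")
  S_A <- input$S_A; S_B <- input$S_B; D <- input$D
  tot <- S_A + S_B + D
  if (sum(tot) <= 0) op_domain_error("degenerate data: no polymorphism or divergence")

  f <- if (sum(S_A) > 0) sum(S_B) / sum(S_A) else 1
  if (f <= 0) f <- 1e-6
  th0 <- pmax(S_A / aA, 1e-8)
  T <- max(sum(D) / sum(th0) - (1 + f) / 2, 0.1)

  par_old <- c(f, T, th0)
  n_iter <- 0L
  resid_tol <- 1e-9
  repeat {
    n_iter <- n_iter + 1L
    th <- tot / (aA + f * aB + T + (1 + f) / 2)
    sum_th <- sum(th)
    if (sum_th <= 0) op_domain_error("degenerate data: estimated sum(theta) = 0")
    f_new <- if (sum(th * aB) > 0) sum(S_B) / sum(th * aB) else f
    T_new <- sum(D) / sum_th - (1 + f_new) / 2
    par_new <- c(f_new, T_new, th)
    delta <- max(abs(par_new - par_old) / pmax(abs(par_old), 1e-12))
    par_old <- par_new
    f <- f_new; T <- T_new
    # converge on parameter stability and on the aggregate estimating
    # equations themselves (absolute residuals in count units)
    resid <- max(abs(sum(S_A) - sum(th * aA)),
                 abs(sum(S_B) - f * sum(th * aB)),
                 abs(sum(D) - (T + (1 + f) / 2) * sum_th))
    if (delta < tol && resid < resid_tol) break
    if (n_iter >= max_iter) {
      op_convergence_error(sprintf(
        "HKA fit did not converge in %d iterations (last delta %.3e; f=%.6g T=%.6g)",
        max_iter, delta, f, T))
    }
  }
  th <- tot / (aA + f * aB + T + (1 + f) / 2)

  EA <- th * aA;              VA <- EA + th^2 * bA
  EB <- f * th * aB;          VB <- EB + (f * th)^2 * bB
  ED <- th * (T + (1 + f) / 2); VD <- ED + (th * (1 + f) / 2)^2
  cA <- (S_A - EA)^2 / VA
  cB <- (S_B - EB)^2 / VB
  cD <- (D - ED)^2 / VD
  X2_i <- cA + cB + cD
  X2 <- sum(X2_i)
  df <- 2L * nrow(input) - 2L
  loci <- data.frame(input, theta_hat = th, E_SA = EA, E_SB = EB, E_D = ED,
                     comp_SA = cA, comp_SB = cB, comp_D = cD, X2_i = X2_i,
                     stringsAsFactors = FALSE)
  structure(
    list(loci = loci, f = f, T = T, X2 = X2, df = df,
         p = pchisq(X2, df, lower.tail = FALSE),
         n_iter = n_iter, converged = TRUE,
         species = attr(input, "species")),
    class = "hka_fit")
}

#' @export
print.hka_fit <- function(x, ...) {
  sp <- if (!is.null(x$species)) paste(x$species, collapse = " vs ") else "A vs B"
  cat(sprintf("HKA fit (%s): %d loci, f=%.4f, T=%.4f, X2=%.4f, df=%d, p=%.4g\n",
              sp, nrow(x$loci), x$f, x$T, x$X2, x$df, x$p))
  invisible(x)
}

#' Summarize HKA fits over species pairs
#'
#' Per species pair: loci used, X2, df, p. Per locus: the component `X2_i`
#' with a flag when it exceeds the chi-square(1) quantile at `alpha` — a
#' documented per-gene significance proxy.
#'
#' @param fits named list of `hka_fit` objects (name = species pair label).
#' @param alpha per-locus flag threshold (default 0.05).
#' @return list with data.frames `pairs` and `loci`, plus `n_flagged` and
#'   `frac_flagged` over all per-locus components.
#' @export
hka_report <- function(fits, alpha = 0.05) {
  if (length(fits) == 0L) op_input_error("empty fit list")
  if (is.null(names(fits))) names(fits) <- sprintf("pair%02d", seq_along(fits))
  crit <- qchisq(1 - alpha, df = 1)
  pair_rows <- list(); locus_rows <- list()
  for (nm in names(fits)) {
    ft <- fits[[nm]]
    pair_rows[[nm]] <- data.frame(
      pair = nm, n_loci = nrow(ft$loci), f = ft$f, T = ft$T,
      X2 = ft$X2, df = ft$df, p = ft$p, stringsAsFactors = FALSE)
    locus_rows[[nm]] <- data.frame(
      pair = nm, ft$loci[, c("gene_id", "S_A", "S_B", "D", "L",
                             "theta_hat", "X2_i")],
      flagged = ft$loci$X2_i > crit, stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, locus_rows)
  rownames(loci) <- NULL
  pairs <- do.call(rbind, pair_rows)
  rownames(pairs) <- NULL
  list(pairs = pairs, loci = loci,
       n_flagged = sum(loci$flagged),
       frac_flagged = mean(loci$flagged),
       alpha = alpha)
}
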