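## alignment_io: per-gene aligned multi-FASTA + sample sheet, sub-alignments,
## cross-gene concatenation with a per-species presence filter.

#' Normalize aligned residues to the six-symbol alphabet
#'
#' Uppercases, maps RNA `U` to `T`, preserves the alignment gap `-`, and maps
#' every other symbol (IUPAC ambiguity codes, `?`, `.`, etc.) to `N`
#' (missing). Heterozygous ambiguity codes are deliberately treated as
#' missing: the panels this package targets are essentially inbred and
#' heterozygous calls are too rare to model. Idempotent.
#'
#' @param x character vector (or matrix) of single residues.
#' @return object of the same shape with residues in `{A,C,G,T,-,N}`.
#' @export
normalize_residues <- function(x) {
  out <- chartr("u", "U", toupper(x))
  out <- chartr("U", "T", out)
  out[!(out %in% ALPHABET)] <- "N"
  if (is.matrix(x)) {
    dim(out) <- dim(x)
    dimnames(out) <- dimnames(x)
  }
  out
}

new_gene_alignment <- function(gene_id, mat) {
  if (!is.matrix(mat) || !is.character(mat)) {
    op_input_error("alignment matrix must be a character matrix")
  }
  if (ncol(mat) < 1L) op_format_error(sprintf("gene '%s': alignment has zero columns", gene_id))
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    op_metadata_error(sprintf("gene '%s': accession IDs missing or duplicated", gene_id))
  }
  bad <- !(mat %in% ALPHABET)
  if (any(bad)) op_format_error(sprintf("gene '%s': un-normalized residues present", gene_id))
  structure(
    list(gene_id = gene_id, accessions = rownames(mat),
         matrix = mat, length = ncol(mat)),
    class = "gene_alignment"
  )
}

#' Read one gene's aligned multi-FASTA
#'
#' The first whitespace-delimited token of each FASTA header is the accession
#' ID; the remainder of the header is ignored. Residues are normalized via
#' [normalize_residues()].
#'
#' @param path path to an aligned multi-FASTA file.
#' @param gene_id gene identifier; defaults to the file name without its
#'   `.fa`/`.fasta` extension.
#' @return a `gene_alignment`: list with `gene_id`, `accessions`, character
#'   `matrix` (rows = accessions, columns = alignment positions), `length`.
#' @export
read_gene_alignment <- function(path, gene_id = sub("\\.fa(sta)?$", "", basename(path))) {
  if (!file.exists(path)) op_input_error(sprintf("no such file: %s", path))
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) op_format_error(
                     sprintf("cannot parse FASTA '%s': %s", path, conditionMessage(e))))
  if (length(recs) == 0L) op_input_error(sprintf("empty FASTA file: %s", path))
  ids <- vapply(strsplit(names(recs), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    op_metadata_error(sprintf("gene '%s': duplicate accession ID '%s'",
                              gene_id, ids[duplicated(ids)][1L]))
  }
  w <- Biostrings::width(recs)
  if (length(unique(w)) != 1L) {
    op_format_error(sprintf(
      "gene '%s': records are not aligned (lengths %s)", gene_id,
      paste(sort(unique(w)), collapse = ", ")))
  }
  if (w[1L] < 1L) op_format_error(sprintf("gene '%s': zero-length records", gene_id))
  mat <- do.call(rbind, strsplit(as.character(recs), "", fixed = TRUE))
  mat <- normalize_residues(mat)
  rownames(mat) <- ids
  new_gene_alignment(gene_id, mat)
}

#' Read a directory of per-gene FASTA files
#'
#' @param dir directory containing `<gene_id>.fasta` (or `.fa`) files.
#' @return named list of `gene_alignment` objects, sorted by gene id.
#' @export
read_gene_dir <- function(dir) {
  if (!dir.exists(dir)) op_input_error(sprintf("no such directory: %s", dir))
  paths <- sort(list.files(dir, pattern = "\\.fa(sta)?$", full.names = TRUE))
  if (length(paths) == 0L) op_input_error(sprintf("no FASTA files in %s", dir))
  genes <- lapply(paths, read_gene_alignment)
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  genes
}

#' Construct a species panel from vectors
#'
#' @param accession character vector of accession IDs.
#' @param species character vector of species names, same length.
#' @return a `species_panel`: data.frame with columns `accession`, `species`.
#' @export
species_panel <- function(accession, species) {
  if (length(accession) != length(species) || length(accession) < 1L) {
    op_input_error("accession and species must be non-empty vectors of equal length")
  }
  df <- unique(data.frame(accession = as.character(accession),
                          species = as.character(species),
                          stringsAsFactors = FALSE))
  if (anyDuplicated(df$accession)) {
    dup <- df$accession[duplicated(df$accession)][1L]
    op_metadata_error(sprintf(
      "accession '%s' listed with conflicting species", dup))
  }
  class(df) <- c("species_panel", "data.frame")
  df
}

#' Read a sample sheet (accession -> species)
#'
#' Tab-separated text with header columns `accession` and `species`.
#' Species names are taken verbatim. An accession listed twice with the same
#' species collapses to one row; conflicting species raise a metadata error.
#'
#' @param path path to the TSV sample sheet.
#' @return a `species_panel`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) op_input_error(sprintf("no such file: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("accession", "species") %in% names(df))) {
    op_format_error("sample sheet must have columns 'accession' and 'species'")
  }
  species_panel(df$accession, df$species)
}

#' @export
print.species_panel <- function(x, ...) {
  cat(sprintf("species panel: %d accessions, %d species\n",
              nrow(x), length(unique(x$species))))
  print(table(species = x$species))
  invisible(x)
}

panel_species <- function(panel) sort(unique(panel$species))

panel_accessions <- function(panel, species = NULL) {
  if (is.null(species)) return(panel$accession)
  panel$accession[panel$species == species]
}

check_accessions_in_panel <- function(aln, panel) {
  missing <- setdiff(aln$accessions, panel$accession)
  if (length(missing) > 0L) {
    op_metadata_error(sprintf(
      "gene '%s': accession(s) not in panel: %s", aln$gene_id,
      paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

## Per-species count of accessions present in a gene with >= coverage
## fraction of non-N columns (gaps count as present sequence).
gene_presence_counts <- function(aln, panel, coverage = 0.5) {
  sp <- panel_species(panel)
  vapply(sp, function(s) {
    accs <- intersect(panel_accessions(panel, s), aln$accessions)
    if (length(accs) == 0L) return(0L)
    cov <- rowMeans(aln$matrix[accs, , drop = FALSE] != "N")
    sum(cov >= coverage)
  }, integer(1))
}

#' Concatenate gene alignments with a per-species presence filter
#'
#' A gene is retained only if, in every species of the panel, at least
#' `min_presence` accessions carry at least `coverage` (default 50%)
#' non-missing columns of that gene. The default `min_presence = 4` encodes
#' the "present in more than three accessions per species" ortholog-selection
#' rule typical of multi-species amplicon panels. Accessions absent from a
#' retained gene are padded with `N` over that gene's span. Gene offsets are
#' 0-based, half-open.
#'
#' @param genes list of `gene_alignment` objects.
#' @param panel a `species_panel`; the concatenated rows are the panel's
#'   accessions in panel order.
#' @param min_presence minimum accession count per species (default 4).
#' @param coverage minimum non-N column fraction for an accession to count
#'   as present (default 0.5).
#' @return a `concat_alignment`: `gene_alignment` plus `offsets`
#'   (data.frame `gene_id`, `start`, `end`) and a `dropped` attribute
#'   listing filtered genes.
#' @export
concatenate <- function(genes, panel, min_presence = 4L, coverage = 0.5) {
  if (length(genes) == 0L) op_input_error("gene list is empty")
  for (g in genes) check_accessions_in_panel(g, panel)
  keep <- vapply(genes, function(g) {
    all(gene_presence_counts(g, panel, coverage) >= min_presence)
  }, logical(1))
  dropped <- data.frame(
    gene_id = vapply(genes[!keep], `[[`, character(1), "gene_id"),
    reason = if (any(!keep)) sprintf("fewer than %d accessions with >=%d%% coverage in some species",
                                     min_presence, round(100 * coverage)) else character(0),
    stringsAsFactors = FALSE
  )
  if (nrow(dropped) > 0L) {
    message(sprintf("concatenate: dropped %d gene(s): %s", nrow(dropped),
                    paste(dropped$gene_id, collapse = ", ")))
  }
  genes <- genes[keep]
  if (length(genes) == 0L) op_empty_error("all genes removed by the presence filter")

  accs <- panel$accession
  lens <- vapply(genes, `[[`, integer(1), "length")
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  total <- ends[length(ends)]
  mat <- matrix("N", nrow = length(accs), ncol = total,
                dimnames = list(accs, NULL))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    cols <- (starts[i] + 1L):ends[i]
    mat[g$accessions, cols] <- g$matrix
  }
  offsets <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    start = as.integer(starts), end = as.integer(ends),
    stringsAsFactors = FALSE
  )
  out <- new_gene_alignment("concatenated", mat)
  out$offsets <- offsets
  class(out) <- c("concat_alignment", class(out))
  attr(out, "dropped") <- dropped
  out
}

#' Write a concatenated alignment plus its gene-offset sidecar
#'
#' Writes multi-FASTA to `path` and a TSV of 0-based half-open gene offsets
#' (`gene_id`, `start`, `end`) to `offsets_path`. Round-trips through
#' [read_concatenated()].
#'
#' @param aln a `concat_alignment`.
#' @param path output FASTA path.
#' @param offsets_path output TSV path (default `<path>.offsets.tsv`).
#' @return invisibly, `c(path, offsets_path)`.
#' @export
write_concatenated <- function(aln, path,
                               offsets_path = paste0(path, ".offsets.tsv")) {
  if (!inherits(aln, "concat_alignment")) op_input_error("not a concat_alignment")
  if (nrow(aln$matrix) == 0L || ncol(aln$matrix) == 0L) {
    op_empty_error("refusing to write an empty alignment")
  }
  seqs <- apply(aln$matrix, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- rownames(aln$matrix)
  tryCatch(Biostrings::writeXStringSet(set, path),
           error = function(e) op_input_error(
             sprintf("cannot write '%s': %s", path, conditionMessage(e))))
  write.table(aln$offsets, offsets_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(path, offsets_path))
}

#' Read a concatenated alignment written by [write_concatenated()]
#'
#' @param path FASTA path.
#' @param offsets_path offsets TSV path (default `<path>.offsets.tsv`).
#' @return a `concat_alignment`.
#' @export
read_concatenated <- function(path, offsets_path = paste0(path, ".offsets.tsv")) {
  aln <- read_gene_alignment(path, gene_id = "concatenated")
  off <- read.delim(offsets_path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "start", "end") %in% names(off))) {
    op_format_error("offsets sidecar must have columns gene_id, start, end")
  }
  if (nrow(off) > 0L && off$end[nrow(off)] != aln$length) {
    op_format_error("offsets do not span the alignment")
  }
  aln$offsets <- off
  class(aln) <- c("concat_alignment", class(aln))
  aln
}

#' Extract one gene's columns from a concatenated alignment
#'
#' @param aln a `concat_alignment`.
#' @param gene_id gene to extract.
#' @return a `gene_alignment` with that gene's columns (all panel accessions,
#'   N-padded rows included).
#' @export
extract_gene <- function(aln, gene_id) {
  i <- match(gene_id, aln$offsets$gene_id)
  if (is.na(i)) op_input_error(sprintf("gene '%s' not in concatenation", gene_id))
  cols <- (aln$offsets$start[i] + 1L):aln$offsets$end[i]
  new_gene_alignment(gene_id, aln$matrix[, cols, drop = FALSE])
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("gene alignment '%s': %d accessions x %d bp\n",
              x$gene_id, length(x$accessions), x$length))
  invisible(x)
}
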