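## cli_pipeline: orchestrate the stages end-to-end and emit report TSVs.

#' Pipeline run configuration
#'
#' @param genes_dir directory of per-gene aligned FASTA files.
#' @param samples path to the sample-sheet TSV (accession, species).
#' @param out_dir output directory for report files.
#' @param stages subset of `c("diversity","divergence","njtree","transspec","hka")`.
#' @param min_presence per-species presence threshold for [concatenate()].
#' @param alpha significance threshold for HKA per-locus flags, in (0, 1).
#' @param seed recorded in report headers (analysis stages are deterministic).
#' @param focal_species focal species for HKA pairs; default: the panel
#'   species with the most accessions (ties broken alphabetically).
#' @param attribution trans-specific pair attribution, `"combinatorial"` or
#'   `"primary"`.
#' @param verbose emit progress messages.
#' @return a `run_config` list.
#' @export
run_config <- function(genes_dir, samples, out_dir,
                       stages = c("diversity", "divergence", "njtree",
                                  "transspec", "hka"),
                       min_presence = 4L, alpha = 0.05, seed = 1L,
                       focal_species = NULL,
                       attribution = c("combinatorial", "primary"),
                       verbose = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  attribution <- match.arg(attribution)
  if (!dir.exists(genes_dir)) op_input_error(sprintf("no such directory: %s", genes_dir))
  if (!file.exists(samples)) op_input_error(sprintf("no such file: %s", samples))
  if (alpha <= 0 || alpha >= 1) op_domain_error("alpha must lie in (0, 1)")
  structure(
    list(genes_dir = genes_dir, samples = samples, out_dir = out_dir,
         stages = stages, min_presence = as.integer(min_presence),
         alpha = alpha, seed = as.integer(seed),
         focal_species = focal_species, attribution = attribution,
         verbose = isTRUE(verbose)),
    class = "run_config")
}

## Hash of the semantic settings: changes iff a setting changes.
config_hash <- function(cfg) {
  sem <- cfg[c("stages", "min_presence", "alpha", "seed",
               "focal_species", "attribution")]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(sem), tf)
  unname(tools::md5sum(tf))
}

report_header <- function(cfg) {
  c(sprintf("# orthopop %s", as.character(packageVersion("orthopop"))),
    sprintf("# seed: %d", cfg$seed),
    sprintf("# config: %s", config_hash(cfg)))
}

write_report <- function(df, path, cfg, footer = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(cfg), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(footer)) writeLines(paste0("# ", footer), con)
  invisible(path)
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    op_abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             "orthopop_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes alignment I/O, site profiling, and the enabled stages:
#' per-species diversity (theta/pi table), species-level Tajima-Nei
#' distances on the concatenated alignment, a neighbor-joining tree,
#' trans-specific polymorphism detection and summaries, and HKA tests of
#' the focal species against every other species. Every report TSV carries
#' a header with the tool version, seed and config hash, so identical
#' inputs and settings yield identical files.
#'
#' @param cfg a `run_config`.
#' @return invisibly, list with `files` (named vector of written paths) and
#'   `results` (the in-memory objects).
#' @export
run_all <- function(cfg) {
  say <- function(...) if (cfg$verbose) message(sprintf(...))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(); results <- list()

  genes <- stage_try("alignment_io", read_gene_dir(cfg$genes_dir))
  panel <- stage_try("alignment_io", read_sample_sheet(cfg$samples))
  say("read %d genes, %d accessions, %d species", length(genes),
      nrow(panel), length(unique(panel$species)))
  concat <- stage_try("alignment_io",
                      concatenate(genes, panel, min_presence = cfg$min_presence))
  dropped <- attr(concat, "dropped")
  if (nrow(dropped) > 0L) {
    say("presence filter dropped %d gene(s)", nrow(dropped))
  }
  retained <- lapply(concat$offsets$gene_id, function(g) extract_gene(concat, g))
  names(retained) <- concat$offsets$gene_id
  profiles <- stage_try("site_stats", lapply(retained, profile_sites, panel = panel))
  results$concat <- concat

  if ("diversity" %in% cfg$stages) {
    div <- stage_try("diversity", diversity_report(retained, panel))
    out <- div
    out$theta <- round(out$theta, 4); out$pi <- round(out$pi, 4)
    files["diversity"] <- write_report(out, file.path(cfg$out_dir, "diversity.tsv"), cfg)
    results$diversity <- div
  }

  dm <- NULL
  if (any(c("divergence", "njtree") %in% cfg$stages)) {
    dm <- stage_try("divergence", distance_matrix(concat, panel, level = "species"))
    results$distance <- dm
  }
  if ("divergence" %in% cfg$stages) {
    mat <- as.data.frame(round(dm$d, 3))
    mat <- cbind(species = rownames(dm$d), mat)
    files["divergence"] <- write_report(mat, file.path(cfg$out_dir, "distance_species.tsv"), cfg)
  }
  if ("njtree" %in% cfg$stages) {
    if (length(dm$labels) < 3L) {
      say("njtree skipped: fewer than 3 species")
    } else {
      nwk <- stage_try("njtree", nj_tree(dm))
      path <- file.path(cfg$out_dir, "tree.nwk")
      writeLines(as.character(nwk), path)
      files["njtree"] <- path
      results$tree <- nwk
    }
  }

  if ("transspec" %in% cfg$stages) {
    loci <- stage_try("transspec", detect_trans_specific(profiles, panel))
    summ <- stage_try("transspec", summarize_trans_specific(loci, cfg$attribution))
    out <- loci
    if (nrow(out) > 0L) out$column <- out$column + 1L  # 1-based in reports
    files["transspec_loci"] <- write_report(out, file.path(cfg$out_dir, "transspec_loci.tsv"), cfg)
    files["transspec_by_k"] <- write_report(summ$by_k, file.path(cfg$out_dir, "transspec_by_k.tsv"), cfg)
    files["transspec_by_class"] <- write_report(summ$by_class, file.path(cfg$out_dir, "transspec_by_class.tsv"), cfg)
    footer <- if (summ$attribution == "combinatorial")
      "pair counts use C(k,2) expansion; their sum exceeds the locus total when k > 2" else
        "pair counts attribute each locus to its first species pair"
    files["transspec_by_pair"] <- write_report(summ$by_pair, file.path(cfg$out_dir, "transspec_by_pair.tsv"), cfg,
                                               footer = footer)
    files["transspec_gene_hist"] <- write_report(summ$gene_histogram,
                                                 file.path(cfg$out_dir, "transspec_gene_hist.tsv"), cfg)
    results$transspec <- list(loci = loci, summary = summ)
  }

  if ("hka" %in% cfg$stages) {
    focal <- cfg$focal_species
    if (is.null(focal)) {
      cnts <- table(panel$species)
      focal <- names(cnts)[order(-cnts, names(cnts))][1L]
    }
    others <- setdiff(panel_species(panel), focal)
    fits <- list()
    for (sp in others) {
      fit <- tryCatch(
        fit_hka(build_hka_input(retained, panel, focal, sp)),
        orthopop_insufficient_data_error = function(e) {
          say("hka %s vs %s skipped: %s", focal, sp, conditionMessage(e)); NULL
        })
      if (!is.null(fit)) fits[[paste(focal, sp, sep = "/")]] <- fit
    }
    if (length(fits) == 0L) {
      say("hka skipped: no species pair had enough data")
    } else {
      rep <- stage_try("hka", hka_report(fits, alpha = cfg$alpha))
      files["hka_summary"] <- write_report(rep$pairs, file.path(cfg$out_dir, "hka_summary.tsv"), cfg)
      files["hka_loci"] <- write_report(rep$loci, file.path(cfg$out_dir, "hka_loci.tsv"), cfg)
      results$hka <- rep
    }
  }

  say("wrote %d report files to %s", length(files), cfg$out_dir)
  invisible(list(files = files, results = results))
}
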