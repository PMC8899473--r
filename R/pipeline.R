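# End-to-end orchestration: a run configuration that round-trips through
# a key=value file, a deterministic run directory (trees/, tables/,
# report.txt, run.log), and a small command-line front end.

#' Pipeline run configuration
#'
#' Aggregates all stage parameters. Defaults carry the study constants:
#' 70 bp minimum read length, 5 percent maximum N fraction, e-value
#' threshold 1e-4, majority-rule consensus frequency 0.5.
#'
#' @param min_len read-filter minimum length (bases).
#' @param max_n_fraction read-filter maximum N fraction.
#' @param e_threshold annotation e-value threshold (strict).
#' @param min_frequency consensus inclusion frequency (strict).
#' @param include_threshold,dominance_threshold motif thresholds.
#' @param run_simulation run the synthetic phylogeny/panel/expression
#'   stages.
#' @param run_fixture run the packaged-peptide-table stages.
#' @param seed integer seed propagated to every stochastic stage.
#' @param ... fields forwarded to [simulation_config()].
#' @return object of class `run_config`.
#' @export
run_config <- function(min_len = 70L, max_n_fraction = 0.05,
                       e_threshold = 1e-4, min_frequency = 0.5,
                       include_threshold = 0.25, dominance_threshold = 0.5,
                       run_simulation = TRUE, run_fixture = TRUE,
                       seed = 1L, ...) {
  sim <- simulation_config(seed = seed, ...)
  structure(c(list(
    min_len = as.integer(min_len), max_n_fraction = max_n_fraction,
    e_threshold = e_threshold, min_frequency = min_frequency,
    include_threshold = include_threshold,
    dominance_threshold = dominance_threshold,
    run_simulation = isTRUE(run_simulation),
    run_fixture = isTRUE(run_fixture)
  ), unclass(sim)), class = "run_config")
}

#' Write / read a run configuration as key=value lines
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` a `run_config` identical to the one written.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- vapply(config, function(v) paste(format(v, digits = 17),
                                           collapse = ","), character(1))
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  parse_val <- function(v) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    if (all(parts %in% c("TRUE", "FALSE"))) return(as.logical(parts))
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) {
      if (all(num == round(num)) && all(abs(num) < .Machine$integer.max)) {
        return(as.integer(num))
      }
      return(num)
    }
    parts
  }
  out <- stats::setNames(lapply(vals, parse_val), keys)
  structure(out, class = "run_config")
}

pipeline_log <- function(con, stage, ...) {
  line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  writeLines(line, con)
  message(line)
}

#' Run the pipeline end to end
#'
#' Executes the configured stages and writes a deterministic run
#' directory: `trees/` (newick), `tables/` (tab-separated), `report.txt`
#' (panel size, consensus supports, peptide clade census, exclusivity
#' p-value) and `run.log`. Rerunning with the same configuration
#' reproduces the directory bit for bit (no timestamps are written).
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the main in-memory results
#'   (`species_tree`, `consensus`, `panel`, `census`, `motif`,
#'   `exclusivity`, `expression`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE,
             recursive = TRUE)
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE,
             recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.txt")
  write_run_config(config, cfg_path)
  param_hash <- unname(tools::md5sum(cfg_path))
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  report <- character()
  results <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop_("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  pipeline_log(log_con, "config", "hash=", param_hash, " seed=", config$seed)

  if (config$run_simulation) {
    stage("species-tree", {
      sp_tree <- simulate_species_tree(config$n_species, seed = config$seed)
      write_newick(sp_tree, file.path(out_dir, "trees", "species_tree.nwk"))
      results$species_tree <- sp_tree
      pipeline_log(log_con, "species-tree", "n_species=", config$n_species)
    })
    stage("gene-trees", {
      gt <- simulate_gene_trees(results$species_tree, config$n_genes,
                                config$discordance_rate,
                                seed = config$seed + 1L)
      writeLines(vapply(gt, write_newick, character(1)),
                 file.path(out_dir, "trees", "gene_trees.nwk"))
      results$gene_trees <- gt
      pipeline_log(log_con, "gene-trees", "n_genes=", config$n_genes,
                   " discordance_rate=", config$discordance_rate)
    })
    stage("consensus", {
      cons <- consensus_with_support(results$gene_trees,
                                     min_frequency = config$min_frequency)
      write_newick(cons, file.path(out_dir, "trees", "consensus.nwk"))
      supp <- attr(cons, "split_support")
      rf <- robinson_foulds(cons, results$species_tree)
      results$consensus <- cons
      report <- c(report,
        sprintf("consensus: %d supported splits, mean support %.3f, RF to species tree %d",
                length(supp), if (length(supp)) mean(supp) else NA_real_, rf))
      summ <- gene_tree_summary(results$gene_trees, cons)
      write_tsv(summ, file.path(out_dir, "tables", "gene_tree_summary.tsv"))
      pipeline_log(log_con, "consensus", "splits=", length(supp), " rf=", rf)
    })
    stage("hkg-panel", {
      ann <- simulate_annotation_table(n_samples = config$n_species,
                                       n_shared = config$n_genes,
                                       seed = config$seed + 2L)
      write_tsv(ann, file.path(out_dir, "tables", "annotations.tsv"))
      kept <- filter_hits(ann, e_threshold = config$e_threshold)
      panel <- build_panel(kept)
      results$panel <- panel
      write_tsv(panel$representatives,
                file.path(out_dir, "tables", "hkg_panel.tsv"))
      report <- c(report,
        sprintf("hkg panel: %d genes shared by %d samples (from %d annotation rows, %d past e<%g)",
                length(panel$gene_labels), panel$n_samples, nrow(ann),
                nrow(kept), config$e_threshold))
      pipeline_log(log_con, "hkg-panel", "rows=", nrow(ann), " kept=",
                   nrow(kept), " panel=", length(panel$gene_labels))
    })
    stage("expression", {
      panel <- results$panel
      reps <- panel$representatives
      sample1 <- panel$samples[1]
      hkg_contigs <- reps[reps$sample_id == sample1, "contig_id"]
      contigs <- data.frame(
        sample_id = sample1,
        contig_id = c(hkg_contigs, "tox_planted", "tox_background"),
        category = c(rep("hkg", length(hkg_contigs)), "toxin", "toxin"),
        stringsAsFactors = FALSE
      )
      sim_cfg <- simulation_config(seed = config$seed)
      expr <- simulate_expression(contigs, sim_cfg,
                                  seed = config$seed + 3L,
                                  planted_fold = c(tox_planted = 8))
      rep_tab <- expression_report(expr, panel,
                                   c("tox_planted", "tox_background"))
      results$expression <- rep_tab
      write_tsv(rep_tab, file.path(out_dir, "tables", "expression.tsv"))
      lead <- rep_tab[rep_tab$lead, ][1, ]
      report <- c(report,
        sprintf("expression: lead toxin %s at log2 fold %.3f vs HKG mean",
                lead$contig_id, lead$log2_fold_vs_hkg))
      pipeline_log(log_con, "expression", "rows=", nrow(rep_tab))
    })
  }

  if (config$run_fixture) {
    stage("peptides", {
      recs <- read_toxin_table()
      census <- framework_census(recs)
      results$census <- census
      write_tsv(census$table,
                file.path(out_dir, "tables", "peptide_frameworks.tsv"))
      motif <- consensus_motif(
        recs[recs$clade %in% c("I", "II"), , drop = FALSE], 1L,
        include_threshold = config$include_threshold,
        dominance_threshold = config$dominance_threshold)
      results$motif <- motif
      dd <- deduplicate(recs)
      write_tsv(dd$summary,
                file.path(out_dir, "tables", "peptide_duplicates.tsv"))
      tr <- mature_peptide_tree(recs[!duplicated(recs$mature), ,
                                     drop = FALSE])
      write_newick(tr, file.path(out_dir, "trees", "peptides_nj.nwk"))
      report <- c(report,
        sprintf("peptides: %d records, modal cysteine count %d, clade I+II loop-1 motif %s",
                nrow(recs), census$modal_n_cys, motif),
        sprintf("peptides: loop-1 lengths per clade: %s",
                paste(vapply(names(census$clade_loop1), function(cl)
                  paste0(cl, "=", paste(census$clade_loop1[[cl]],
                                        collapse = "/")), character(1)),
                  collapse = ", ")))
      pipeline_log(log_con, "peptides", "records=", nrow(recs))
    })
    stage("congruence", {
      recs <- read_toxin_table()
      ex <- exclusivity_permutation_test(recs, n_permutations = 10000L,
                                         seed = config$seed + 4L)
      results$exclusivity <- ex
      report <- c(report,
        sprintf("congruence: %d genus-mixed clades (null mean %.2f), permutation p = %.4f",
                ex$statistic, ex$null_mean, ex$p.value),
        paste("congruence note:", ex$caveat))
      pipeline_log(log_con, "congruence", "statistic=", ex$statistic,
                   " p=", format(ex$p.value, digits = 4))
    })
  }

  writeLines(report, file.path(out_dir, "report.txt"))
  pipeline_log(log_con, "done", "report lines=", length(report))
  invisible(results)
}

#' Command-line entry point
#'
#' Subcommands: `all` (default), `simulate`, `peptides`, `congruence`
#' run the corresponding stage groups; `filter-reads <in.fasta>
#' <out.fasta>` applies the read filter; `hkg-panel <annotations.tsv>
#' <out.tsv>` builds the panel table; `consensus <gene_trees.nwk>
#' <out.nwk>` builds the consensus tree. Common flags: `--seed <int>`,
#' `--out <dir>`.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return integer exit code: 0 success, 2 validation error, 3 stage
#'   failure.
#' @export
turripep_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_flag <- function(flag, default) {
    i <- which(args == flag)
    if (length(i)) args[i[1] + 1L] else default
  }
  positional <- function() {
    drop <- integer()
    for (f in c("--seed", "--out")) {
      i <- which(args == f)
      if (length(i)) drop <- c(drop, i[1], i[1] + 1L)
    }
    if (length(drop)) args[-drop] else args
  }
  tryCatch({
    pos <- positional()
    cmd <- if (length(pos)) pos[1] else "all"
    seed <- as.integer(get_flag("--seed", "1"))
    out <- get_flag("--out", "turripep_run")
    if (is.na(seed)) stop_("--seed must be an integer")
    code <- tryCatch({
      switch(cmd,
        "all" = run_pipeline(run_config(seed = seed), out),
        "simulate" = run_pipeline(run_config(seed = seed,
                                             run_fixture = FALSE), out),
        "peptides" = ,
        "congruence" = run_pipeline(run_config(seed = seed,
                                               run_simulation = FALSE), out),
        "filter-reads" = {
          if (length(pos) < 3L) stop_("usage: filter-reads <in> <out>")
          kept <- filter_reads(read_fasta(pos[2]))
          write_fasta(kept, pos[3])
          message("kept ", attr(kept, "n_kept"), ", discarded ",
                  attr(kept, "n_discarded"))
        },
        "hkg-panel" = {
          if (length(pos) < 3L) stop_("usage: hkg-panel <annotations.tsv> <out.tsv>")
          panel <- build_panel(filter_hits(read_tsv(pos[2])))
          write_tsv(panel$representatives, pos[3])
          message("panel size: ", length(panel$gene_labels))
        },
        "consensus" = {
          if (length(pos) < 3L) stop_("usage: consensus <gene_trees.nwk> <out.nwk>")
          trees <- ape::read.tree(pos[2])
          if (inherits(trees, "phylo")) trees <- list(trees)
          cons <- consensus_with_support(trees)
          write_newick(cons, pos[3])
        },
        stop_("unknown subcommand: ", cmd)
      )
      0L
    }, error = function(e) {
      message("error: ", conditionMessage(e))
      if (grepl("^stage '", conditionMessage(e))) 3L else 2L
    })
    code
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
}
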