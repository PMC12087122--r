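# Workspace layout, configuration parsing/validation, and pipeline
# orchestration. The workspace is a directory with four data subfolders
# (blastresults/, fastas/, resulttables/, combinedtables/), five plain-text
# configuration files at its root, and a run log.

WORKSPACE_DIRS <- c("blastresults", "fastas", "resulttables", "combinedtables")
CONFIG_FILES <- c("proteinlist.txt", "limits.txt", "heatmap_config.txt",
                  "tree_config.txt", "tree_to_prune.txt")
PIPELINE_STAGES <- c("parse", "qc", "filter", "combine", "heatmap", "tree")

config_templates <- function() {
  list(
    "proteinlist.txt" = c(
      "# Protein list: one row per protein.",
      "#   <protein_name> <seed_fasta_filename>",
      "# The FASTA file lives in fastas/ and may contain several seed",
      "# sequences; each seed is queried separately and the query results",
      "# are stored as blastresults/<protein>__<seed_id>.xml."),
    "limits.txt" = c(
      "# Filtering cutoffs, one row per protein:",
      "#   <protein> <evalue_cutoff> <min_length_aa>",
      "# Proteins without a row use the global defaults: e-value 1e-30,",
      "# minimum subject length 50 aa. A row whose protein field is",
      "# 'default' replaces those defaults. Both cutoffs are inclusive."),
    "heatmap_config.txt" = c(
      "# Heatmap settings, key = value. Recognised keys and defaults:",
      "# organisms = <comma-separated taxids or scientific names>",
      "#             (empty: all organisms with hits)",
      "# linkage = centroid",
      "#   one of single, complete, average, weighted, centroid, median, ward",
      "# colors = #ffffff, #000000",
      "# slider_default = 30"),
    "tree_config.txt" = c(
      "# Tree settings, key = value.",
      "# proteins = <up to three comma-separated protein names>",
      "#            (order sets the combination-code bit positions;",
      "#             empty: the first three proteins of proteinlist.txt)",
      "# colors = <2^p - 1 comma-separated pie colors>"),
    "tree_to_prune.txt" = c(
      "# One taxid or scientific name per line: these taxa are collapsed",
      "# into terminal nodes that keep their aggregated counts.",
      "# An optional line 'partition: <taxon>' restricts the tree to that",
      "# subtree (e.g. one superkingdom).")
  )
}

#' Initialise a workspace
#'
#' Creates the folder structure and the five configuration file templates
#' in `root`. Idempotent: re-running never touches existing files or
#' folders, so user-edited configurations are safe; the no-op is logged.
#'
#' @param root workspace directory (created if absent).
#' @return a `workspace` object (see [workspace()]).
#' @export
init_workspace <- function(root) {
  if (file.exists(root) && !dir.exists(root)) {
    stop_filesystem(sprintf("workspace root '%s' exists and is not a directory",
                            root))
  }
  if (!dir.exists(root)) {
    ok <- dir.create(root, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_filesystem(sprintf("cannot create workspace root '%s'", root))
  }
  created <- character(0)
  for (d in WORKSPACE_DIRS) {
    p <- file.path(root, d)
    if (!dir.exists(p)) { dir.create(p); created <- c(created, d) }
  }
  templates <- config_templates()
  for (f in CONFIG_FILES) {
    p <- file.path(root, f)
    if (!file.exists(p)) { writeLines(templates[[f]], p); created <- c(created, f) }
  }
  ws <- workspace(root)
  if (length(created)) {
    ws_log(ws, sprintf("init: created %s", paste(created, collapse = ", ")))
  } else {
    ws_log(ws, "init: no-op, workspace already initialised")
  }
  ws
}

#' Workspace handle
#'
#' Wraps an initialised workspace directory; errors if the expected
#' layout is missing (run [init_workspace()] first).
#'
#' @param root workspace directory.
#' @return object of class `workspace` with `root`, `dirs` and `configs`
#'   path lists.
#' @export
workspace <- function(root) {
  if (!dir.exists(root)) {
    stop_filesystem(sprintf("workspace root '%s' does not exist", root))
  }
  structure(list(
    root = normalizePath(root),
    dirs = stats::setNames(as.list(file.path(root, WORKSPACE_DIRS)), WORKSPACE_DIRS),
    configs = stats::setNames(as.list(file.path(root, CONFIG_FILES)), CONFIG_FILES),
    log = file.path(root, "run.log")
  ), class = "workspace")
}

#' @export
print.workspace <- function(x, ...) {
  cat(sprintf("workspace: %s\n", x$root))
  invisible(x)
}

ws_log <- function(ws, msg, level = "INFO") {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg)
  cat(line, "\n", sep = "", file = ws$log, append = TRUE)
  invisible(line)
}

#' Read proteinlist.txt
#'
#' Whitespace-separated rows `protein_name seed_fasta_filename`; `#`
#' comments ignored; protein names must be unique.
#'
#' @param path path to the protein list file.
#' @return data.frame with columns `protein` and `fasta`.
#' @export
read_proteinlist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(protein = character(0), fasta = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop_config(sprintf("proteinlist line %d: expected 'protein fasta_file'",
                        bad[1L]))
  }
  protein <- vapply(parts, `[`, "", 1L)
  fasta <- vapply(parts, `[`, "", 2L)
  dup <- protein[duplicated(protein)]
  if (length(dup)) {
    stop_config(sprintf("duplicate protein name(s) in proteinlist: %s",
                        paste(unique(dup), collapse = ", ")))
  }
  data.frame(protein = protein, fasta = fasta, stringsAsFactors = FALSE)
}

#' Parse and cross-validate all configuration files
#'
#' Parses the five configuration files of a workspace and enforces
#' cross-file consistency: limits and tree proteins must be listed in
#' `proteinlist.txt`, and at most three tree proteins are allowed. All
#' violations are collected and reported together in a single
#' configuration error.
#'
#' @param ws a [workspace()].
#' @param require_proteins error when `proteinlist.txt` lists no proteins
#'   (the default; disable to validate a freshly initialised workspace).
#' @return list with `proteins`, `limits`, `heatmap`, `tree`, `prune`.
#' @export
parse_configs <- function(ws, require_proteins = TRUE) {
  errors <- character(0)
  grab <- function(expr) {
    tryCatch(expr, taxoprofile_error = function(e) {
      errors <<- c(errors, conditionMessage(e))
      NULL
    })
  }
  proteins <- grab(read_proteinlist(ws$configs[["proteinlist.txt"]]))
  if (require_proteins && !is.null(proteins) && !nrow(proteins)) {
    errors <- c(errors, "proteinlist.txt: no proteins listed")
  }
  lim <- grab(read_limits(ws$configs[["limits.txt"]],
                          proteins = proteins$protein))
  hm <- grab(read_heatmap_config(ws$configs[["heatmap_config.txt"]]))
  tr <- grab(read_tree_config(ws$configs[["tree_config.txt"]]))
  pr <- grab(read_prune_config(ws$configs[["tree_to_prune.txt"]]))
  if (!is.null(tr) && !is.null(proteins)) {
    unknown <- setdiff(tr$proteins, proteins$protein)
    if (length(unknown)) {
      errors <- c(errors, sprintf("tree_config: protein(s) not in proteinlist: %s",
                                  paste(unknown, collapse = ", ")))
    }
  }
  if (length(errors)) {
    stop_config(paste0("configuration errors:\n",
                       paste0("  - ", errors, collapse = "\n")))
  }
  list(proteins = proteins, limits = lim, heatmap = hm, tree = tr, prune = pr)
}

load_workspace_taxonomy <- function(ws) {
  nodes <- file.path(ws$root, "taxonomy", "nodes.dmp")
  names_f <- file.path(ws$root, "taxonomy", "names.dmp")
  if (!file.exists(nodes) || !file.exists(names_f)) {
    stop_environment(sprintf(
      "no taxonomy found under %s/taxonomy (nodes.dmp + names.dmp); pass db=",
      ws$root))
  }
  load_taxonomy(nodes, names_f)
}

seed_xml_files <- function(ws, protein) {
  fs <- list.files(ws$dirs$blastresults,
                   pattern = paste0("^", protein, "__.*\\.xml$"),
                   full.names = TRUE)
  sort(fs, method = "radix")
}

filtered_table_files <- function(ws, protein) {
  fs <- list.files(ws$dirs$resulttables,
                   pattern = paste0("^", protein, "__.*\\.filtered\\.tsv$"),
                   full.names = TRUE)
  sort(fs, method = "radix")
}

raw_table_files <- function(ws, protein) {
  fs <- list.files(ws$dirs$resulttables,
                   pattern = paste0("^", protein, "__.*\\.tsv$"),
                   full.names = TRUE)
  sort(fs[!grepl("\\.filtered\\.tsv$", fs)], method = "radix")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order: `parse` (BLAST XML2
#' to result tables), `qc` (length histograms and coverage profiles),
#' `filter` (e-value/length cutoffs), `combine` (pooling per protein,
#' organism listings, cross-hit matrix), `heatmap`, and `tree`. Each stage
#' requires its upstream outputs and fails with a dependency error naming
#' the missing stage otherwise. The pipeline is re-entrant: stages can be
#' re-run individually after adjusting cutoffs without re-parsing. All
#' outputs are written deterministically, so identical inputs and
#' configurations yield byte-identical tables, Newick and HTML files.
#'
#' @param ws a [workspace()] (or its root path).
#' @param stages subset of the canonical stages to run.
#' @param db a `taxonomy_db`; when `NULL`, loaded from
#'   `<root>/taxonomy/nodes.dmp` and `names.dmp`.
#' @return a run report: named list per executed stage with the record and
#'   organism counts of that stage.
#' @export
run_pipeline <- function(ws, stages = PIPELINE_STAGES, db = NULL) {
  if (is.character(ws)) ws <- workspace(ws)
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown)) {
    stop_validation(sprintf("unknown stage(s): %s; valid: %s",
                            paste(unknown, collapse = ", "),
                            paste(PIPELINE_STAGES, collapse = ", ")))
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  cfg <- parse_configs(ws)
  if (is.null(db) && any(c("combine", "heatmap", "tree") %in% stages)) {
    db <- load_workspace_taxonomy(ws)
  }
  report <- list()
  for (stage in stages) {
    ws_log(ws, sprintf("stage %s: start", stage))
    report[[stage]] <- switch(stage,
      parse = stage_parse(ws, cfg),
      qc = stage_qc(ws, cfg),
      filter = stage_filter(ws, cfg),
      combine = stage_combine(ws, cfg, db),
      heatmap = stage_heatmap(ws, cfg, db),
      tree = stage_tree(ws, cfg, db)
    )
    ws_log(ws, sprintf("stage %s: done", stage))
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  for (stage in names(x)) {
    cat(sprintf("== %s ==\n", stage))
    utils::str(x[[stage]], max.level = 2, give.attr = FALSE)
  }
  invisible(x)
}

stage_parse <- function(ws, cfg) {
  out <- list()
  for (p in cfg$proteins$protein) {
    fasta <- file.path(ws$dirs$fastas, cfg$proteins$fasta[cfg$proteins$protein == p])
    if (!file.exists(fasta)) {
      stop_dependency(sprintf("seed FASTA %s missing for protein %s",
                              basename(fasta), p))
    }
    xmls <- seed_xml_files(ws, p)
    if (!length(xmls)) {
      stop_dependency(sprintf(
        "no BLAST XML2 results for protein %s in blastresults/ (expected %s__<seed>.xml)",
        p, p))
    }
    for (x in xmls) {
      tb <- parse_blast_xml(x, protein = p)
      dst <- file.path(ws$dirs$resulttables,
                       sprintf("%s__%s.tsv", p, sanitize_label(tb$seed_id)))
      n <- write_result_table(tb, dst)
      ws_log(ws, sprintf("parse: %s -> %s (%d hits, %d skipped)",
                         basename(x), basename(dst), n, tb$skipped_hits))
      out[[tb$seed_id]] <- c(hits = n, skipped = tb$skipped_hits)
    }
  }
  out
}

stage_qc <- function(ws, cfg) {
  out <- list()
  for (p in cfg$proteins$protein) {
    files <- raw_table_files(ws, p)
    if (!length(files)) {
      stop_dependency(sprintf("qc stage needs parse outputs for protein %s", p))
    }
    tables <- lapply(files, read_result_table)
    hist <- length_histogram(tables)
    hist_tsv <- file.path(ws$root, sprintf("qc_%s_lengths.tsv", p))
    utils::write.table(hist, hist_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    plot_length_histogram(hist, file.path(ws$root, sprintf("qc_%s_lengths.pdf", p)),
                          title = sprintf("Hit length distribution: %s", p))
    for (tb in tables) {
      prof <- coverage_profile(tb)
      plot_coverage_profile(prof, file.path(
        ws$root, sprintf("qc_%s_%s_coverage.pdf", p, sanitize_label(tb$seed_id))))
    }
    out[[p]] <- c(records = sum(vapply(tables, function(t) nrow(t$records), 0L)),
                  bins = nrow(hist))
  }
  out
}

stage_filter <- function(ws, cfg) {
  out <- list()
  for (p in cfg$proteins$protein) {
    files <- raw_table_files(ws, p)
    if (!length(files)) {
      stop_dependency(sprintf("filter stage needs parse outputs for protein %s", p))
    }
    for (f in files) {
      tb <- read_result_table(f)
      ft <- apply_limits(tb, cfg$limits)
      counts <- attr(ft, "filter_counts")
      dst <- sub("\\.tsv$", ".filtered.tsv", f)
      write_result_table(ft, dst)
      ws_log(ws, sprintf(
        "filter: %s/%s parsed=%d kept=%d removed_by_evalue=%d removed_by_length=%d",
        p, tb$seed_id, counts["parsed"], counts["kept"],
        counts["removed_by_evalue"], counts["removed_by_length"]), "WARN")
      out[[paste(p, tb$seed_id, sep = "/")]] <- counts
    }
  }
  out
}

stage_combine <- function(ws, cfg, db) {
  combined <- list()
  out <- list()
  for (p in cfg$proteins$protein) {
    files <- filtered_table_files(ws, p)
    if (!length(files)) {
      stop_dependency(sprintf("combine stage needs filter outputs for protein %s", p))
    }
    tables <- lapply(files, read_result_table)
    ct <- combine_protein(tables, db)
    write_combined_table(ct, file.path(ws$dirs$combinedtables,
                                       sprintf("%s.tsv", p)))
    combined[[p]] <- ct
    out[[p]] <- c(records = nrow(ct$records),
                  organisms = length(ct$best_by_organism))
  }
  org <- unique_organisms(combined, db)
  write_organism_listings(org, ws$dirs$combinedtables)
  out$overall_organisms <- nrow(org$overall)
  if (length(combined) >= 2L) {
    m <- cross_hit_matrix(combined)
    write_cross_hit_matrix(m, file.path(ws$root, "matrix.csv"))
    out$cross_hits <- sum(unclass(m)[upper.tri(m)] > 0)
  } else {
    ws_log(ws, "combine: single protein, cross-hit matrix skipped")
  }
  out
}

read_all_combined <- function(ws, cfg, stage) {
  combined <- list()
  for (p in cfg$proteins$protein) {
    f <- file.path(ws$dirs$combinedtables, sprintf("%s.tsv", p))
    if (!file.exists(f)) {
      stop_dependency(sprintf("%s stage needs combine outputs for protein %s",
                              stage, p))
    }
    combined[[p]] <- read_combined_table(f)
  }
  combined
}

stage_heatmap <- function(ws, cfg, db) {
  combined <- read_all_combined(ws, cfg, "heatmap")
  hm_cfg <- cfg$heatmap
  if (!length(hm_cfg$organisms)) {
    org <- unique_organisms(combined, db)
    hm_cfg$organisms <- as.character(org$overall$taxid)
    ws_log(ws, sprintf("heatmap: empty organism selection, using all %d organisms",
                       nrow(org$overall)))
  }
  m <- build_score_matrix(combined, hm_cfg, db)
  orders <- cluster_axes(m, hm_cfg$linkage)
  write_score_matrix(m, file.path(ws$root, "score_matrix.tsv"))
  render_heatmap(m, orders, hm_cfg, file.path(ws$root, "heatmap.html"))
  list(organisms = nrow(m), proteins = ncol(m),
       nonzero_cells = sum(unclass(m) > 0))
}

stage_tree <- function(ws, cfg, db) {
  combined <- read_all_combined(ws, cfg, "tree")
  tr_proteins <- cfg$tree$proteins
  if (!length(tr_proteins)) {
    tr_proteins <- utils::head(cfg$proteins$protein, 3L)
  }
  out <- list()
  emit <- function(proteins, stem, colors) {
    presence <- lapply(combined[proteins], function(ct) unique(ct$records$organism))
    names(presence) <- proteins
    tree <- annotate_tree(db, presence)
    tree <- prune_tree(tree, cfg$prune)
    render_tree(tree, colors = colors,
                graphic_path = file.path(ws$root, sprintf("tree_%s.pdf", stem)),
                newick_path = file.path(ws$root, sprintf("tree_%s.nwk", stem)),
                counts_path = file.path(ws$root, sprintf("tree_%s_counts.tsv", stem)))
    c(nodes = nrow(tree$nodes),
      organisms = unname(tree$total[as.character(tree$root)]))
  }
  for (p in tr_proteins) {  # one tree per protein
    out[[p]] <- emit(p, sanitize_label(p), colors = cfg$tree$colors[1L])
  }
  if (length(tr_proteins) > 1L) {
    out$combined <- emit(tr_proteins, "combined", colors = cfg$tree$colors)
  }
  out
}
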