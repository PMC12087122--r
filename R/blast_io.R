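# Result tables: the per-seed container every downstream step consumes.
# One row per HSP; coordinates are 1-based inclusive exactly as delivered by
# BLAST XML2 and are never converted anywhere in the package.

HIT_COLUMNS <- c("subject_accession", "subject_taxid", "evalue", "bitscore",
                 "query_start", "query_end", "subject_length",
                 "aligned_subject_seq")

empty_hit_records <- function() {
  data.frame(
    subject_accession = character(0), subject_taxid = integer(0),
    evalue = numeric(0), bitscore = numeric(0),
    query_start = integer(0), query_end = integer(0),
    subject_length = integer(0), aligned_subject_seq = character(0),
    stringsAsFactors = FALSE
  )
}

#' Construct a per-seed result table
#'
#' @param protein logical protein name (as listed in `proteinlist.txt`).
#' @param seed_id identifier of the seed (query) sequence.
#' @param seed_length query length in amino acids.
#' @param records data.frame of hit records, one row per HSP, with columns
#'   `subject_accession`, `subject_taxid`, `evalue`, `bitscore`,
#'   `query_start`, `query_end`, `subject_length`, `aligned_subject_seq`.
#' @param skipped_hits number of hits dropped at parse time (e.g. missing
#'   taxid), kept as metadata.
#' @return an object of class `result_table`.
#' @export
result_table <- function(protein, seed_id, seed_length,
                         records = empty_hit_records(), skipped_hits = 0L) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing <- setdiff(HIT_COLUMNS, names(records))
  if ("aligned_subject_seq" %in% missing && nrow(records) == 0L) {
    records$aligned_subject_seq <- character(0)
    missing <- setdiff(missing, "aligned_subject_seq")
  }
  if (length(missing)) {
    stop_validation(sprintf("result table records missing column(s): %s",
                            paste(missing, collapse = ", ")))
  }
  records <- records[, HIT_COLUMNS]
  if (nrow(records)) {
    if (any(records$evalue < 0)) stop_validation("negative e-value in records")
    if (any(records$query_start < 1L | records$query_start > records$query_end)) {
      stop_validation("query coordinates must satisfy 1 <= start <= end")
    }
    if (any(records$subject_length < 1L)) {
      stop_validation("subject_length must be >= 1")
    }
  }
  rownames(records) <- NULL
  structure(
    list(protein = protein, seed_id = seed_id,
         seed_length = as.integer(seed_length), records = records,
         skipped_hits = as.integer(skipped_hits)),
    class = "result_table"
  )
}

#' @export
print.result_table <- function(x, ...) {
  cat(sprintf("result_table: protein %s, seed %s (%d aa), %d hit record(s)\n",
              x$protein, x$seed_id, x$seed_length, nrow(x$records)))
  invisible(x)
}

# descending significance: ascending e-value, ties by descending bitscore,
# then accession lexicographic (C locale for platform independence)
order_records <- function(records) {
  acc <- factor(records$subject_accession,
                levels = sort(unique(records$subject_accession), method = "radix"))
  order(records$evalue, -records$bitscore, acc, method = "radix")
}

#' Parse a BLAST XML2 result document
#'
#' Reads a single-query BLASTp result in the XML2 dialect (`-outfmt 14`;
#' root element `BlastXML2` or `BlastOutput2`) into a [result_table()]. One
#' record is produced per HSP; records are sorted by ascending e-value with
#' ties broken by descending bitscore and then accession. Hits lacking a
#' taxid are skipped with a warning and counted in the returned table's
#' `skipped_hits` field. Hits carrying several taxids (multispecies
#' proteins) keep the first; the remainder are reported in a warning.
#'
#' @param source path to an XML2 file, or its text.
#' @param protein logical protein name to stamp on the table.
#' @return a [result_table()].
#' @export
parse_blast_xml <- function(source, protein) {
  doc <- tryCatch(xml2::read_xml(source),
                  error = function(e) stop_format(
                    sprintf("not parseable as XML: %s", conditionMessage(e))))
  xml2::xml_ns_strip(doc)  # XML2 documents carry a default namespace
  search <- xml2::xml_find_first(doc, ".//Search")
  if (inherits(search, "xml_missing")) {
    stop_format("no <Search> element: not a BLAST XML2 result document")
  }
  seed_id <- xml2::xml_text(xml2::xml_find_first(search, "./query-title"))
  if (is.na(seed_id) || !nzchar(seed_id)) {
    seed_id <- xml2::xml_text(xml2::xml_find_first(search, "./query-id"))
  }
  seed_length <- as.integer(xml2::xml_text(
    xml2::xml_find_first(search, "./query-len")))
  if (is.na(seed_length)) stop_format("missing or non-integer <query-len>")

  hits <- xml2::xml_find_all(search, ".//hits/Hit")
  rows <- list()
  skipped <- 0L
  multi_taxid <- character(0)
  for (hit in hits) {
    descr <- xml2::xml_find_all(hit, "./description/HitDescr")
    if (!length(descr)) { skipped <- skipped + 1L; next }
    taxids <- as.integer(xml2::xml_text(xml2::xml_find_all(descr, "./taxid")))
    taxids <- taxids[!is.na(taxids)]
    accession <- xml2::xml_text(xml2::xml_find_first(descr[[1L]], "./accession"))
    if (!length(taxids)) { skipped <- skipped + 1L; next }
    if (length(taxids) > 1L) multi_taxid <- c(multi_taxid, accession)
    subject_length <- as.integer(xml2::xml_text(xml2::xml_find_first(hit, "./len")))
    hsps <- xml2::xml_find_all(hit, "./hsps/Hsp")
    for (hsp in hsps) {
      num <- function(xp) as.numeric(xml2::xml_text(xml2::xml_find_first(hsp, xp)))
      hseq <- xml2::xml_text(xml2::xml_find_first(hsp, "./hseq"))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_accession = accession,
        subject_taxid = taxids[1L],
        evalue = num("./evalue"),
        bitscore = num("./bit-score"),
        query_start = as.integer(num("./query-from")),
        query_end = as.integer(num("./query-to")),
        subject_length = subject_length,
        aligned_subject_seq = if (is.na(hseq)) "" else hseq,
        stringsAsFactors = FALSE
      )
    }
  }
  if (skipped > 0L) {
    warning(sprintf("%s/%s: skipped %d hit(s) without a taxid",
                    protein, seed_id, skipped), call. = FALSE)
  }
  if (length(multi_taxid)) {
    warning(sprintf("%s/%s: kept first taxid for multispecies hit(s): %s",
                    protein, seed_id, paste(multi_taxid, collapse = ", ")),
            call. = FALSE)
  }
  records <- if (length(rows)) do.call(rbind, rows) else empty_hit_records()
  if (nrow(records)) records <- records[order_records(records), , drop = FALSE]
  result_table(protein, seed_id, seed_length, records, skipped_hits = skipped)
}

fmt_num <- function(x) {
  # round-trip-exact numeric formatting ("." decimal, scientific e-values)
  vapply(x, function(v) sprintf("%.17g", v), "")
}

#' Write a result table as TSV
#'
#' Serialises a [result_table()] into the package's tab-separated dialect:
#' three `#`-prefixed metadata lines (protein, seed id, seed length), a
#' mandatory header row, then one row per record. Numbers use `.` decimals
#' and enough digits for bit-exact round trips. The aligned-sequence column
#' is written only when at least one record carries a sequence.
#'
#' @param table a [result_table()].
#' @param path output file path.
#' @return invisibly, the number of record rows written.
#' @export
write_result_table <- function(table, path) {
  stopifnot(inherits(table, "result_table"))
  rec <- table$records
  with_seq <- nrow(rec) > 0L && any(nzchar(rec$aligned_subject_seq))
  cols <- if (with_seq) HIT_COLUMNS else setdiff(HIT_COLUMNS, "aligned_subject_seq")
  lines <- c(
    sprintf("# protein: %s", table$protein),
    sprintf("# seed_id: %s", table$seed_id),
    sprintf("# seed_length: %d", table$seed_length),
    paste(cols, collapse = "\t")
  )
  if (nrow(rec)) {
    body <- cbind(
      rec$subject_accession, as.character(rec$subject_taxid),
      fmt_num(rec$evalue), fmt_num(rec$bitscore),
      as.character(rec$query_start), as.character(rec$query_end),
      as.character(rec$subject_length)
    )
    if (with_seq) body <- cbind(body, rec$aligned_subject_seq)
    lines <- c(lines, apply(body, 1L, paste, collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(nrow(rec))
}

#' Read a result table from TSV
#'
#' Inverse of [write_result_table()]; validates the header against the
#' documented column set and rejects non-numeric values in numeric columns.
#'
#' @param path path to a TSV written by [write_result_table()].
#' @return a [result_table()]; `aligned_subject_seq` is empty when the file
#'   was written without sequences.
#' @export
read_result_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^# ", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(sprintf("^# %s: ", key), meta, value = TRUE)
    if (!length(hit)) stop_format(sprintf("missing '# %s:' metadata line", key))
    sub(sprintf("^# %s: ", key), "", hit[1L])
  }
  protein <- get_meta("protein")
  seed_id <- get_meta("seed_id")
  seed_length <- as.integer(get_meta("seed_length"))
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop_format("missing header row")
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  required <- setdiff(HIT_COLUMNS, "aligned_subject_seq")
  missing <- setdiff(required, header)
  if (length(missing)) {
    stop_format(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  extra <- setdiff(header, HIT_COLUMNS)
  if (length(extra)) {
    stop_format(sprintf("unexpected column(s): %s", paste(extra, collapse = ", ")))
  }
  rows <- body[-1L]
  rows <- rows[nzchar(rows)]
  if (!length(rows)) {
    return(result_table(protein, seed_id, seed_length))
  }
  cells <- strsplit(rows, "\t", fixed = TRUE)
  if (any(lengths(cells) != length(header))) {
    stop_format("row with wrong number of fields")
  }
  m <- do.call(rbind, cells)
  colnames(m) <- header
  num_col <- function(col, label = col) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) stop_format(sprintf("non-numeric value in column %s", label))
    v
  }
  records <- data.frame(
    subject_accession = m[, "subject_accession"],
    subject_taxid = as.integer(num_col("subject_taxid")),
    evalue = num_col("evalue"),
    bitscore = num_col("bitscore"),
    query_start = as.integer(num_col("query_start")),
    query_end = as.integer(num_col("query_end")),
    subject_length = as.integer(num_col("subject_length")),
    aligned_subject_seq = if ("aligned_subject_seq" %in% header) {
      m[, "aligned_subject_seq"]
    } else {
      rep("", nrow(m))
    },
    stringsAsFactors = FALSE
  )
  result_table(protein, seed_id, seed_length, records)
}

#' Collect hit sequences into FASTA
#'
#' Extracts the aligned subject segments from a set of result tables (or
#' combined tables) into FASTA text for downstream alignment, stripping gap
#' characters. Headers are `>accession taxid protein`. With `dedupe = TRUE`
#' an accession occurring in several tables is emitted once, keeping the
#' occurrence with the lowest e-value.
#'
#' @param tables list of [result_table()] or [combined_table()] objects.
#' @param dedupe drop duplicate accessions, keeping the most significant?
#' @param strict error (rather than skip with a warning) on records with an
#'   empty aligned sequence?
#' @param path optional output file; when `NULL` the FASTA text is returned
#'   only.
#' @return character vector of FASTA lines, invisibly when `path` is given.
#' @export
blast2fasta <- function(tables, dedupe = TRUE, strict = FALSE, path = NULL) {
  pool <- lapply(tables, function(t) {
    rec <- t$records
    if (!nrow(rec)) return(NULL)
    data.frame(accession = rec$subject_accession, taxid = rec$subject_taxid,
               evalue = rec$evalue, seq = rec$aligned_subject_seq,
               protein = t$protein, stringsAsFactors = FALSE)
  })
  pool <- do.call(rbind, pool)
  if (is.null(pool) || !nrow(pool)) {
    out <- character(0)
    if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
    return(out)
  }
  empty <- !nzchar(pool$seq)
  if (any(empty)) {
    if (strict) {
      stop_validation(sprintf("record(s) with empty aligned sequence: %s",
                              paste(pool$accession[empty], collapse = ", ")))
    }
    warning(sprintf("skipped %d record(s) with empty aligned sequence",
                    sum(empty)), call. = FALSE)
    pool <- pool[!empty, , drop = FALSE]
  }
  pool <- pool[order(pool$evalue, pool$accession, method = "radix"), , drop = FALSE]
  if (dedupe) pool <- pool[!duplicated(pool$accession), , drop = FALSE]
  seqs <- gsub("-", "", pool$seq, fixed = TRUE)
  out <- as.vector(rbind(
    sprintf(">%s %d %s", pool$accession, pool$taxid, pool$protein), seqs))
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' BLASTp invocation wrapper (interface only)
#'
#' Builds and optionally executes a local or remote protein BLAST search
#' writing XML2 output. This is a convenience interface around an external
#' search step; the package's analysis never depends on it, and its
#' execution paths require an installed `blastp` executable (local mode) or
#' network access (remote mode). Defaults follow common practice for broad
#' presence scans: BLOSUM62, word size 6, gap open 11, gap extend 1,
#' e-value threshold 0.001, up to 20000 target sequences.
#'
#' @param seed_fasta path to the seed (query) FASTA file.
#' @param database BLAST database name, e.g. `"nr"`.
#' @param mode `"local"` (BLAST+ `blastp`) or `"remote"` (`-remote` flag).
#' @param out output XML2 path; defaults next to the input.
#' @param params named list overriding the defaults (`matrix`, `word_size`,
#'   `gapopen`, `gapextend`, `evalue`, `max_target_seqs`).
#' @param execute actually run the search? With `FALSE` (the default) the
#'   assembled command line is returned without side effects.
#' @return list with `command` (character vector of program + arguments),
#'   `params` (the effective parameter set) and `out`; when `execute = TRUE`
#'   and the run succeeds, the path to the XML2 file.
#' @export
run_blastp <- function(seed_fasta, database, mode = c("local", "remote"),
                       out = NULL, params = list(), execute = FALSE) {
  mode <- match.arg(mode)
  if (!is.character(database) || length(database) != 1L || !nzchar(database)) {
    stop_validation("database must be a non-empty string")
  }
  if (!is.character(seed_fasta) || length(seed_fasta) != 1L || !nzchar(seed_fasta)) {
    stop_validation("seed_fasta must be a non-empty path")
  }
  defaults <- list(matrix = "BLOSUM62", word_size = 6L, gapopen = 11L,
                   gapextend = 1L, evalue = 1e-3, max_target_seqs = 20000L)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop_validation(sprintf("unknown BLAST parameter(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  eff <- utils::modifyList(defaults, params)
  if (is.null(out)) {
    out <- paste0(tools::file_path_sans_ext(seed_fasta), ".xml")
  }
  args <- c("-query", seed_fasta, "-db", database,
            "-outfmt", "14", "-out", out,
            "-matrix", eff$matrix,
            "-word_size", as.character(eff$word_size),
            "-gapopen", as.character(eff$gapopen),
            "-gapextend", as.character(eff$gapextend),
            "-evalue", format(eff$evalue, scientific = TRUE),
            "-max_target_seqs", as.character(eff$max_target_seqs))
  if (mode == "remote") args <- c(args, "-remote")
  spec <- list(command = c("blastp", args), params = eff, out = out)
  if (!execute) return(spec)
  if (Sys.which("blastp") == "") {
    stop_environment("blastp executable not found on PATH")
  }
  status <- system2("blastp", args)
  if (!identical(status, 0L)) {
    if (file.exists(out)) unlink(out)  # atomic failure: no partial file
    stop_environment(sprintf("blastp exited with status %d", status))
  }
  out
}
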