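# Combination step: pool filtered per-seed tables into one table per
# protein and derive non-redundant organism listings.

#' Combined per-protein hit table
#'
#' Container produced by [combine_protein()]: all surviving records of one
#' protein pooled over its seeds, deduplicated by subject accession
#' (keeping the most significant occurrence), with each record assigned an
#' organism identity (species-collapsed taxid) and a per-organism best
#' record index.
#'
#' @param protein protein name.
#' @param records data.frame of hit records with the [result_table()]
#'   columns plus `seed_id` and `organism`.
#' @return object of class `combined_table`.
#' @export
combined_table <- function(protein, records) {
  stopifnot(is.data.frame(records))
  rownames(records) <- NULL
  best <- integer(0)
  if (nrow(records)) {
    split_idx <- split(seq_len(nrow(records)), records$organism)
    best <- vapply(split_idx, function(ix) ix[which.min(records$evalue[ix])], 0L)
  }
  structure(list(protein = protein, records = records,
                 best_by_organism = best),
            class = "combined_table")
}

#' @export
print.combined_table <- function(x, ...) {
  cat(sprintf("combined_table: protein %s, %d record(s), %d organism(s)\n",
              x$protein, nrow(x$records), length(x$best_by_organism)))
  invisible(x)
}

#' Combine filtered result tables for one protein
#'
#' Pools the records of all (filtered) per-seed tables of one protein,
#' deduplicates identical subject accessions hit by several seeds (the
#' minimum-e-value occurrence is kept, ties broken by higher bitscore then
#' seed order), re-sorts by ascending e-value, and assigns each record its
#' organism: the species-collapsed subject taxid ([species_of()]), or the
#' raw taxid with a warning when collapsing is disabled or the taxid is
#' unknown to the taxonomy.
#'
#' @param tables list of [result_table()] objects sharing one protein name.
#' @param db a `taxonomy_db`, used for species collapsing.
#' @param collapse_species collapse strain-level taxids onto their species
#'   (the default)? With `FALSE`, raw taxids are the organism identity.
#' @return a [combined_table()].
#' @export
combine_protein <- function(tables, db, collapse_species = TRUE) {
  if (inherits(tables, "result_table")) tables <- list(tables)
  if (!length(tables)) stop_validation("no tables to combine")
  proteins <- unique(vapply(tables, function(t) t$protein, ""))
  if (length(proteins) != 1L) {
    stop_validation(sprintf("mixed protein names in combine: %s",
                            paste(proteins, collapse = ", ")))
  }
  pooled <- do.call(rbind, lapply(tables, function(t) {
    rec <- t$records
    if (!nrow(rec)) return(NULL)
    rec$seed_id <- t$seed_id
    rec
  }))
  if (is.null(pooled) || !nrow(pooled)) {
    rec <- empty_hit_records()
    rec$seed_id <- character(0)
    rec$organism <- integer(0)
    return(combined_table(proteins, rec))
  }
  # drop exact (accession, seed) duplicates, then dedupe by accession
  pooled <- pooled[order(pooled$evalue, -pooled$bitscore,
                         pooled$subject_accession, method = "radix"), , drop = FALSE]
  pooled <- pooled[!duplicated(pooled[, c("subject_accession", "seed_id")]), ,
                   drop = FALSE]
  pooled <- pooled[!duplicated(pooled$subject_accession), , drop = FALSE]

  known <- pooled$subject_taxid %in% db$taxid
  if (any(!known)) {
    warning(sprintf("%s: %d record(s) with taxid unknown to the taxonomy kept uncollapsed: %s",
                    proteins, sum(!known),
                    paste(unique(pooled$subject_taxid[!known]), collapse = ", ")),
            call. = FALSE)
  }
  organism <- pooled$subject_taxid
  if (collapse_species && any(known)) {
    organism[known] <- species_of(db, pooled$subject_taxid[known])
  }
  pooled$organism <- organism
  combined_table(proteins, pooled)
}

#' Non-redundant organism listings
#'
#' Derives, for each combined table and overall, the sorted unique set of
#' organisms (taxid and scientific name) with at least one surviving hit.
#' Organisms whose taxid is unknown to the taxonomy are listed as
#' `"unknown taxid <n>"` with a warning.
#'
#' @param combined list of [combined_table()] objects (or one).
#' @param db a `taxonomy_db`.
#' @return list with `per_protein` (named list of data.frames `taxid`,
#'   `scientific_name`) and `overall` (the union, same shape).
#' @export
unique_organisms <- function(combined, db) {
  if (inherits(combined, "combined_table")) combined <- list(combined)
  names(combined) <- vapply(combined, function(x) x$protein, "")
  listing <- function(taxids) {
    taxids <- sort(unique(as.integer(taxids)))
    known <- taxids %in% db$taxid
    if (any(!known)) {
      warning(sprintf("organism listing: unknown taxid(s) %s",
                      paste(taxids[!known], collapse = ", ")), call. = FALSE)
    }
    nm <- character(length(taxids))
    nm[known] <- tax_name(db, taxids[known])
    nm[!known] <- sprintf("unknown taxid %d", taxids[!known])
    data.frame(taxid = taxids, scientific_name = nm, stringsAsFactors = FALSE)
  }
  per_protein <- lapply(combined, function(ct) listing(ct$records$organism))
  overall <- listing(unlist(lapply(combined, function(ct) ct$records$organism)))
  list(per_protein = per_protein, overall = overall)
}

#' Write organism listings as text files
#'
#' Emits `names_<protein>.txt` / `taxids_<protein>.txt` per protein plus
#' `names_all.txt` / `taxids_all.txt` for the overall union, one entry per
#' line.
#'
#' @param org result of [unique_organisms()].
#' @param dir output directory (conventionally `combinedtables/`).
#' @return invisibly, character vector of the files written.
#' @export
write_organism_listings <- function(org, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  emit <- function(df, label) {
    fn <- file.path(dir, sprintf("names_%s.txt", label))
    ft <- file.path(dir, sprintf("taxids_%s.txt", label))
    writeLines(df$scientific_name, fn)
    writeLines(as.character(df$taxid), ft)
    c(fn, ft)
  }
  for (p in names(org$per_protein)) {
    written <- c(written, emit(org$per_protein[[p]], p))
  }
  written <- c(written, emit(org$overall, "all"))
  invisible(written)
}

#' Write a combined table as TSV
#'
#' Same dialect as [write_result_table()], with additional `seed_id` and
#' `organism` columns.
#'
#' @param ct a [combined_table()].
#' @param path output path.
#' @return invisibly, the number of record rows written.
#' @export
write_combined_table <- function(ct, path) {
  rec <- ct$records
  cols <- c("subject_accession", "subject_taxid", "organism", "seed_id",
            "evalue", "bitscore", "query_start", "query_end", "subject_length")
  lines <- c(sprintf("# protein: %s", ct$protein),
             paste(cols, collapse = "\t"))
  if (nrow(rec)) {
    body <- cbind(rec$subject_accession, as.character(rec$subject_taxid),
                  as.character(rec$organism), rec$seed_id,
                  fmt_num(rec$evalue), fmt_num(rec$bitscore),
                  as.character(rec$query_start), as.character(rec$query_end),
                  as.character(rec$subject_length))
    lines <- c(lines, apply(body, 1L, paste, collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(nrow(rec))
}

#' Read a combined table from TSV
#'
#' @param path path written by [write_combined_table()].
#' @return a [combined_table()].
#' @export
read_combined_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^# protein: ", lines, value = TRUE)
  if (!length(meta)) stop_format("missing '# protein:' metadata line")
  protein <- sub("^# protein: ", "", meta[1L])
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  rows <- body[-1L]
  rows <- rows[nzchar(rows)]
  if (!length(rows)) {
    rec <- empty_hit_records()
    rec$seed_id <- character(0)
    rec$organism <- integer(0)
    return(combined_table(protein, rec))
  }
  m <- do.call(rbind, strsplit(rows, "\t", fixed = TRUE))
  colnames(m) <- header
  rec <- data.frame(
    subject_accession = m[, "subject_accession"],
    subject_taxid = as.integer(m[, "subject_taxid"]),
    evalue = as.numeric(m[, "evalue"]),
    bitscore = as.numeric(m[, "bitscore"]),
    query_start = as.integer(m[, "query_start"]),
    query_end = as.integer(m[, "query_end"]),
    subject_length = as.integer(m[, "subject_length"]),
    aligned_subject_seq = "",
    seed_id = m[, "seed_id"],
    organism = as.integer(m[, "organism"]),
    stringsAsFactors = FALSE
  )
  combined_table(protein, rec)
}
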