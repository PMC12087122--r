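#' Load a taxonomy from NCBI-style dump files
#'
#' Reads a pair of taxonomy dump files in the NCBI taxdump dialect (fields
#' separated by `"\t|\t"`, lines terminated by `"\t|"`) and builds an
#' in-memory taxonomy store. Only the first three fields of the nodes file
#' (taxid, parent taxid, rank) and names lines of class `"scientific name"`
#' are used; additional fields (as present in real `nodes.dmp` files) are
#' ignored, and rank strings are preserved verbatim.
#'
#' The root is the unique node whose parent taxid equals its own taxid. The
#' loader is strict: malformed lines, orphan nodes (parent absent from the
#' file), duplicate taxids, a missing or duplicated root, and parent cycles
#' are all errors. Ambiguous scientific names (the same name attached to
#' several taxids) are resolved to the lowest taxid with a warning.
#'
#' @param nodes_source path to a nodes dump file (or a character vector of
#'   its lines).
#' @param names_source path to a names dump file (or a character vector of
#'   its lines).
#' @return An object of class `taxonomy_db` with parallel vectors `taxid`,
#'   `parent`, `rank`, `name`, plus lookup indexes. Query it with
#'   [lineage()], [species_of()], [tax_name()], and [tax_rank()].
#' @seealso [write_taxonomy()] for the inverse operation.
#' @examples
#' nodes <- c("1\t|\t1\t|\tno rank\t|", "2\t|\t1\t|\tsuperkingdom\t|")
#' names <- c("1\t|\troot\t|\t\t|\tscientific name\t|",
#'            "2\t|\tBacteria\t|\t\t|\tscientific name\t|")
#' db <- load_taxonomy(nodes, names)
#' lineage(db, 2)
#' @export
load_taxonomy <- function(nodes_source, names_source) {
  node_lines <- read_dump_lines(nodes_source)
  name_lines <- read_dump_lines(names_source)

  nodes <- parse_dump_fields(node_lines, min_fields = 3L, what = "nodes")
  taxid <- suppressWarnings(as.integer(vapply(nodes, `[`, "", 1L)))
  parent <- suppressWarnings(as.integer(vapply(nodes, `[`, "", 2L)))
  rank <- vapply(nodes, `[`, "", 3L)
  bad <- which(is.na(taxid) | is.na(parent) | taxid <= 0L | parent <= 0L)
  if (length(bad)) {
    stop_parse(sprintf("nodes line %d: taxid/parent not a positive integer",
                       bad[1L]))
  }
  if (anyDuplicated(taxid)) {
    stop_structure(sprintf("duplicate taxid(s) in nodes: %s",
                           paste(unique(taxid[duplicated(taxid)]), collapse = ", ")))
  }

  orphans <- setdiff(parent, taxid)
  if (length(orphans)) {
    stop_structure(sprintf("orphan node(s): parent taxid(s) %s absent",
                           paste(sort(orphans), collapse = ", ")))
  }
  root <- taxid[taxid == parent]
  if (length(root) != 1L) {
    stop_structure(sprintf("expected exactly one self-parented root, found %d",
                           length(root)))
  }

  idx <- seq_along(taxid)
  names(idx) <- as.character(taxid)

  # cycle check: walk every node to the root, bounded by the node count
  pos_parent <- idx[as.character(parent)]
  for (i in seq_along(taxid)) {
    j <- i
    for (step in seq_len(length(taxid) + 1L)) {
      if (taxid[j] == parent[j]) break
      j <- pos_parent[j]
      if (step > length(taxid)) {
        stop_structure(sprintf("cycle detected walking parents from taxid %d",
                               taxid[i]))
      }
    }
  }

  name_fields <- parse_dump_fields(name_lines, min_fields = 4L, what = "names")
  n_taxid <- suppressWarnings(as.integer(vapply(name_fields, `[`, "", 1L)))
  n_name <- vapply(name_fields, `[`, "", 2L)
  n_class <- vapply(name_fields, `[`, "", 4L)
  if (anyNA(n_taxid)) {
    stop_parse(sprintf("names line %d: taxid not an integer",
                       which(is.na(n_taxid))[1L]))
  }
  keep <- n_class == "scientific name"
  n_taxid <- n_taxid[keep]
  n_name <- n_name[keep]

  name <- rep(NA_character_, length(taxid))
  known <- n_taxid %in% taxid
  name[idx[as.character(n_taxid[known])]] <- n_name[known]

  # name -> taxid index; ambiguous names resolve to the lowest taxid
  ord <- order(n_name[known], n_taxid[known])
  nm <- n_name[known][ord]
  nt <- n_taxid[known][ord]
  dup <- duplicated(nm)
  if (any(dup)) {
    warning(sprintf("ambiguous scientific name(s) resolved to lowest taxid: %s",
                    paste(unique(nm[dup]), collapse = ", ")), call. = FALSE)
  }
  name_index <- nt[!dup]
  names(name_index) <- nm[!dup]

  structure(
    list(taxid = taxid, parent = parent, rank = rank, name = name,
         root = root, index = idx, name_index = name_index),
    class = "taxonomy_db"
  )
}

read_dump_lines <- function(source) {
  if (length(source) == 1L && !grepl("\t", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
}

parse_dump_fields <- function(lines, min_fields, what) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_parse(sprintf("%s source is empty", what))
  stripped <- sub("\t\\|$", "", lines)
  fields <- strsplit(stripped, "\t\\|\t")
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    stop_parse(sprintf("%s line %d: expected at least %d fields, found %d",
                       what, which(nf < min_fields)[1L], min_fields,
                       nf[which(nf < min_fields)[1L]]))
  }
  fields
}

#' @export
print.taxonomy_db <- function(x, ...) {
  cat(sprintf("taxonomy_db: %d nodes, root taxid %d, %d indexed names\n",
              length(x$taxid), x$root, length(x$name_index)))
  invisible(x)
}

tax_pos <- function(db, taxid) {
  pos <- db$index[as.character(taxid)]
  if (anyNA(pos)) {
    missing <- taxid[is.na(pos)]
    stop_lookup(sprintf("unknown taxid(s): %s",
                        paste(missing, collapse = ", ")),
                taxid = missing)
  }
  unname(pos)
}

#' Taxon scientific name and rank by taxid
#'
#' @param db a `taxonomy_db` from [load_taxonomy()].
#' @param taxid integer vector of taxids present in `db`.
#' @return character vector of names (resp. ranks).
#' @export
tax_name <- function(db, taxid) db$name[tax_pos(db, taxid)]

#' @rdname tax_name
#' @export
tax_rank <- function(db, taxid) db$rank[tax_pos(db, taxid)]

#' Resolve a scientific name to a taxid
#'
#' Ambiguous names were resolved to the lowest taxid at load time.
#'
#' @inheritParams tax_name
#' @param name character vector of scientific names.
#' @return integer vector of taxids (`NA` for unknown names).
#' @export
tax_id_by_name <- function(db, name) {
  unname(db$name_index[name])
}

#' Full lineage of a taxon, root first
#'
#' Walks parent pointers from the query node up to the root and returns the
#' chain in root-to-query order.
#'
#' @inheritParams tax_name
#' @param taxid a single taxid present in `db`.
#' @return a data.frame with columns `taxid`, `parent_taxid`, `rank`,
#'   `scientific_name`; the first row is the root and the last the query.
#' @export
lineage <- function(db, taxid) {
  stopifnot(length(taxid) == 1L)
  pos <- tax_pos(db, taxid)
  chain <- pos
  while (db$taxid[pos] != db$parent[pos]) {
    pos <- unname(db$index[as.character(db$parent[pos])])
    chain <- c(pos, chain)
  }
  data.frame(
    taxid = db$taxid[chain],
    parent_taxid = db$parent[chain],
    rank = db$rank[chain],
    scientific_name = db$name[chain],
    stringsAsFactors = FALSE
  )
}

#' Collapse a taxid to its species
#'
#' Returns the nearest ancestor-or-self of rank `"species"`; taxids with no
#' species on their root path (e.g. genus-level hits) are returned
#' unchanged. Vectorised and idempotent, this is the organism-identity rule
#' used when counting unique organisms, so that strain-level hits collapse
#' onto one species.
#'
#' @inheritParams tax_name
#' @param taxid integer vector of taxids present in `db`.
#' @return integer vector of species-collapsed taxids.
#' @export
species_of <- function(db, taxid) {
  vapply(as.integer(taxid), function(t) {
    pos <- tax_pos(db, t)
    while (TRUE) {
      if (db$rank[pos] == "species") return(db$taxid[pos])
      if (db$taxid[pos] == db$parent[pos]) return(t)
      pos <- unname(db$index[as.character(db$parent[pos])])
    }
  }, integer(1L))
}

#' Write a taxonomy back to dump files
#'
#' Serialises a `taxonomy_db` in the same taxdump dialect accepted by
#' [load_taxonomy()], so that a load/write/load round trip reproduces the
#' node set.
#'
#' @inheritParams tax_name
#' @param nodes_path,names_path output file paths.
#' @return invisibly, a list with the two paths.
#' @export
write_taxonomy <- function(db, nodes_path, names_path) {
  node_lines <- sprintf("%d\t|\t%d\t|\t%s\t|", db$taxid, db$parent, db$rank)
  has_name <- !is.na(db$name)
  name_lines <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                        db$taxid[has_name], db$name[has_name])
  writeLines(node_lines, nodes_path)
  writeLines(name_lines, names_path)
  invisible(list(nodes = nodes_path, names = names_path))
}
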