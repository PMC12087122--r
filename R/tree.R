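# Taxonomic presence trees: map per-protein organism sets onto the
# taxonomy topology, count presence combinations per node, prune/collapse,
# and render pie-annotated trees plus Newick and per-node count tables.

#' Combination code of a presence flag vector
#'
#' Encodes which of up to three proteins an organism possesses as a bitmask
#' integer: protein `k` (in the configured order) contributes bit `k`, so a
#' 3-protein run uses codes 1..7. An organism present for no protein has no
#' code (it is excluded from the tree); this case returns `NA` rather than
#' a code.
#'
#' @param flags logical vector of length 1..3, one flag per protein in
#'   configured order.
#' @return integer code in `1..(2^length(flags) - 1)`, or `NA` if all
#'   flags are `FALSE`.
#' @examples
#' combo_code(c(TRUE, FALSE, FALSE))  # 1
#' combo_code(c(TRUE, TRUE, TRUE))    # 7
#' @export
combo_code <- function(flags) {
  if (length(flags) < 1L || length(flags) > 3L) {
    stop_validation("combo_code takes 1 to 3 presence flags")
  }
  if (!any(flags)) return(NA_integer_)
  as.integer(sum(2^(which(flags) - 1L)))
}

combo_label <- function(code, proteins) {
  bits <- which(bitwAnd(code, 2^(seq_along(proteins) - 1L)) > 0L)
  paste(proteins[bits], collapse = "+")
}

#' Annotate the taxonomy with protein presence
#'
#' Builds the union of the taxonomy lineages of every organism present for
#' at least one protein (the tree topology therefore follows the taxonomy,
#' not the hit sequences), assigns each organism its combination code, and
#' aggregates per-node counts bottom-up: a node's count for a code is the
#' number of organisms with that code in the node's subtree (the node
#' itself included when it is an organism). Organisms whose taxid is
#' unknown to the taxonomy are attached directly under the root with a
#' warning.
#'
#' @param db a `taxonomy_db`.
#' @param presence named list (1..3 entries), protein -> integer vector of
#'   organism taxids (species-collapsed); the list order fixes the bit
#'   positions of the combination codes.
#' @return object of class `annotated_tax_tree`: list with `nodes`
#'   (data.frame `taxid`, `parent`, `rank`, `name`), `children` (taxid ->
#'   sorted child taxids), `counts` (taxid -> integer vector over codes
#'   `1..2^p-1`), `total` (taxid -> organism count), `organism_codes`
#'   (organism taxid -> code), `proteins`, and `root`.
#' @export
annotate_tree <- function(db, presence) {
  if (!length(presence) || length(presence) > 3L) {
    stop_validation("presence must map 1 to 3 proteins")
  }
  proteins <- names(presence)
  if (is.null(proteins) || any(!nzchar(proteins))) {
    stop_validation("presence must be a named list")
  }
  presence <- lapply(presence, function(v) unique(as.integer(v)))
  organisms <- sort(unique(unlist(presence)))
  if (!length(organisms)) stop_validation("no hits to map")

  codes <- vapply(organisms, function(o) {
    combo_code(vapply(presence, function(set) o %in% set, TRUE))
  }, 0L)
  names(codes) <- as.character(organisms)

  known <- organisms %in% db$taxid
  if (any(!known)) {
    warning(sprintf("organism taxid(s) not in taxonomy, attached to root: %s",
                    paste(organisms[!known], collapse = ", ")), call. = FALSE)
  }

  ncodes <- 2L^length(proteins) - 1L
  nodes <- list()  # taxid(chr) -> c(parent, rank, name)
  counts <- list()
  total <- list()
  children <- list()
  add_node <- function(taxid, parent, rank, name) {
    key <- as.character(taxid)
    if (is.null(nodes[[key]])) {
      nodes[[key]] <<- list(parent = parent, rank = rank, name = name)
      counts[[key]] <<- integer(ncodes)
      total[[key]] <<- 0L
      if (taxid != parent) {
        pkey <- as.character(parent)
        children[[pkey]] <<- sort(unique(c(children[[pkey]], taxid)))
      }
    }
  }

  root <- db$root
  add_node(root, root, tax_rank(db, root), tax_name(db, root))
  for (k in seq_along(organisms)) {
    o <- organisms[k]
    if (known[k]) {
      lin <- lineage(db, o)
      for (r in seq_len(nrow(lin))) {
        add_node(lin$taxid[r], lin$parent_taxid[r], lin$rank[r],
                 lin$scientific_name[r])
      }
      path <- lin$taxid
    } else {
      add_node(o, root, "no rank", sprintf("unknown taxid %d", o))
      path <- c(root, o)
    }
    code <- codes[[as.character(o)]]
    for (t in path) {
      key <- as.character(t)
      counts[[key]][code] <- counts[[key]][code] + 1L
      total[[key]] <- total[[key]] + 1L
    }
  }

  keys <- names(nodes)
  node_df <- data.frame(
    taxid = as.integer(keys),
    parent = vapply(nodes, function(n) as.integer(n$parent), 0L),
    rank = vapply(nodes, function(n) n$rank, ""),
    name = vapply(nodes, function(n) n$name, ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(nodes = node_df, children = children,
                 counts = counts, total = unlist(total),
                 organism_codes = codes, proteins = proteins, root = root),
            class = "annotated_tax_tree")
}

#' @export
print.annotated_tax_tree <- function(x, ...) {
  cat(sprintf("annotated_tax_tree: %d node(s), %d organism(s), proteins: %s\n",
              nrow(x$nodes), x$total[[as.character(x$root)]],
              paste(x$proteins, collapse = ", ")))
  invisible(x)
}

tree_descendants <- function(tree, taxid) {
  out <- integer(0)
  queue <- tree$children[[as.character(taxid)]]
  while (length(queue)) {
    out <- c(out, queue)
    queue <- unlist(lapply(as.character(queue), function(k) tree$children[[k]]))
  }
  out
}

resolve_in_tree <- function(tree, entry) {
  entry <- trimws(entry)
  if (grepl("^[0-9]+$", entry)) {
    t <- as.integer(entry)
    if (t %in% tree$nodes$taxid) return(t)
  } else {
    hit <- tree$nodes$taxid[tree$nodes$name == entry]
    if (length(hit)) return(hit[1L])
  }
  NA_integer_
}

#' Prune and partition an annotated tree
#'
#' Applies a prune configuration: taxa named for collapsing become terminal
#' nodes that retain their aggregated counts (their subtrees are dropped),
#' and an optional partition restricts the tree to the subtree rooted at
#' one taxon (e.g. a single superkingdom). Entries that do not resolve to a
#' node of the tree are skipped with a warning, except a non-resolving
#' partition, which would prune away the entire tree and is an error.
#'
#' @param tree an [annotate_tree()] result.
#' @param prune_config list with `collapse` (character vector of taxids or
#'   scientific names) and `partition` (single taxid/name or `NULL`), as
#'   returned by [read_prune_config()]. An empty configuration returns the
#'   tree unchanged.
#' @return a pruned `annotated_tax_tree`.
#' @export
prune_tree <- function(tree, prune_config = list(collapse = character(0),
                                                 partition = NULL)) {
  collapse <- prune_config$collapse %||% character(0)
  partition <- prune_config$partition

  root <- tree$root
  keep <- tree$nodes$taxid
  if (!is.null(partition)) {
    part <- resolve_in_tree(tree, partition)
    if (is.na(part)) {
      stop_validation(sprintf(
        "partition '%s' does not resolve in the tree: pruning would remove everything",
        partition))
    }
    keep <- c(part, tree_descendants(tree, part))
    root <- part
  }

  drop <- integer(0)
  for (entry in collapse) {
    t <- resolve_in_tree(tree, entry)
    if (is.na(t) || !(t %in% keep)) {
      warning(sprintf("prune entry '%s' does not resolve in the tree; skipped",
                      entry), call. = FALSE)
      next
    }
    drop <- c(drop, tree_descendants(tree, t))
  }
  keep <- setdiff(keep, drop)

  sel <- tree$nodes$taxid %in% keep
  node_df <- tree$nodes[sel, , drop = FALSE]
  rownames(node_df) <- NULL
  node_df$parent[node_df$taxid == root] <- root
  keys <- as.character(node_df$taxid)
  children <- lapply(tree$children[keys], function(v) v[v %in% keep])
  children <- children[vapply(children, length, 0L) > 0L]
  structure(list(nodes = node_df, children = children,
                 counts = tree$counts[keys],
                 total = tree$total[keys],
                 organism_codes = tree$organism_codes,
                 proteins = tree$proteins, root = root),
            class = "annotated_tax_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read tree_config.txt
#'
#' `key = value` lines: `proteins` is the ordered, comma-separated list of
#' up to three proteins to map (the order defines the combination-code bit
#' positions and legend order), `colors` an optional comma-separated list
#' of `2^p - 1` pie colors.
#'
#' @param path path to the configuration file.
#' @return list with `proteins` (character) and `colors` (character or
#'   `NULL` for the default palette).
#' @export
read_tree_config <- function(path) {
  kv <- read_key_values(path)
  proteins <- character(0)
  if (!is.null(kv$proteins)) {
    proteins <- trimws(strsplit(kv$proteins, ",", fixed = TRUE)[[1L]])
  }
  if (length(proteins) > 3L) {
    stop_config(sprintf("tree_config: at most 3 proteins, found %d",
                        length(proteins)))
  }
  colors <- NULL
  if (!is.null(kv$colors)) {
    colors <- trimws(strsplit(kv$colors, ",", fixed = TRUE)[[1L]])
  }
  list(proteins = proteins, colors = colors)
}

#' Read tree_to_prune.txt
#'
#' One taxid or scientific name per line (taxa to collapse); an optional
#' `partition: <taxon>` line restricts the tree to that subtree. Blank
#' lines and `#` comments are ignored.
#'
#' @param path path to the configuration file.
#' @return list with `collapse` and `partition` for [prune_tree()].
#' @export
read_prune_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  part_lines <- grepl("^partition\\s*:", lines)
  partition <- NULL
  if (any(part_lines)) {
    partition <- trimws(sub("^partition\\s*:", "", lines[part_lines][1L]))
  }
  list(collapse = lines[!part_lines], partition = partition)
}

DEFAULT_TREE_COLORS <- c("#e41a1c", "#377eb8", "#984ea3",
                         "#4daf4a", "#ff7f00", "#a65628", "#f781bf")

sanitize_label <- function(x) gsub("[][ ,:;()']+", "_", x)

#' Newick serialisation of an annotated tree
#'
#' Leaf and internal labels are `<scientific name>_<taxid>` with
#' Newick-unsafe characters replaced by underscores; children are emitted
#' in ascending taxid order for determinism.
#'
#' @param tree an `annotated_tax_tree`.
#' @return single Newick string (terminated by `;`).
#' @export
newick_string <- function(tree) {
  node_name <- function(taxid) {
    i <- match(taxid, tree$nodes$taxid)
    sanitize_label(sprintf("%s_%d", tree$nodes$name[i], taxid))
  }
  rec <- function(taxid) {
    kids <- tree$children[[as.character(taxid)]]
    if (is.null(kids) || !length(kids)) return(node_name(taxid))
    paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")",
           node_name(taxid))
  }
  paste0(rec(tree$root), ";")
}

#' Per-node count table of an annotated tree
#'
#' @param tree an `annotated_tax_tree`.
#' @return data.frame with one row per node: `taxid`, `name`, `rank`,
#'   `parent`, `total_organisms`, and one `combo_<label>` column per
#'   combination code in code order.
#' @export
node_counts <- function(tree) {
  ncodes <- 2L^length(tree$proteins) - 1L
  keys <- as.character(tree$nodes$taxid)
  cm <- do.call(rbind, tree$counts[keys])
  colnames(cm) <- vapply(seq_len(ncodes), function(code) {
    sprintf("combo_%s", combo_label(code, tree$proteins))
  }, "")
  df <- data.frame(taxid = tree$nodes$taxid, name = tree$nodes$name,
                   rank = tree$nodes$rank, parent = tree$nodes$parent,
                   total_organisms = unname(tree$total[keys]),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(cm, row.names = NULL))
}

#' Render an annotated tree
#'
#' Writes up to three artefacts: a pie-annotated cladogram (PDF/PNG), the
#' Newick topology, and the per-node counts TSV (the machine-checkable
#' surface). Each node's pie splits the full circle by
#' `count(code)/total`, and the pie radius grows with `sqrt(total)`
#' (clamped), so pie area is proportional to the number of organisms in
#' the subtree.
#'
#' @param tree an `annotated_tax_tree`.
#' @param colors pie colors, one per combination code (`2^p - 1` values);
#'   `NULL` uses the default palette.
#' @param graphic_path,newick_path,counts_path output paths; `NULL` skips
#'   that artefact.
#' @param radius_scale multiplier of `sqrt(total)` for the pie radius, in
#'   display units (points).
#' @param radius_clamp two-element `c(min, max)` radius clamp in points.
#' @param min_pie_total suppress pies at nodes with fewer organisms.
#' @return invisibly, a named list of the paths written.
#' @export
render_tree <- function(tree, colors = NULL, graphic_path = NULL,
                        newick_path = NULL, counts_path = NULL,
                        radius_scale = 4, radius_clamp = c(4, 40),
                        min_pie_total = 1L) {
  ncodes <- 2L^length(tree$proteins) - 1L
  if (is.null(colors)) colors <- DEFAULT_TREE_COLORS[seq_len(ncodes)]
  if (length(colors) != ncodes) {
    stop_config(sprintf("need %d pie colors for %d protein(s), got %d",
                        ncodes, length(tree$proteins), length(colors)))
  }
  out <- list()
  if (!is.null(newick_path)) {
    writeLines(newick_string(tree), newick_path)
    out$newick <- newick_path
  }
  if (!is.null(counts_path)) {
    df <- node_counts(tree)
    utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$counts <- counts_path
  }
  if (!is.null(graphic_path)) {
    draw_tree_graphic(tree, colors, graphic_path, radius_scale,
                      radius_clamp, min_pie_total)
    out$graphic <- graphic_path
  }
  invisible(out)
}

draw_tree_graphic <- function(tree, colors, path, radius_scale,
                              radius_clamp, min_pie_total) {
  # cladogram layout: leaves on a vertical axis, depth on the horizontal
  ys <- numeric(0)
  xs <- numeric(0)
  leaf_y <- 0
  pos <- new.env(parent = emptyenv())
  layout <- function(taxid, depth) {
    kids <- tree$children[[as.character(taxid)]]
    if (is.null(kids) || !length(kids)) {
      leaf_y <<- leaf_y + 1
      y <- leaf_y
    } else {
      y <- mean(vapply(kids, layout, 0, depth = depth + 1))
    }
    assign(as.character(taxid), c(depth, y), envir = pos)
    y
  }
  layout(tree$root, 0)
  n_leaves <- leaf_y
  max_depth <- max(vapply(ls(pos), function(k) get(k, envir = pos)[1L], 0))

  open_device(path)
  on.exit(grDevices.dev_off())
  graphics::par(mar = c(1, 1, 2, 12), xpd = NA)
  graphics::plot(NULL, xlim = c(0, max_depth + 0.5), ylim = c(0, n_leaves + 1),
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("Presence of %s on the taxonomy",
                                paste(tree$proteins, collapse = ", ")))
  usr <- graphics::par("usr")
  pin <- graphics::par("pin")
  pt_x <- diff(usr[1:2]) / (pin[1L] * 72)  # user units per point
  pt_y <- diff(usr[3:4]) / (pin[2L] * 72)

  draw_node <- function(taxid) {
    key <- as.character(taxid)
    p <- get(key, envir = pos)
    kids <- tree$children[[key]]
    if (!is.null(kids) && length(kids)) {
      kid_pos <- vapply(kids, function(k) get(as.character(k), envir = pos),
                        numeric(2))
      graphics::segments(p[1L], min(kid_pos[2L, ]), p[1L], max(kid_pos[2L, ]),
                         col = "grey50")
      graphics::segments(p[1L], kid_pos[2L, ], kid_pos[1L, ], kid_pos[2L, ],
                         col = "grey50")
      for (k in kids) draw_node(k)
    } else {
      i <- match(taxid, tree$nodes$taxid)
      graphics::text(p[1L] + 12 * pt_x, p[2L], tree$nodes$name[i],
                     adj = c(0, 0.5), cex = 0.55)
    }
    tot <- tree$total[[key]]
    if (tot >= min_pie_total) {
      r_pt <- min(max(radius_scale * sqrt(tot), radius_clamp[1L]),
                  radius_clamp[2L])
      draw_pie(p[1L], p[2L], r_pt * pt_x, r_pt * pt_y,
               tree$counts[[key]], colors)
    }
  }
  draw_node(tree$root)

  labels <- vapply(seq_along(colors), function(code) {
    combo_label(code, tree$proteins)
  }, "")
  graphics::legend("topright", inset = c(-0.25, 0), legend = labels,
                   fill = colors, cex = 0.7, bty = "n",
                   title = "presence combination")
}

draw_pie <- function(x, y, rx, ry, counts, colors) {
  total <- sum(counts)
  if (total == 0L) return(invisible())
  angles <- 2 * pi * c(0, cumsum(counts) / total)
  for (k in seq_along(counts)) {
    if (counts[k] == 0L) next
    theta <- seq(angles[k], angles[k + 1L], length.out = 64L)
    theta <- pi / 2 - theta  # start at 12 o'clock, clockwise
    graphics::polygon(c(x, x + rx * cos(theta)), c(y, y + ry * sin(theta)),
                      col = colors[k], border = "grey20", lwd = 0.3)
  }
}
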