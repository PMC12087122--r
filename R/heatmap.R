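# Heatmap building: capped -log10(e-value) significance scores, organism x
# protein score matrix, deterministic agglomerative clustering of both
# axes, and a self-contained interactive HTML rendering.

#' Integer significance score of an e-value
#'
#' Maps an e-value to the integer score stored in the heatmap matrix:
#' `floor(-log10(evalue))` clamped to `[0, 200]`. An e-value of exactly 0
#' maps to the cap (200); e-values of 1 or more map to 0. The score is a
#' bounded, monotone non-increasing measure of hit significance.
#'
#' @param evalue numeric vector of non-negative e-values.
#' @return integer vector of scores in `[0, 200]`.
#' @examples
#' significance_score(c(1e-30, 1e-250, 0.5, 0))
#' @export
significance_score <- function(evalue) {
  if (any(evalue < 0)) stop_validation("e-values must be non-negative")
  score <- rep(200, length(evalue))
  nz <- evalue > 0
  score[nz] <- pmin(200, pmax(0, floor(-log10(evalue[nz]))))
  as.integer(score)
}

VALID_LINKAGES <- c("single", "complete", "average", "weighted",
                    "centroid", "median", "ward")

#' Heatmap configuration
#'
#' @param organisms character or integer vector selecting the organisms to
#'   show (taxids, or scientific names resolved against the taxonomy).
#' @param linkage hierarchical clustering linkage method; one of `single`,
#'   `complete`, `average`, `weighted`, `centroid`, `median`, `ward`.
#'   Default `"centroid"`.
#' @param colors length-2 character vector: color ramp endpoints for the
#'   relative (grayscale) view, absent through most significant.
#' @param slider_default default e-value exponent of the absolute-view
#'   slider (a cell is shown when its score is at least this threshold).
#' @return object of class `heatmap_config`.
#' @export
heatmap_config <- function(organisms = character(0), linkage = "centroid",
                           colors = c("#ffffff", "#000000"),
                           slider_default = 30L) {
  if (!(linkage %in% VALID_LINKAGES)) {
    stop_config(sprintf("unknown linkage '%s'; valid options: %s",
                        linkage, paste(VALID_LINKAGES, collapse = ", ")))
  }
  if (length(colors) != 2L) stop_config("colors must be 2 ramp endpoints")
  structure(list(organisms = organisms, linkage = linkage, colors = colors,
                 slider_default = as.integer(slider_default)),
            class = "heatmap_config")
}

#' Read heatmap_config.txt
#'
#' `key = value` lines; recognised keys are `organisms` (comma-separated
#' taxids or names), `linkage`, `colors` (two comma-separated values), and
#' `slider_default`. Blank lines and `#` comments are ignored; an empty
#' file yields the defaults (centroid linkage, slider 30).
#'
#' @param path path to the configuration file.
#' @return a [heatmap_config()].
#' @export
read_heatmap_config <- function(path) {
  kv <- read_key_values(path)
  args <- list()
  if (!is.null(kv$organisms)) {
    args$organisms <- trimws(strsplit(kv$organisms, ",", fixed = TRUE)[[1L]])
  }
  if (!is.null(kv$linkage)) args$linkage <- kv$linkage
  if (!is.null(kv$colors)) {
    args$colors <- trimws(strsplit(kv$colors, ",", fixed = TRUE)[[1L]])
  }
  if (!is.null(kv$slider_default)) {
    v <- suppressWarnings(as.integer(kv$slider_default))
    if (is.na(v)) stop_config("slider_default must be an integer")
    args$slider_default <- v
  }
  do.call(heatmap_config, args)
}

read_key_values <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (i in seq_along(lines)) {
    if (!grepl("=", lines[i], fixed = TRUE)) {
      stop_config(sprintf("%s line %d: expected 'key = value'",
                          basename(path), i))
    }
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    kv[[trimws(parts[1L])]] <- trimws(paste(parts[-1L], collapse = "="))
  }
  kv
}

#' Build the organism x protein score matrix
#'
#' For every selected organism and every protein, looks up the best
#' (minimum) e-value among the protein's combined records whose organism
#' (species-collapsed taxid) matches, and stores its
#' [significance_score()]; cells without any hit are 0. Selected organisms
#' are resolved against the taxonomy (names via the name index, taxids
#' collapsed to species); organisms that cannot be resolved produce an
#' all-zero row and a warning, not an error. Selection order is preserved.
#'
#' @param combined list of [combined_table()] objects.
#' @param config a [heatmap_config()] with a non-empty organism selection.
#' @param db a `taxonomy_db`.
#' @return object of class `score_matrix`: an integer matrix (organisms x
#'   proteins) with taxids as rownames, plus attributes `display_names`
#'   (organism names) and `evalues` (matrix of best e-values, `NA` when
#'   absent).
#' @export
build_score_matrix <- function(combined, config, db) {
  if (inherits(combined, "combined_table")) combined <- list(combined)
  sel <- config$organisms
  if (!length(sel)) stop_validation("organism selection is empty")
  proteins <- vapply(combined, function(x) x$protein, "")

  resolve_one <- function(s) {
    s_chr <- as.character(s)
    if (grepl("^[0-9]+$", s_chr)) {
      t <- as.integer(s_chr)
      if (t %in% db$taxid) {
        list(taxid = species_of(db, t), name = tax_name(db, species_of(db, t)))
      } else {
        warning(sprintf("selected organism taxid %d not in taxonomy; all-zero row", t),
                call. = FALSE)
        list(taxid = NA_integer_, name = sprintf("unknown taxid %d", t))
      }
    } else {
      t <- tax_id_by_name(db, s_chr)
      if (is.na(t)) {
        warning(sprintf("selected organism '%s' not in taxonomy; all-zero row", s_chr),
                call. = FALSE)
        list(taxid = NA_integer_, name = s_chr)
      } else {
        list(taxid = species_of(db, t), name = s_chr)
      }
    }
  }
  resolved <- lapply(sel, resolve_one)
  taxids <- vapply(resolved, function(r) r$taxid, 0L)
  display <- vapply(resolved, function(r) r$name, "")

  scores <- matrix(0L, nrow = length(sel), ncol = length(proteins),
                   dimnames = list(as.character(taxids), proteins))
  evalues <- matrix(NA_real_, nrow = length(sel), ncol = length(proteins),
                    dimnames = dimnames(scores))
  for (j in seq_along(proteins)) {
    rec <- combined[[j]]$records
    if (!nrow(rec)) next
    best <- tapply(rec$evalue, rec$organism, min)
    hit <- match(taxids, as.integer(names(best)))
    has <- !is.na(hit)
    evalues[has, j] <- unname(best[hit[has]])
    scores[has, j] <- significance_score(evalues[has, j])
  }
  structure(scores, display_names = display, evalues = evalues,
            class = c("score_matrix", "matrix", "array"))
}

#' Write a score matrix as TSV
#'
#' Tabular companion of the heatmap: one row per organism with its taxid,
#' display name, and the integer score per protein.
#'
#' @param m a [build_score_matrix()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_score_matrix <- function(m, path) {
  proteins <- colnames(m)
  lines <- c(paste(c("taxid", "organism", proteins), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], attr(m, "display_names")[i],
                       as.character(unclass(m)[i, ])), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Cluster the heatmap axes
#'
#' Agglomerative hierarchical clustering of the score matrix rows
#' (organisms) and columns (proteins) with a deterministic tie-break:
#' equal-distance merges are resolved in favour of the earliest-created
#' cluster pair, and each merge places the subtree containing the smaller
#' original index on the left, so leaf orders are reproducible across runs
#' and platforms. Distances are Euclidean on score vectors; `centroid`,
#' `median` and `ward` follow their geometric definitions (distance
#' between centroids / recursive midpoints / Ward's SSE-increase form).
#' Axes with fewer than 2 elements pass through in input order with an
#' empty dendrogram.
#'
#' @param m a [build_score_matrix()] result (or plain numeric matrix).
#' @param linkage linkage method (see [heatmap_config()]).
#' @return list with `row` and `col`, each a list `order` (leaf order as
#'   input indices), `merge` (hclust-convention merge matrix or `NULL`),
#'   `height`, `labels`.
#' @export
cluster_axes <- function(m, linkage = "centroid") {
  if (!(linkage %in% VALID_LINKAGES)) {
    stop_config(sprintf("unknown linkage '%s'; valid options: %s",
                        linkage, paste(VALID_LINKAGES, collapse = ", ")))
  }
  x <- unclass(m)
  row_labels <- rownames(x)
  col_labels <- colnames(x)
  list(row = agglomerate(x, linkage, labels = row_labels),
       col = agglomerate(t(x), linkage, labels = col_labels))
}

# Deterministic agglomerative clustering. Clusters are identified by
# creation order (originals first, merges after); ties in the minimum
# distance go to the earliest pair, and each merge puts the subtree with
# the smaller minimum original index on the left.
agglomerate <- function(x, linkage, labels = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 2L) {
    return(list(order = seq_len(n), merge = NULL, height = NULL,
                labels = labels, linkage = linkage))
  }
  euclid <- function(a, b) sqrt(sum((a - b)^2))

  size <- rep(1, n)
  centroid <- lapply(seq_len(n), function(i) x[i, ])
  midpoint <- centroid  # recursive midpoints for median linkage
  min_idx <- seq_len(n)
  leaves <- as.list(seq_len(n))
  hid <- -seq_len(n)    # hclust-convention ids
  active <- rep(TRUE, n)

  D <- as.matrix(stats::dist(x))
  diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    dmin <- min(sub)
    eps <- 1e-9 * max(1, abs(dmin))
    pick <- NULL
    for (ii in seq_along(act)) {        # earliest-created pair wins ties
      jj <- which(sub[ii, ] <= dmin + eps)
      jj <- jj[jj > ii]
      if (length(jj)) { pick <- c(act[ii], act[jj[1L]]); break }
    }
    i <- pick[1L]; j <- pick[2L]

    new_size <- size[i] + size[j]
    new_centroid <- (size[i] * centroid[[i]] + size[j] * centroid[[j]]) / new_size
    new_midpoint <- (midpoint[[i]] + midpoint[[j]]) / 2
    left_first <- min_idx[i] <= min_idx[j]
    new_leaves <- if (left_first) c(leaves[[i]], leaves[[j]]) else c(leaves[[j]], leaves[[i]])

    merge[step, ] <- c(hid[i], hid[j])
    height[step] <- dmin

    # grow the state by one cluster slot
    k_new <- length(size) + 1L
    size <- c(size, new_size)
    centroid[[k_new]] <- new_centroid
    midpoint[[k_new]] <- new_midpoint
    min_idx <- c(min_idx, min(min_idx[i], min_idx[j]))
    leaves[[k_new]] <- new_leaves
    hid <- c(hid, step)
    active[i] <- FALSE; active[j] <- FALSE
    active <- c(active, TRUE)

    D <- rbind(cbind(D, Inf), Inf)
    for (k in which(active)) {
      if (k == k_new) next
      dnew <- switch(linkage,
        single   = min(D[i, k], D[j, k]),
        complete = max(D[i, k], D[j, k]),
        average  = (size[i] * D[i, k] + size[j] * D[j, k]) / new_size,
        weighted = (D[i, k] + D[j, k]) / 2,
        centroid = euclid(new_centroid, centroid[[k]]),
        median   = euclid(new_midpoint, midpoint[[k]]),
        ward     = sqrt(2 * new_size * size[k] / (new_size + size[k])) *
                     euclid(new_centroid, centroid[[k]])
      )
      D[k_new, k] <- D[k, k_new] <- dnew
    }
    D[k_new, k_new] <- Inf
  }
  list(order = leaves[[length(leaves)]], merge = merge, height = height,
       labels = labels, linkage = linkage)
}

#' Render the interactive HTML heatmap
#'
#' Writes a self-contained HTML document (no external assets) showing the
#' clustered score matrix. The page supports a relative view (grayscale
#' proportional to score/200), an absolute view (a cell is black iff its
#' score is at least the slider threshold, boundary inclusive), an e-value
#' exponent slider enabled only in the absolute view, an
#' alphabetical-vs-clustered column order toggle, and a per-cell tooltip
#' showing the best hit's e-value. The matrix, orders and settings are
#' embedded as structured JSON (in the `heatmap-data` script element) so
#' the document's semantics are machine-checkable without a browser.
#'
#' @param m a [build_score_matrix()] result.
#' @param orders a [cluster_axes()] result for `m`.
#' @param config a [heatmap_config()].
#' @param path output HTML path.
#' @return invisibly, `path`.
#' @export
render_heatmap <- function(m, orders, config, path) {
  scores <- unclass(m)
  if (!identical(sort(orders$row$order), seq_len(nrow(scores))) ||
      !identical(sort(orders$col$order), seq_len(ncol(scores)))) {
    stop_validation("cluster orders do not match matrix shape")
  }
  ev <- attr(m, "evalues")
  ev_chr <- matrix(NA_character_, nrow(scores), ncol(scores))
  ev_chr[!is.na(ev)] <- sprintf("%.2e", ev[!is.na(ev)])
  proteins <- colnames(scores)
  payload <- list(
    organisms = data.frame(taxid = rownames(scores),
                           name = attr(m, "display_names"),
                           stringsAsFactors = FALSE),
    proteins = proteins,
    scores = unname(apply(scores, 1L, function(r) as.integer(r), simplify = FALSE)),
    evalues = unname(apply(ev_chr, 1L, function(r) as.list(r), simplify = FALSE)),
    row_order = orders$row$order,
    col_order = orders$col$order,
    col_order_alpha = order(proteins, method = "radix"),
    slider_default = config$slider_default,
    colors = config$colors,
    score_cap = 200L
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null", na = "null")
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>Protein presence heatmap</title>",
    "<style>",
    "body{font-family:sans-serif;margin:1em}",
    "table{border-collapse:collapse}",
    "td.cell{width:18px;height:18px;border:1px solid #ddd}",
    "td.lab{padding:0 6px;font-size:11px;white-space:nowrap}",
    "th{font-size:11px;writing-mode:vertical-rl;padding:4px 2px}",
    "#controls{margin-bottom:1em}",
    "</style></head><body>",
    "<h2>Protein presence heatmap</h2>",
    "<div id=\"controls\">",
    "<button id=\"toggle-view\">view: relative</button>",
    "<button id=\"toggle-order\">columns: clustered</button>",
    "<label> e-value exponent <input id=\"slider\" type=\"range\" min=\"0\" max=\"200\" disabled>",
    "<span id=\"slider-val\"></span></label>",
    "</div>",
    "<div id=\"heatmap\"></div>",
    paste0("<script id=\"heatmap-data\" type=\"application/json\">", json,
           "</script>"),
    "<script>",
    "var data=JSON.parse(document.getElementById('heatmap-data').textContent);",
    "var absolute=false,clustered=true;",
    "var slider=document.getElementById('slider');",
    "slider.value=data.slider_default;",
    "document.getElementById('slider-val').textContent='1e-'+slider.value;",
    "function colOrder(){return clustered?data.col_order:data.col_order_alpha;}",
    "function cellColor(s){",
    " if(absolute){return s>=Number(slider.value)?'#000000':'#ffffff';}",
    " var g=Math.round(255*(1-s/data.score_cap));",
    " return 'rgb('+g+','+g+','+g+')';}",
    "function render(){",
    " var co=colOrder();var h='<table><tr><td></td>';",
    " co.forEach(function(j){h+='<th>'+data.proteins[j-1]+'</th>';});",
    " h+='</tr>';",
    " data.row_order.forEach(function(i){",
    "  h+='<tr><td class=\"lab\">'+data.organisms.name[i-1]+'</td>';",
    "  co.forEach(function(j){",
    "   var s=data.scores[i-1][j-1];var e=data.evalues[i-1][j-1];",
    "   h+='<td class=\"cell\" title=\"'+(e===null?'no hit':'best e-value '+e)+",
    "    '\" style=\"background:'+cellColor(s)+'\"></td>';});",
    "  h+='</tr>';});",
    " h+='</table>';document.getElementById('heatmap').innerHTML=h;}",
    "document.getElementById('toggle-view').onclick=function(){",
    " absolute=!absolute;this.textContent='view: '+(absolute?'absolute':'relative');",
    " slider.disabled=!absolute;render();};",
    "document.getElementById('toggle-order').onclick=function(){",
    " clustered=!clustered;this.textContent='columns: '+(clustered?'clustered':'alphabetical');",
    " render();};",
    "slider.oninput=function(){",
    " document.getElementById('slider-val').textContent='1e-'+this.value;render();};",
    "render();",
    "</script></body></html>"
  )
  writeLines(html, path)
  invisible(path)
}

#' Extract the embedded data of a rendered heatmap
#'
#' Parses the JSON payload embedded by [render_heatmap()], allowing the
#' document's semantics (scores, orders, slider default) to be inspected
#' programmatically.
#'
#' @param path path to a heatmap HTML file.
#' @return the embedded payload as a list.
#' @export
read_heatmap_data <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  m <- regmatches(txt, regexpr(
    "<script id=\"heatmap-data\" type=\"application/json\">.*?</script>", txt))
  if (!length(m)) stop_format("no embedded heatmap data found")
  json <- sub("^<script[^>]*>", "", sub("</script>$", "", m))
  jsonlite::fromJSON(json, simplifyVector = TRUE)
}
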