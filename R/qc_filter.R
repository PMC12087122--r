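# Quality check and filtering: length histogram, six-interval coverage
# profile, e-value/length cutoffs, and the cross-hit similarity matrix.

#' Per-protein filtering limits
#'
#' Holds the e-value threshold and minimum subject-length cutoff applied to
#' each protein's hits, with global defaults of 1e-30 and 50 aa. Both
#' cutoffs are inclusive: a record is kept when `evalue <= evalue_cutoff`
#' and `subject_length >= min_length`. The length cutoff applies to the
#' subject (hit) sequence length, not the aligned span, so that hits much
#' shorter than the query protein can be discarded.
#'
#' @param overrides named list, protein -> `c(evalue, min_length)` (or a
#'   2-element list).
#' @param default_evalue,default_min_length global defaults used for
#'   proteins without an override.
#' @return an object of class `limits`.
#' @export
limits <- function(overrides = list(), default_evalue = 1e-30,
                   default_min_length = 50L) {
  if (default_evalue <= 0) stop_validation("evalue cutoff must be > 0")
  if (default_min_length < 0) stop_validation("min_length must be >= 0")
  for (p in names(overrides)) {
    o <- overrides[[p]]
    if (length(o) != 2L || !is.numeric(unlist(o))) {
      stop_config(sprintf("limits override for %s must be (evalue, min_length)", p))
    }
    if (o[[1L]] <= 0) stop_config(sprintf("evalue cutoff for %s must be > 0", p))
    if (o[[2L]] < 0) stop_config(sprintf("min_length for %s must be >= 0", p))
  }
  structure(list(overrides = overrides,
                 default_evalue = default_evalue,
                 default_min_length = as.integer(default_min_length)),
            class = "limits")
}

#' @export
print.limits <- function(x, ...) {
  cat(sprintf("limits: defaults evalue <= %g, length >= %d aa; %d override(s)\n",
              x$default_evalue, x$default_min_length, length(x$overrides)))
  invisible(x)
}

#' Resolve the cutoffs for one protein
#'
#' @param lim a [limits()] object.
#' @param protein protein name.
#' @return list with `evalue` and `min_length`.
#' @export
limits_for <- function(lim, protein) {
  o <- lim$overrides[[protein]]
  if (is.null(o)) {
    list(evalue = lim$default_evalue, min_length = lim$default_min_length)
  } else {
    list(evalue = as.numeric(o[[1L]]), min_length = as.integer(o[[2L]]))
  }
}

#' Read limits.txt
#'
#' Whitespace-separated lines `protein evalue min_length`; lines starting
#' with `#` and blank lines are ignored. A line whose protein field is
#' `default` overrides the global defaults.
#'
#' @param path path to a limits file.
#' @param proteins optional character vector of known protein names; lines
#'   for other proteins raise a configuration error.
#' @return a [limits()] object.
#' @export
read_limits <- function(path, proteins = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  default_evalue <- 1e-30
  default_min_length <- 50L
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "[[:space:]]+")[[1L]]
    if (length(parts) != 3L) {
      stop_config(sprintf("limits line %d: expected 'protein evalue min_length'", i))
    }
    ev <- suppressWarnings(as.numeric(parts[2L]))
    ml <- suppressWarnings(as.numeric(parts[3L]))
    if (is.na(ev) || is.na(ml)) {
      stop_config(sprintf("limits line %d: non-numeric cutoff", i))
    }
    if (identical(parts[1L], "default")) {
      default_evalue <- ev
      default_min_length <- as.integer(ml)
    } else {
      if (!is.null(proteins) && !(parts[1L] %in% proteins)) {
        stop_config(sprintf("limits line %d: unknown protein '%s'", i, parts[1L]))
      }
      overrides[[parts[1L]]] <- c(ev, ml)
    }
  }
  limits(overrides, default_evalue, default_min_length)
}

#' Filter a result table by its cutoffs
#'
#' Keeps exactly the records with `evalue <= cutoff` and
#' `subject_length >= min_length` (both inclusive), preserving record
#' order. Filtering counts are attached as the `"filter_counts"` attribute
#' (`parsed`, `kept`, `removed_by_evalue`, `removed_by_length`);
#' `removed_by_length` counts records that passed the e-value cutoff only,
#' so the four numbers are additive.
#'
#' @param table a [result_table()].
#' @param lim a [limits()] object whose defaults/overrides resolve
#'   `table$protein`.
#' @return the filtered [result_table()].
#' @export
apply_limits <- function(table, lim) {
  stopifnot(inherits(table, "result_table"), inherits(lim, "limits"))
  cut <- limits_for(lim, table$protein)
  rec <- table$records
  fail_ev <- rec$evalue > cut$evalue
  fail_len <- !fail_ev & rec$subject_length < cut$min_length
  keep <- !fail_ev & !fail_len
  out <- result_table(table$protein, table$seed_id, table$seed_length,
                      rec[keep, , drop = FALSE],
                      skipped_hits = table$skipped_hits)
  attr(out, "filter_counts") <- c(parsed = nrow(rec), kept = sum(keep),
                                  removed_by_evalue = sum(fail_ev),
                                  removed_by_length = sum(fail_len))
  out
}

#' Hit length histogram
#'
#' Bins the subject (hit) sequence lengths of one or more result tables
#' into fixed-width bins covering `[0, max length]`. The histogram is the
#' visual guide for choosing the per-protein minimum-length cutoff, e.g.
#' spotting a bimodal length distribution of full-length hits vs truncated
#' domains.
#'
#' @param tables list of [result_table()] objects (or a single one).
#' @param bin_width bin width in amino acids (>= 1).
#' @return data.frame with `bin_start`, `bin_end` (half-open bins
#'   `[start, end)`) and `count`; zero rows when there are no records.
#' @export
length_histogram <- function(tables, bin_width = 50L) {
  if (inherits(tables, "result_table")) tables <- list(tables)
  if (bin_width < 1L) stop_validation("bin_width must be >= 1")
  lengths <- unlist(lapply(tables, function(t) t$records$subject_length))
  if (!length(lengths)) {
    return(data.frame(bin_start = integer(0), bin_end = integer(0),
                      count = integer(0)))
  }
  nbin <- floor(max(lengths) / bin_width) + 1L
  starts <- (seq_len(nbin) - 1L) * bin_width
  idx <- floor(lengths / bin_width) + 1L
  counts <- tabulate(idx, nbins = nbin)
  data.frame(bin_start = starts, bin_end = starts + bin_width, count = counts)
}

#' Plot a length histogram
#'
#' @param hist data.frame from [length_histogram()].
#' @param path output file (PDF or PNG by extension).
#' @param title plot title.
#' @return invisibly, `path`.
#' @export
plot_length_histogram <- function(hist, path, title = "Hit length distribution") {
  open_device(path)
  on.exit(grDevices.dev_off())
  if (!nrow(hist)) {
    graphics::plot.new()
    graphics::title(main = title)
    graphics::text(0.5, 0.5, "no hits")
  } else {
    graphics::barplot(hist$count, names.arg = hist$bin_start, space = 0,
                      xlab = "subject length (aa, bin start)", ylab = "hits",
                      main = title, col = "grey40", border = NA)
  }
  invisible(path)
}

DEFAULT_COVERAGE_EDGES <- 10^-(seq(0L, 180L, by = 30L))

#' Coverage profile of hits over the query
#'
#' Assigns every hit of a single-seed result table to one of six e-value
#' intervals of increasing significance and collects its aligned query span
#' (1-based inclusive). The default interval edges are log-uniform in the
#' exponent between a working threshold of 1 and 1e-180, i.e.
#' `1e0, 1e-30, ..., 1e-180`; a hit with e-value `e` lands in interval `i`
#' when `edges[i+1] < e <= edges[i]`. The most significant interval absorbs
#' e-values below the last edge (including 0), the least significant one
#' absorbs e-values above the first edge. Within an interval, spans are
#' sorted by ascending e-value.
#'
#' @param table a [result_table()] for one seed.
#' @param interval_edges optional 7 strictly descending e-value bounds.
#' @return object of class `coverage_profile`: list with `interval_edges`,
#'   `intervals` (list of 6 data.frames `query_start`, `query_end`,
#'   `evalue`), and `query_length`.
#' @export
coverage_profile <- function(table, interval_edges = NULL) {
  stopifnot(inherits(table, "result_table"))
  edges <- if (is.null(interval_edges)) DEFAULT_COVERAGE_EDGES else interval_edges
  if (length(edges) != 7L || any(diff(edges) >= 0)) {
    stop_validation("interval_edges must be 7 strictly descending bounds")
  }
  rec <- table$records
  if (nrow(rec) && any(rec$query_end > table$seed_length)) {
    bad <- rec$subject_accession[rec$query_end > table$seed_length][1L]
    stop_data(sprintf("record %s: query span exceeds query length", bad))
  }
  intervals <- vector("list", 6L)
  for (i in seq_len(6L)) {
    if (nrow(rec)) {
      in_i <- rec$evalue <= edges[i] & rec$evalue > edges[i + 1L]
      if (i == 1L) in_i <- in_i | rec$evalue > edges[1L]
      if (i == 6L) in_i <- in_i | rec$evalue <= edges[7L]
      sub <- rec[in_i, c("query_start", "query_end", "evalue"), drop = FALSE]
      sub <- sub[order(sub$evalue, method = "radix"), , drop = FALSE]
      rownames(sub) <- NULL
    } else {
      sub <- data.frame(query_start = integer(0), query_end = integer(0),
                        evalue = numeric(0))
    }
    intervals[[i]] <- sub
  }
  structure(list(interval_edges = edges, intervals = intervals,
                 query_length = table$seed_length,
                 protein = table$protein, seed_id = table$seed_id),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile: %s/%s, query %d aa, hits per interval: %s\n",
              x$protein, x$seed_id, x$query_length,
              paste(vapply(x$intervals, nrow, 0L), collapse = " ")))
  invisible(x)
}

#' Plot a coverage profile
#'
#' Draws each hit span as a horizontal bar over the query axis, grouped by
#' e-value interval (most significant at the top), in the style of a
#' graphic summary of search results.
#'
#' @param profile a [coverage_profile()].
#' @param path output file (PDF or PNG by extension).
#' @return invisibly, `path`.
#' @export
plot_coverage_profile <- function(profile, path) {
  open_device(path)
  on.exit(grDevices.dev_off())
  n_per <- vapply(profile$intervals, nrow, 0L)
  total <- sum(n_per)
  graphics::plot(NULL, xlim = c(1, max(2, profile$query_length)),
                 ylim = c(0, max(1, total + 6)),
                 xlab = "query position (aa)", ylab = "",
                 yaxt = "n", main = sprintf("Hit coverage: %s/%s",
                                            profile$protein, profile$seed_id))
  shades <- grDevices::grey(seq(0.8, 0.0, length.out = 6L))
  y <- total + 6
  for (i in seq_len(6L)) {
    y <- y - 1
    graphics::text(1, y, sprintf("<= %.0e", profile$interval_edges[i]),
                   adj = c(0, 0.5), cex = 0.6, col = "grey30")
    sub <- profile$intervals[[i]]
    if (nrow(sub)) {
      for (k in seq_len(nrow(sub))) {
        y <- y - 1
        graphics::segments(sub$query_start[k], y, sub$query_end[k], y,
                           lwd = 3, col = shades[i], lend = 1)
      }
    }
  }
  invisible(path)
}

#' Cross-hit similarity matrix
#'
#' Detects subject accessions shared between the hit sets of different
#' query proteins (a symptom of paralog confusion). Entry `(i, j)` is the
#' minimum e-value over all occurrences, in either protein's set, of
#' accessions shared between proteins `i` and `j`; 0 means the accession
#' sets are disjoint. Because 0 is the no-cross-hit sentinel, true e-values
#' of 0.0 are floored to 1e-200 before entering the matrix.
#'
#' @param tables_by_protein named list, protein -> [result_table()] /
#'   [combined_table()] (or a data.frame with columns `subject_accession`
#'   and `evalue`).
#' @return object of class `cross_hit_matrix`: a symmetric numeric matrix
#'   with zero diagonal and protein names as dimnames.
#' @export
cross_hit_matrix <- function(tables_by_protein) {
  if (length(tables_by_protein) < 2L) {
    stop_validation("cross-hit check needs at least 2 proteins")
  }
  proteins <- names(tables_by_protein)
  if (is.null(proteins) || any(!nzchar(proteins))) {
    stop_validation("tables_by_protein must be a named list")
  }
  sets <- lapply(tables_by_protein, function(t) {
    rec <- if (is.data.frame(t)) t else t$records
    ev <- pmax(rec$evalue, 1e-200)  # floor true zeros below the sentinel
    tapply(ev, rec$subject_accession, min)
  })
  n <- length(proteins)
  m <- matrix(0, n, n, dimnames = list(proteins, proteins))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      shared <- intersect(names(sets[[i]]), names(sets[[j]]))
      if (length(shared)) {
        m[i, j] <- m[j, i] <- min(sets[[i]][shared], sets[[j]][shared])
      }
    }
  }
  structure(m, class = c("cross_hit_matrix", "matrix", "array"))
}

#' Write the cross-hit matrix as matrix.csv
#'
#' Comma-separated with proteins as header row and first column; a comment
#' line records the zero-sentinel and the 1e-200 floor for true zero
#' e-values.
#'
#' @param m a [cross_hit_matrix()].
#' @param path output path (conventionally `matrix.csv`).
#' @return invisibly, `path`.
#' @export
write_cross_hit_matrix <- function(m, path) {
  proteins <- rownames(m)
  lines <- c(
    "# cross-hit matrix: 0 = no shared accession; true e-values of 0.0 are floored to 1e-200",
    paste(c("", proteins), collapse = ","),
    vapply(seq_along(proteins), function(i) {
      paste(c(proteins[i], fmt_num(unclass(m)[i, ])), collapse = ",")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

open_device <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdf = grDevices::pdf(path, width = 8, height = 6),
         png = grDevices::png(path, width = 1200, height = 900, res = 150),
         stop_validation(sprintf("unsupported graphics format: .%s", ext)))
}

grDevices.dev_off <- function() invisible(grDevices::dev.off())
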