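# Brute-force agglomerative clustering oracle. Unlike the package
# implementation, which maintains an incrementally updated cluster
# distance matrix, this oracle recomputes every cluster-pair distance from
# the definitions at every step (member enumeration for the geometric
# linkages; naive recursion over the merge trees for the recursively
# defined ones). Tie-break and leaf rotation follow the same stated rules:
# earliest-created pair wins, subtree with the smaller minimum original
# index goes left.

oracle_agglomerate <- function(x, linkage) {
  x <- as.matrix(x)
  n <- nrow(x)
  euclid <- function(a, b) sqrt(sum((a - b)^2))

  # cluster = list(tree, leaves, created); tree is a leaf index or
  # list(l, r, created)
  clusters <- lapply(seq_len(n), function(i)
    list(tree = i, leaves = i, created = 0L))

  midpoint <- function(tree) {
    if (is.numeric(tree)) return(x[tree, ])
    (midpoint(tree$l) + midpoint(tree$r)) / 2
  }
  created_of <- function(tree) if (is.numeric(tree)) 0L else tree$created
  wdist <- function(a, b) {
    if (is.numeric(a) && is.numeric(b)) return(euclid(x[a, ], x[b, ]))
    # decompose the later-created cluster (the one whose merge defined
    # the distance recurrence)
    if (created_of(a) >= created_of(b)) {
      (wdist(a$l, b) + wdist(a$r, b)) / 2
    } else {
      (wdist(a, b$l) + wdist(a, b$r)) / 2
    }
  }
  cdist <- function(A, B) {
    la <- A$leaves; lb <- B$leaves
    switch(linkage,
      single = min(apply(expand.grid(la, lb), 1L,
                         function(p) euclid(x[p[1L], ], x[p[2L], ]))),
      complete = max(apply(expand.grid(la, lb), 1L,
                           function(p) euclid(x[p[1L], ], x[p[2L], ]))),
      average = mean(apply(expand.grid(la, lb), 1L,
                           function(p) euclid(x[p[1L], ], x[p[2L], ]))),
      centroid = euclid(colMeans(x[la, , drop = FALSE]),
                        colMeans(x[lb, , drop = FALSE])),
      ward = sqrt(2 * length(la) * length(lb) / (length(la) + length(lb))) *
        euclid(colMeans(x[la, , drop = FALSE]), colMeans(x[lb, , drop = FALSE])),
      weighted = wdist(A$tree, B$tree),
      median = euclid(midpoint(A$tree), midpoint(B$tree))
    )
  }

  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- NULL; dmin <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        d <- cdist(clusters[[i]], clusters[[j]])
        if (is.null(best) || d < dmin - 1e-9 * max(1, abs(dmin))) {
          dmin <- d; best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    heights[step] <- dmin
    left_first <- min(clusters[[i]]$leaves) <= min(clusters[[j]]$leaves)
    leaves <- if (left_first) {
      c(clusters[[i]]$leaves, clusters[[j]]$leaves)
    } else {
      c(clusters[[j]]$leaves, clusters[[i]]$leaves)
    }
    merged <- list(tree = list(l = clusters[[i]]$tree, r = clusters[[j]]$tree,
                               created = step),
                   leaves = leaves, created = step)
    clusters <- c(clusters[-c(i, j)], list(merged))
  }
  list(order = clusters[[1L]]$leaves, height = heights)
}
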