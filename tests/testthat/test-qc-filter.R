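make_table <- function(evalues, lengths, protein = "protX") {
  n <- length(evalues)
  if (n == 0L) {
    return(result_table(protein, paste0(protein, "_seed1"), 500L))
  }
  rec <- data.frame(
    subject_accession = sprintf("ACC%03d", seq_len(n)),
    subject_taxid = 1000L + seq_len(n), evalue = evalues,
    bitscore = 100, query_start = 1L, query_end = 50L,
    subject_length = as.integer(lengths), aligned_subject_seq = "",
    stringsAsFactors = FALSE)
  result_table(protein, paste0(protein, "_seed1"), 500L, rec)
}

test_that("default cutoffs are inclusive on both boundaries", {
  lim <- limits()
  expect_equal(lim$default_evalue, 1e-30)
  expect_equal(lim$default_min_length, 50L)
  tb <- make_table(c(1e-30, 1e-29, 1e-31, 1e-31), c(50, 500, 49, 50))
  kept <- apply_limits(tb, lim)
  # (1e-30, 50) kept on the boundary; (1e-29, 500) fails evalue;
  # (1e-31, 49) fails length; input order preserved
  expect_equal(kept$records$subject_accession, c("ACC001", "ACC004"))
  counts <- attr(kept, "filter_counts")
  expect_equal(unname(counts["parsed"]), 4L)
  expect_equal(unname(counts["kept"]), 2L)
  expect_equal(unname(counts["removed_by_evalue"]), 1L)
  expect_equal(unname(counts["removed_by_length"]), 1L)
  empty <- apply_limits(make_table(numeric(0), integer(0)), lim)
  expect_equal(nrow(empty$records), 0L)
})

test_that("apply_limits agrees with a record-by-record oracle and is monotone", {
  set.seed(41)
  lim_tight <- limits(default_evalue = 1e-50, default_min_length = 200L)
  lim_loose <- limits(default_evalue = 1e-10, default_min_length = 60L)
  for (rep in 1:10) {
    tb <- random_result_table(30L)
    got <- apply_limits(tb, lim_tight)$records$subject_accession
    oracle <- character(0)
    for (i in seq_len(nrow(tb$records))) {   # brute force, one record at a time
      r <- tb$records[i, ]
      if (r$evalue <= 1e-50 && r$subject_length >= 200L) {
        oracle <- c(oracle, r$subject_accession)
      }
    }
    expect_equal(got, oracle)
    loose <- apply_limits(tb, lim_loose)$records$subject_accession
    expect_true(all(got %in% loose))  # relaxing keeps a superset
    counts <- attr(apply_limits(tb, lim_tight), "filter_counts")
    expect_equal(unname(counts["parsed"]),
                 unname(counts["kept"] + counts["removed_by_evalue"] +
                          counts["removed_by_length"]))
  }
})

test_that("limits.txt parsing handles overrides, defaults and bad lines", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "", "protA 1e-60 200", "default 1e-20 30"), tmp)
  lim <- read_limits(tmp)
  expect_equal(limits_for(lim, "protA"), list(evalue = 1e-60, min_length = 200L))
  expect_equal(limits_for(lim, "other"), list(evalue = 1e-20, min_length = 30L))
  writeLines("protA not-a-number 50", tmp)
  expect_error(read_limits(tmp), "line 1", class = "taxoprofile_config_error")
  writeLines("ghost 1e-5 50", tmp)
  expect_error(read_limits(tmp, proteins = c("protA")), "ghost",
               class = "taxoprofile_config_error")
})

test_that("length histogram bins by hand-checkable arithmetic", {
  tb <- make_table(rep(1e-40, 3), c(400, 401, 598))
  h <- length_histogram(tb, bin_width = 50L)
  expect_equal(h$count[h$bin_start == 400], 2L)
  expect_equal(h$count[h$bin_start == 550], 1L)
  expect_equal(sum(h$count), 3L)
  h1 <- length_histogram(make_table(1e-10, 123), bin_width = 50L)
  expect_equal(sum(h1$count > 0), 1L)
  expect_equal(sum(h1$count), 1L)
  expect_equal(nrow(length_histogram(make_table(numeric(0), integer(0)))), 0L)
})

test_that("histogram counts are conserved for generated fixtures", {
  fxspec <- presence_spec(n_clades = 4L, species_per_clade = 4L, seed = 5L)
  real <- realize_presence(fxspec)
  tb <- make_table(real$evalue, real$subject_length)
  for (bw in c(10L, 50L, 137L)) {
    expect_equal(sum(length_histogram(tb, bw)$count), nrow(real))
  }
})

test_that("a bimodal length rule produces two histogram peaks", {
  fxspec <- presence_spec(
    n_clades = 6L, species_per_clade = 6L, seed = 9L,
    proteins = list(napratlike = list(fraction = 1,
                                      length_mean = c(400, 590),
                                      length_sd = c(15, 10))),
    seeds_per_protein = 2L, cross_hit = FALSE)
  real <- realize_presence(fxspec)
  h <- length_histogram(make_table(real$evalue, real$subject_length), 50L)
  counts <- h$count
  # local maxima: higher than both neighbours
  maxima <- which(counts > c(-1, counts[-length(counts)]) &
                    counts > c(counts[-1], -1))
  expect_gte(length(maxima), 2L)
  expect_true(any(h$bin_start[maxima] %in% c(350, 400)))
  expect_true(any(h$bin_start[maxima] %in% c(550, 600)))
})

test_that("coverage profile assigns one hit per interval at the default edges", {
  tb <- make_table(c(1e-5, 1e-35, 1e-65, 1e-95, 1e-125, 1e-155),
                   rep(300, 6))
  prof <- coverage_profile(tb)
  expect_equal(vapply(prof$intervals, nrow, 0L), rep(1L, 6L))
  expect_equal(prof$intervals[[1L]]$evalue, 1e-5)
  expect_equal(prof$intervals[[6L]]$evalue, 1e-155)
})

test_that("coverage profile handles extremes and degenerate input", {
  # full-length highly significant hit falls in the most significant
  # applicable interval
  rec <- data.frame(subject_accession = "A", subject_taxid = 1L,
                    evalue = 1e-150, bitscore = 500, query_start = 1L,
                    query_end = 500L, subject_length = 500L,
                    aligned_subject_seq = "", stringsAsFactors = FALSE)
  tb <- result_table("p", "s", 500L, rec)
  prof <- coverage_profile(tb)
  expect_equal(nrow(prof$intervals[[6L]]), 1L)
  expect_equal(prof$intervals[[6L]]$query_end, 500L)
  # empty table: six empty intervals
  empty <- coverage_profile(result_table("p", "s", 500L))
  expect_equal(vapply(empty$intervals, nrow, 0L), rep(0L, 6L))
  # span beyond the query is a data error naming the record
  bad <- result_table("p", "s", 40L, within <- transform(rec, query_end = 50L))
  expect_error(coverage_profile(bad), "A", class = "taxoprofile_data_error")
  expect_error(coverage_profile(tb, interval_edges = c(1, 2, 3)),
               class = "taxoprofile_validation_error")
})

test_that("cross-hit matrix reports shared accessions at the minimum e-value", {
  rec <- function(acc, ev) data.frame(
    subject_accession = acc, subject_taxid = 1L, evalue = ev, bitscore = 10,
    query_start = 1L, query_end = 5L, subject_length = 100L,
    aligned_subject_seq = "", stringsAsFactors = FALSE)
  tabs <- list(
    A = result_table("A", "s", 10L, rbind(rec("X1", 1e-60), rec("A9", 1e-5))),
    B = result_table("B", "s", 10L, rbind(rec("X1", 1e-45), rec("B9", 1e-7))),
    C = result_table("C", "s", 10L, rec("C9", 1e-9)))
  m <- cross_hit_matrix(tabs)
  expect_equal(unclass(m)["A", "B"], 1e-60)
  expect_equal(unclass(m)["B", "A"], 1e-60)
  expect_equal(sum(unclass(m) > 0), 2L)  # exactly one symmetric pair
  expect_equal(diag(unclass(m)), c(A = 0, B = 0, C = 0))

  disjoint <- cross_hit_matrix(tabs[c("A", "C")])
  expect_true(all(unclass(disjoint) == 0))
  expect_error(cross_hit_matrix(tabs["A"]),
               class = "taxoprofile_validation_error")
})

test_that("cross-hit matrix is symmetric with zero diagonal (property)", {
  set.seed(51)
  for (rep in 1:5) {
    tabs <- lapply(1:4, function(i) random_result_table(15L,
                                                        protein = sprintf("p%d", i)))
    names(tabs) <- sprintf("p%d", 1:4)
    m <- unclass(cross_hit_matrix(tabs))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
  }
})

test_that("true zero e-values are floored below the sentinel", {
  rec <- function(acc, ev) data.frame(
    subject_accession = acc, subject_taxid = 1L, evalue = ev, bitscore = 10,
    query_start = 1L, query_end = 5L, subject_length = 100L,
    aligned_subject_seq = "", stringsAsFactors = FALSE)
  tabs <- list(A = result_table("A", "s", 10L, rec("X1", 0)),
               B = result_table("B", "s", 10L, rec("X1", 1e-45)))
  m <- cross_hit_matrix(tabs)
  expect_equal(unclass(m)["A", "B"], 1e-200)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cross_hit_matrix(m, tmp)
  lines <- readLines(tmp)
  expect_match(lines[1L], "1e-200")
  expect_equal(length(lines), 1L + 1L + 2L)  # comment + header + 2 rows
})
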