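test_that("HSPs are parsed and ordered by ascending e-value", {
  xml <- tiny_blast_xml(list(
    list(accession = "A1", taxid = 1001L, evalue = 1e-50),
    list(accession = "A2", taxid = 1002L, evalue = 1e-10),
    list(accession = "A3", taxid = 1003L, evalue = 1e-80)))
  tb <- parse_blast_xml(xml, "protX")
  expect_s3_class(tb, "result_table")
  expect_equal(tb$records$evalue, c(1e-80, 1e-50, 1e-10))
  expect_equal(tb$records$subject_accession, c("A3", "A1", "A2"))
  expect_equal(tb$seed_length, 100L)
  expect_equal(tb$seed_id, "tiny_seed1")
})

test_that("a zero-hit document yields an empty table", {
  tb <- parse_blast_xml(tiny_blast_xml(list()), "protX")
  expect_equal(nrow(tb$records), 0L)
  expect_equal(tb$skipped_hits, 0L)
})

test_that("query coordinates pass through 1-based inclusive", {
  xml <- tiny_blast_xml(list(
    list(accession = "A1", taxid = 1001L, evalue = 1e-5, from = 10L, to = 60L)))
  tb <- parse_blast_xml(xml, "protX")
  expect_equal(tb$records$query_start, 10L)
  expect_equal(tb$records$query_end, 60L)
})

test_that("hits without a taxid are skipped with a warning and counted", {
  xml <- tiny_blast_xml(list(
    list(accession = "A1", taxid = 1001L, evalue = 1e-50),
    list(accession = "A2", taxid = NULL, evalue = 1e-90)))
  expect_warning(tb <- parse_blast_xml(xml, "protX"), "without a taxid")
  expect_equal(nrow(tb$records), 1L)
  expect_equal(tb$skipped_hits, 1L)
})

test_that("non-XML input raises a format error", {
  expect_error(parse_blast_xml("this is not xml at all <", "p"),
               class = "taxoprofile_format_error")
  expect_error(parse_blast_xml("<notblast><a/></notblast>", "p"),
               "Search", class = "taxoprofile_format_error")
})

test_that("record order is a total order: shuffled documents parse identically", {
  set.seed(11)
  hits <- lapply(1:8, function(i) list(
    accession = sprintf("H%02d", i), taxid = 1000L + i,
    evalue = sample(c(1e-20, 1e-40, 1e-40, 1e-60), 1L),
    bitscore = sample(c(100, 200), 1L)))
  tb1 <- parse_blast_xml(tiny_blast_xml(hits), "p")
  tb2 <- parse_blast_xml(tiny_blast_xml(hits[sample(seq_along(hits))]), "p")
  expect_equal(tb1$records, tb2$records)
})

test_that("TSV round trip is lossless, including the empty table", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  empty <- result_table("protX", "protX_seed1", 300L)
  write_result_table(empty, tmp)
  body <- grep("^#", readLines(tmp), invert = TRUE, value = TRUE)
  expect_equal(length(body), 1L)  # header only
  back <- read_result_table(tmp)
  expect_equal(back$records, empty$records)
  expect_equal(back$protein, "protX")

  set.seed(21)
  for (n in c(1L, 3L, 25L)) {
    for (with_seq in c(TRUE, FALSE)) {
      tb <- random_result_table(n, with_seq = with_seq)
      write_result_table(tb, tmp)
      body <- grep("^#", readLines(tmp), invert = TRUE, value = TRUE)
      expect_equal(length(body), n + 1L)  # records + header
      back <- read_result_table(tmp)
      expect_equal(back$records, tb$records)
      expect_equal(back$seed_length, tb$seed_length)
    }
  }
})

test_that("TSV reader rejects broken files naming the problem", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tb <- random_result_table(2L)
  write_result_table(tb, tmp)
  lines <- readLines(tmp)
  # corrupt the evalue of the first record
  parts <- strsplit(lines[5L], "\t")[[1L]]
  parts[3L] <- "abc"
  lines[5L] <- paste(parts, collapse = "\t")
  writeLines(lines, tmp)
  expect_error(read_result_table(tmp), "evalue",
               class = "taxoprofile_format_error")
  # drop a required column
  writeLines(c("# protein: p", "# seed_id: s", "# seed_length: 10",
               "subject_accession\tevalue"), tmp)
  expect_error(read_result_table(tmp), "subject_taxid",
               class = "taxoprofile_format_error")
})

test_that("blast2fasta strips gaps and dedupes by minimum e-value", {
  rec <- function(acc, ev, seq) data.frame(
    subject_accession = acc, subject_taxid = 1001L, evalue = ev,
    bitscore = 50, query_start = 1L, query_end = 5L, subject_length = 100L,
    aligned_subject_seq = seq, stringsAsFactors = FALSE)
  t1 <- result_table("p1", "s1", 100L, rec("X1", 1e-10, "MK-LV"))
  t2 <- result_table("p2", "s2", 100L, rec("X1", 1e-40, "MKQLV"))
  fa <- blast2fasta(list(t1, t2), dedupe = TRUE)
  expect_equal(length(fa), 2L)
  expect_equal(fa[1L], ">X1 1001 p2")  # the 1e-40 occurrence wins
  expect_equal(fa[2L], "MKQLV")
  fa1 <- blast2fasta(list(t1))
  expect_equal(fa1[2L], "MKLV")  # gap stripped
  expect_equal(blast2fasta(list()), character(0))
})

test_that("blast2fasta output has no gaps or duplicate headers (property)", {
  set.seed(31)
  tables <- lapply(1:4, function(i) random_result_table(10L,
                                                        protein = sprintf("p%d", i),
                                                        seed_id = sprintf("p%d_s1", i)))
  fa <- blast2fasta(tables, dedupe = TRUE)
  headers <- grep("^>", fa, value = TRUE)
  seqs <- grep("^>", fa, invert = TRUE, value = TRUE)
  expect_false(any(grepl("-", seqs, fixed = TRUE)))
  expect_equal(anyDuplicated(headers), 0L)
})

test_that("blast2fasta strictness flag controls empty-sequence handling", {
  rec <- data.frame(subject_accession = "E1", subject_taxid = 1L,
                    evalue = 1e-5, bitscore = 40, query_start = 1L,
                    query_end = 5L, subject_length = 60L,
                    aligned_subject_seq = "", stringsAsFactors = FALSE)
  tb <- result_table("p", "s", 100L, rec)
  expect_warning(fa <- blast2fasta(list(tb), strict = FALSE), "empty")
  expect_equal(length(fa), 0L)
  expect_error(blast2fasta(list(tb), strict = TRUE),
               class = "taxoprofile_validation_error")
})

test_that("run_blastp records default parameters without executing", {
  spec <- run_blastp("seeds.fasta", "nr", mode = "remote")
  expect_equal(spec$params$matrix, "BLOSUM62")
  expect_equal(spec$params$word_size, 6L)
  expect_equal(spec$params$gapopen, 11L)
  expect_equal(spec$params$gapextend, 1L)
  expect_equal(spec$params$evalue, 1e-3)
  expect_equal(spec$params$max_target_seqs, 20000L)
  expect_true("-remote" %in% spec$command)
  expect_equal(spec$command[which(spec$command == "-outfmt") + 1L], "14")
})

test_that("run_blastp validates its inputs before any execution", {
  expect_error(run_blastp("seeds.fasta", ""),
               class = "taxoprofile_validation_error")
  expect_error(run_blastp("seeds.fasta", "nr", params = list(bogus = 1)),
               "bogus", class = "taxoprofile_validation_error")
})
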