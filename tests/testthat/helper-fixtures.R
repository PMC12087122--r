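# Shared fixture builders for the unit tests. Everything is generated in
# code; no data files are read from disk.

# Minimal taxonomy: root -> 2 superkingdoms -> phylum -> genus -> species
# (-> strain), with hand-assigned taxids so expectations can be walked by
# hand.
tiny_taxonomy <- function() {
  nodes <- c(
    "1\t|\t1\t|\tno rank\t|",
    "2\t|\t1\t|\tsuperkingdom\t|",
    "3\t|\t1\t|\tsuperkingdom\t|",
    "11\t|\t2\t|\tphylum\t|",
    "12\t|\t3\t|\tphylum\t|",
    "101\t|\t11\t|\tgenus\t|",
    "102\t|\t12\t|\tgenus\t|",
    "1001\t|\t101\t|\tspecies\t|",
    "1002\t|\t101\t|\tspecies\t|",
    "1003\t|\t102\t|\tspecies\t|",
    "20001\t|\t1001\t|\tno rank\t|"
  )
  names <- c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "2\t|\tBacteria-like\t|\t\t|\tscientific name\t|",
    "3\t|\tEukaryota-like\t|\t\t|\tscientific name\t|",
    "11\t|\tPhylum A\t|\t\t|\tscientific name\t|",
    "12\t|\tPhylum B\t|\t\t|\tscientific name\t|",
    "101\t|\tGenus A\t|\t\t|\tscientific name\t|",
    "102\t|\tGenus B\t|\t\t|\tscientific name\t|",
    "1001\t|\tSpecies A1\t|\t\t|\tscientific name\t|",
    "1002\t|\tSpecies A2\t|\t\t|\tscientific name\t|",
    "1003\t|\tSpecies B1\t|\t\t|\tscientific name\t|",
    "20001\t|\tSpecies A1 strain X\t|\t\t|\tscientific name\t|"
  )
  load_taxonomy(nodes, names)
}

# Hand-built single-query BLAST XML2 document. `hits` is a list of lists
# with fields accession, taxid (NULL to omit), evalue, bitscore, from, to,
# len, hseq.
tiny_blast_xml <- function(hits, qlen = 100L, seed_id = "tiny_seed1") {
  hit_xml <- character(0)
  for (i in seq_along(hits)) {
    h <- hits[[i]]
    taxid_line <- if (is.null(h$taxid)) character(0) else
      sprintf("<taxid>%d</taxid>", h$taxid)
    hit_xml <- c(hit_xml, sprintf(
      paste0("<Hit><num>%d</num><description><HitDescr>",
             "<id>gb|%s|</id><accession>%s</accession><title>t</title>%s",
             "</HitDescr></description><len>%d</len><hsps><Hsp><num>1</num>",
             "<bit-score>%s</bit-score><score>10</score><evalue>%s</evalue>",
             "<identity>5</identity><query-from>%d</query-from>",
             "<query-to>%d</query-to><hit-from>1</hit-from><hit-to>5</hit-to>",
             "<align-len>%d</align-len><qseq>%s</qseq><hseq>%s</hseq>",
             "</Hsp></hsps></Hit>"),
      i, h$accession, h$accession, paste(taxid_line, collapse = ""),
      h$len %||% 80L, format(h$bitscore %||% 50), format(h$evalue),
      h$from %||% 1L, h$to %||% 50L,
      nchar(h$hseq %||% "MKLVA"), strrep("A", nchar(h$hseq %||% "MKLVA")),
      h$hseq %||% "MKLVA"))
  }
  paste0(
    "<?xml version=\"1.0\"?>",
    "<BlastXML2 xmlns=\"http://www.ncbi.nlm.nih.gov\"><BlastOutput2>",
    "<report><Report><program>blastp</program>",
    "<results><Results><search><Search>",
    sprintf("<query-id>Query_1</query-id><query-title>%s</query-title>", seed_id),
    sprintf("<query-len>%d</query-len>", qlen),
    "<hits>", paste(hit_xml, collapse = ""), "</hits>",
    "</Search></search></Results></results>",
    "</Report></report></BlastOutput2></BlastXML2>")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Randomised result table for round-trip / property tests.
random_result_table <- function(n, protein = "protX", seed_id = "protX_seed1",
                                with_seq = TRUE) {
  if (n == 0L) return(result_table(protein, seed_id, 300L))
  recs <- data.frame(
    subject_accession = sprintf("ACC%04d", sample.int(9999L, n)),
    subject_taxid = sample.int(5000L, n, replace = TRUE),
    evalue = 10^stats::runif(n, -180, 0),
    bitscore = round(stats::runif(n, 30, 900), 2),
    query_start = sample.int(200L, n, replace = TRUE),
    subject_length = sample(50:900, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  recs$query_end <- recs$query_start + sample.int(100L, n, replace = TRUE)
  recs$aligned_subject_seq <- if (with_seq) {
    vapply(seq_len(n), function(i)
      paste(sample(c(LETTERS[1:20], "-"), 20, replace = TRUE), collapse = ""), "")
  } else ""
  recs <- recs[order(recs$evalue, -recs$bitscore, recs$subject_accession,
                     method = "radix"), ]
  result_table(protein, seed_id, 300L, recs)
}
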