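test_that("initialisation creates the folder structure and config templates", {
  root <- file.path(withr::local_tempdir(), "ws")
  ws <- init_workspace(root)
  expect_true(all(dir.exists(file.path(root, c("blastresults", "fastas",
                                               "resulttables", "combinedtables")))))
  cfgs <- c("proteinlist.txt", "limits.txt", "heatmap_config.txt",
            "tree_config.txt", "tree_to_prune.txt")
  expect_true(all(file.exists(file.path(root, cfgs))))
  expect_equal(length(list.dirs(root, recursive = FALSE)), 4L)
})

test_that("re-initialisation is a no-op that preserves user edits", {
  root <- file.path(withr::local_tempdir(), "ws")
  init_workspace(root)
  marker <- c("protA seeds.fasta")
  writeLines(marker, file.path(root, "proteinlist.txt"))
  before <- lapply(list.files(root, recursive = TRUE, full.names = TRUE), readLines)
  init_workspace(root)
  expect_equal(readLines(file.path(root, "proteinlist.txt")), marker)
  expect_match(paste(readLines(file.path(root, "run.log")), collapse = "\n"),
               "no-op")
})

test_that("a file at the workspace root is a filesystem error", {
  f <- withr::local_tempfile()
  writeLines("x", f)
  expect_error(init_workspace(f), class = "taxoprofile_filesystem_error")
})

test_that("config cross-validation collects all violations at once", {
  root <- file.path(withr::local_tempdir(), "ws")
  ws <- init_workspace(root)
  writeLines(c("protA a.fasta", "protB b.fasta"), ws$configs[["proteinlist.txt"]])
  writeLines("ghost 1e-5 50", ws$configs[["limits.txt"]])
  writeLines("proteins = protA, protB, protC, protD",
             ws$configs[["tree_config.txt"]])
  err <- tryCatch(parse_configs(ws), taxoprofile_config_error = identity)
  expect_s3_class(err, "taxoprofile_config_error")
  expect_match(conditionMessage(err), "ghost")
  expect_match(conditionMessage(err), "at most 3")
})

test_that("a fresh workspace parses to the documented defaults", {
  root <- file.path(withr::local_tempdir(), "ws")
  ws <- init_workspace(root)
  writeLines("protA a.fasta", ws$configs[["proteinlist.txt"]])
  cfg <- parse_configs(ws)
  expect_equal(cfg$limits$default_evalue, 1e-30)
  expect_equal(cfg$limits$default_min_length, 50L)
  expect_equal(cfg$heatmap$linkage, "centroid")
  expect_equal(cfg$heatmap$slider_default, 30L)
  expect_equal(cfg$tree$proteins, character(0))
  expect_equal(cfg$prune$collapse, character(0))
})

test_that("tree proteins must appear in the protein list", {
  root <- file.path(withr::local_tempdir(), "ws")
  ws <- init_workspace(root)
  writeLines("protA a.fasta", ws$configs[["proteinlist.txt"]])
  writeLines("proteins = protZ", ws$configs[["tree_config.txt"]])
  expect_error(parse_configs(ws), "protZ",
               class = "taxoprofile_config_error")
})

test_that("stages depend on their upstream outputs", {
  fx <- make_workspace_fixture(file.path(withr::local_tempdir(), "ws"),
                               presence_spec(n_clades = 2L,
                                             species_per_clade = 2L, seed = 2L))
  expect_error(run_pipeline(fx$ws, stages = "heatmap"),
               "combine", class = "taxoprofile_dependency_error")
  expect_error(run_pipeline(fx$ws, stages = "filter"),
               "parse", class = "taxoprofile_dependency_error")
  expect_error(run_pipeline(fx$ws, stages = "nonsense"),
               class = "taxoprofile_validation_error")
})

test_that("the run report is arithmetically self-consistent with a recount", {
  spec <- presence_spec(n_clades = 3L, species_per_clade = 3L, seed = 6L)
  fx <- make_workspace_fixture(file.path(withr::local_tempdir(), "ws"), spec)
  rep <- run_pipeline(fx$ws, stages = c("parse", "filter", "combine"))
  for (key in names(rep$filter)) {
    counts <- rep$filter[[key]]
    expect_equal(unname(counts["parsed"]),
                 unname(counts["kept"] + counts["removed_by_evalue"] +
                          counts["removed_by_length"]))
  }
  # parse counts match the generated realisation per seed
  per_seed <- table(fx$realization$seed_id)
  for (sid in names(rep$parse)) {
    expect_equal(unname(rep$parse[[sid]]["hits"]),
                 unname(as.integer(per_seed[sid])))
  }
  # combined organism counts match a brute-force recount under defaults
  db <- load_taxonomy(file.path(fx$ws$root, "taxonomy", "nodes.dmp"),
                      file.path(fx$ws$root, "taxonomy", "names.dmp"))
  kept <- fx$realization[fx$realization$evalue <= 1e-30 &
                           fx$realization$subject_length >= 50L, ]
  for (p in names(spec$proteins)) {
    want <- length(unique(kept$organism[kept$protein == p]))
    expect_equal(unname(rep$combine[[p]]["organisms"]), want)
  }
})

test_that("single-stage reruns after cutoff edits pick up the new limits", {
  spec <- presence_spec(n_clades = 2L, species_per_clade = 3L, seed = 8L)
  fx <- make_workspace_fixture(file.path(withr::local_tempdir(), "ws"), spec)
  run_pipeline(fx$ws, stages = "parse")
  r1 <- run_pipeline(fx$ws, stages = "filter")
  writeLines("default 1e-200 50", fx$ws$configs[["limits.txt"]])
  r2 <- run_pipeline(fx$ws, stages = "filter")
  kept1 <- sum(vapply(r1$filter, function(x) unname(x["kept"]), 0L))
  kept2 <- sum(vapply(r2$filter, function(x) unname(x["kept"]), 0L))
  expect_lt(kept2, kept1)
})

test_that("qc stage writes histogram tables and coverage plots", {
  spec <- presence_spec(n_clades = 2L, species_per_clade = 3L, seed = 12L)
  fx <- make_workspace_fixture(file.path(withr::local_tempdir(), "ws"), spec)
  rep <- run_pipeline(fx$ws, stages = c("parse", "qc"))
  for (p in names(spec$proteins)) {
    tsv <- file.path(fx$ws$root, sprintf("qc_%s_lengths.tsv", p))
    expect_true(file.exists(tsv))
    h <- utils::read.delim(tsv)
    expect_equal(sum(h$count), unname(rep$qc[[p]]["records"]))
    expect_true(file.exists(file.path(fx$ws$root,
                                      sprintf("qc_%s_lengths.pdf", p))))
  }
  covs <- list.files(fx$ws$root, pattern = "_coverage\\.pdf$")
  expect_equal(length(covs),
               length(spec$proteins) * spec$seeds_per_protein)
})
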