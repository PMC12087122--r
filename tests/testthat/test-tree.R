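test_that("combination codes are bitmasks over the configured protein order", {
  expect_equal(combo_code(c(TRUE, FALSE, FALSE)), 1L)
  expect_equal(combo_code(c(FALSE, TRUE, FALSE)), 2L)
  expect_equal(combo_code(c(TRUE, TRUE, TRUE)), 7L)
  expect_true(is.na(combo_code(c(FALSE, FALSE))))
  expect_error(combo_code(logical(0)), class = "taxoprofile_validation_error")
  expect_error(combo_code(rep(TRUE, 4L)), class = "taxoprofile_validation_error")
  # a 2-protein run can only produce codes 1..3
  codes <- vapply(list(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE)),
                  combo_code, 0L)
  expect_true(all(codes %in% 1:3))
})

test_that("a single organism under the root gives a two-node annotated path", {
  db <- load_taxonomy(
    c("1\t|\t1\t|\tno rank\t|", "2\t|\t1\t|\tspecies\t|"),
    c("1\t|\troot\t|\t\t|\tscientific name\t|",
      "2\t|\tOnly species\t|\t\t|\tscientific name\t|"))
  tree <- annotate_tree(db, list(protA = 2L))
  expect_equal(nrow(tree$nodes), 2L)
  expect_equal(tree$counts[["1"]], 1L)
  expect_equal(tree$counts[["2"]], 1L)
  expect_equal(unname(tree$total[c("1", "2")]), c(1L, 1L))
})

test_that("clade counts aggregate hand-computed combination tallies", {
  spec <- presence_spec(n_clades = 2L, species_per_clade = 4L,
                        strain_fraction = 0, seed = 13L)
  tax <- make_taxonomy(spec)
  db <- load_taxonomy(tax$nodes, tax$names)
  clade1 <- tax$organisms$taxid[tax$organisms$clade == 1L]  # 4 organisms
  presence <- list(pA = clade1[c(1L, 2L, 4L)],   # codes: 1,1,-,3
                   pB = clade1[c(3L, 4L)])       # codes: -,-,2,3
  tree <- annotate_tree(db, presence)
  clade_key <- as.character(11L)  # phylum of clade 1
  expect_equal(tree$counts[[clade_key]], c(2L, 1L, 1L))
  expect_equal(unname(tree$total[clade_key]), 4L)
  # organisms present for no protein are simply absent from the tree
  clade2 <- tax$organisms$taxid[tax$organisms$clade == 2L]
  expect_false(any(clade2 %in% tree$nodes$taxid))
  expect_error(annotate_tree(db, list(pA = integer(0))),
               "no hits", class = "taxoprofile_validation_error")
})

test_that("organisms unknown to the taxonomy attach under the root with a warning", {
  db <- tiny_taxonomy()
  expect_warning(tree <- annotate_tree(db, list(pA = c(1001L, 777777L))),
                 "777777")
  expect_true(777777L %in% tree$nodes$taxid)
  i <- match(777777L, tree$nodes$taxid)
  expect_equal(tree$nodes$parent[i], 1L)
  expect_equal(unname(tree$total["1"]), 2L)
})

test_that("counts are conserved at every internal node on random fixtures", {
  set.seed(81)
  for (rep in 1:20) {
    spec <- presence_spec(n_clades = sample(2:5, 1L),
                          species_per_clade = sample(2:5, 1L),
                          strain_fraction = 0, seed = rep,
                          cross_hit = FALSE)
    tax <- make_taxonomy(spec)
    db <- load_taxonomy(tax$nodes, tax$names)
    orgs <- tax$organisms$taxid
    presence <- list(pA = sample(orgs, ceiling(length(orgs) * 0.7)),
                     pB = sample(orgs, ceiling(length(orgs) * 0.4)),
                     pC = sample(orgs, ceiling(length(orgs) * 0.3)))
    tree <- annotate_tree(db, presence)
    for (key in names(tree$children)) {
      kids <- as.character(tree$children[[key]])
      kid_sum <- Reduce(`+`, tree$counts[kids])
      expect_equal(tree$counts[[key]], kid_sum,
                   info = sprintf("node %s rep %d", key, rep))
      expect_equal(sum(tree$counts[[key]]), unname(tree$total[key]))
    }
    # slice fractions per node sum to exactly 1 on integer counts
    for (key in as.character(tree$nodes$taxid)) {
      expect_equal(sum(tree$counts[[key]]), unname(tree$total[key]))
    }
  }
})

prune_fixture <- function() {
  db <- tiny_taxonomy()
  # organisms: two species in genus A (superkingdom 2), one in genus B (sk 3)
  tree <- annotate_tree(db, list(pA = c(1001L, 1002L, 1003L),
                                 pB = c(1001L, 1003L)))
  list(db = db, tree = tree)
}

test_that("collapsing a taxon keeps its aggregated counts as a terminal node", {
  fx <- prune_fixture()
  pruned <- prune_tree(fx$tree, list(collapse = "Genus A", partition = NULL))
  expect_false(1001L %in% pruned$nodes$taxid)
  expect_true(101L %in% pruned$nodes$taxid)
  expect_null(pruned$children[["101"]])
  expect_equal(unname(pruned$total["101"]), 2L)
  expect_equal(pruned$counts[["101"]], fx$tree$counts[["101"]])
})

test_that("a partition restricts the tree to one superkingdom subtree", {
  fx <- prune_fixture()
  part <- prune_tree(fx$tree, list(collapse = character(0), partition = "2"))
  expect_equal(part$root, 2L)
  expect_setequal(part$nodes$taxid, c(2L, 11L, 101L, 1001L, 1002L))
  expect_equal(unname(part$total["2"]), 2L)
  expect_error(prune_tree(fx$tree, list(collapse = character(0),
                                        partition = "Atlantis")),
               class = "taxoprofile_validation_error")
})

test_that("empty prune config is the identity; unresolvable entries warn", {
  fx <- prune_fixture()
  same <- prune_tree(fx$tree)
  expect_equal(same$nodes, fx$tree$nodes)
  expect_equal(same$counts, fx$tree$counts)
  expect_warning(prune_tree(fx$tree, list(collapse = "Nonexistent taxon",
                                          partition = NULL)), "skipped")
})

test_that("partition after annotation equals annotating the restricted sets", {
  fx <- prune_fixture()
  part <- prune_tree(fx$tree, list(collapse = character(0), partition = "2"))
  direct <- annotate_tree(fx$db, list(pA = c(1001L, 1002L), pB = 1001L))
  direct_sub <- prune_tree(direct, list(collapse = character(0), partition = "2"))
  expect_setequal(part$nodes$taxid, direct_sub$nodes$taxid)
  keys <- as.character(sort(part$nodes$taxid))
  expect_equal(part$counts[keys], direct_sub$counts[keys])
})

test_that("rendered outputs: counts TSV, Newick round trip, color validation", {
  fx <- prune_fixture()
  dir <- withr::local_tempdir()
  paths <- render_tree(fx$tree,
                       graphic_path = file.path(dir, "tree.pdf"),
                       newick_path = file.path(dir, "tree.nwk"),
                       counts_path = file.path(dir, "counts.tsv"))
  expect_true(all(file.exists(unlist(paths))))
  counts <- utils::read.delim(paths$counts)
  expect_equal(sort(names(counts)),
               sort(c("taxid", "name", "rank", "parent", "total_organisms",
                      "combo_pA", "combo_pB", "combo_pA.pB")))
  expect_equal(counts$total_organisms[counts$taxid == 1L], 3L)
  expect_equal(sum(counts$total_organisms[counts$rank == "species"]), 3L)

  phy <- ape::read.tree(paths$newick)
  expect_equal(sort(phy$tip.label),
               sort(c("Species_A1_1001", "Species_A2_1002", "Species_B1_1003")))

  expect_error(render_tree(fx$tree, colors = c("#fff", "#000"),
                           newick_path = file.path(dir, "x.nwk")),
               class = "taxoprofile_config_error")
})

test_that("a single-protein tree uses one combination category", {
  db <- tiny_taxonomy()
  tree <- annotate_tree(db, list(solo = c(1001L, 1003L)))
  expect_true(all(vapply(tree$counts, length, 0L) == 1L))
  expect_equal(unname(tree$total["1"]), 2L)
})

test_that("prune configuration files parse collapse entries and partitions", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "Genus A", "1003", "partition: 2"), tmp)
  cfg <- read_prune_config(tmp)
  expect_equal(cfg$collapse, c("Genus A", "1003"))
  expect_equal(cfg$partition, "2")
})
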