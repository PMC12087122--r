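# Synthetic-data generator: miniature taxonomy dumps and BLAST XML2
# documents with controlled presence-absence structure, so every pipeline
# stage is testable without network access or real databases. The
# generator emulates the *structure* of homology-search output only; it
# does not simulate sequence evolution.

#' Specification of a synthetic presence-absence study
#'
#' Describes a miniature clade layout and per-protein presence rules from
#' which [make_taxonomy()] and [make_blast_results()] draw deterministic
#' fixtures: the same seed always produces byte-identical outputs. The
#' defaults describe the generator's reference conditions: 10 clades split
#' over two superkingdoms, 5 species per clade (50 organisms), a 20%
#' chance of a strain below each species, three proteins with presence
#' fractions 0.6/0.5/0.5, log-uniform e-values in `[1e-120, 1e-10]`,
#' normal(400, 30) subject lengths, two seeds per protein, and one crafted
#' cross-hit accession shared between the first two proteins.
#'
#' @param n_clades number of clades (>= 1), alternating between the two
#'   superkingdoms.
#' @param species_per_clade species per clade (>= 1).
#' @param strain_fraction probability that a species carries one strain.
#' @param proteins named list; each entry a list with `fraction` (scalar
#'   or one value per clade, in `[0, 1]`), `evalue_range` (positive,
#'   `c(low, high)`), `length_mean` (scalar or mixture component means)
#'   and `length_sd`.
#' @param seeds_per_protein seed (query) sequences per protein.
#' @param query_length seed sequence length in aa.
#' @param cross_hit plant one shared accession between the first two
#'   proteins (exercises the cross-hit matrix path)?
#' @param seed RNG seed; all outputs are a pure function of the spec.
#' @return object of class `presence_spec`.
#' @export
presence_spec <- function(n_clades = 10L, species_per_clade = 5L,
                          strain_fraction = 0.2,
                          proteins = list(
                            protA = list(fraction = 0.6),
                            protB = list(fraction = 0.5),
                            protC = list(fraction = 0.5)
                          ),
                          seeds_per_protein = 2L, query_length = 500L,
                          cross_hit = TRUE, seed = 42L) {
  if (n_clades < 1L) stop_validation("need at least 1 clade")
  if (species_per_clade < 1L) stop_validation("need at least 1 species per clade")
  if (!length(proteins) || is.null(names(proteins))) {
    stop_validation("proteins must be a named list")
  }
  defaults <- list(fraction = 0.5, evalue_range = c(1e-120, 1e-10),
                   length_mean = 400, length_sd = 30)
  proteins <- lapply(proteins, function(p) {
    p <- utils::modifyList(defaults, p)
    if (any(p$fraction < 0 | p$fraction > 1)) {
      stop_validation("presence fractions must lie in [0, 1]")
    }
    if (length(p$fraction) != 1L && length(p$fraction) != n_clades) {
      stop_validation("fraction must be scalar or one value per clade")
    }
    if (any(p$evalue_range <= 0)) stop_validation("evalue_range must be positive")
    p$evalue_range <- sort(p$evalue_range)
    p
  })
  structure(list(n_clades = as.integer(n_clades),
                 species_per_clade = as.integer(species_per_clade),
                 strain_fraction = strain_fraction, proteins = proteins,
                 seeds_per_protein = as.integer(seeds_per_protein),
                 query_length = as.integer(query_length),
                 cross_hit = isTRUE(cross_hit), seed = as.integer(seed)),
            class = "presence_spec")
}

with_fixture_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed + offset)
  code
}

#' Generate a miniature taxonomy
#'
#' Emits taxdump-dialect nodes/names texts for the spec's clade layout:
#' root, two superkingdoms, one phylum ("clade") and genus per clade,
#' species leaves, and strain nodes of rank `"no rank"` below a random
#' subset of species. Taxids are assigned on a fixed scheme (superkingdoms
#' 2-3, clades 10+, genera 100+, species 1000+, strains 10000+).
#'
#' @param spec a [presence_spec()].
#' @return list with `nodes` and `names` (character vectors of dump
#'   lines) and `organisms`, a data.frame of the species (taxid, name,
#'   clade, superkingdom, strain_taxid or `NA`).
#' @export
make_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "presence_spec"))
  nodes <- c("1\t|\t1\t|\tno rank\t|")
  names_l <- c("1\t|\troot\t|\t\t|\tscientific name\t|")
  sk_tax <- c(2L, 3L)
  sk_name <- c("Synthobacteria", "Synthokaryota")
  for (s in 1:2) {
    nodes <- c(nodes, sprintf("%d\t|\t1\t|\tsuperkingdom\t|", sk_tax[s]))
    names_l <- c(names_l, sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                                  sk_tax[s], sk_name[s]))
  }
  org <- list()
  with_fixture_seed(spec$seed, 0L, {
    for (i in seq_len(spec$n_clades)) {
      sk <- sk_tax[(i - 1L) %% 2L + 1L]
      clade_tax <- 10L + i
      genus_tax <- 100L + i
      nodes <- c(nodes,
                 sprintf("%d\t|\t%d\t|\tphylum\t|", clade_tax, sk),
                 sprintf("%d\t|\t%d\t|\tgenus\t|", genus_tax, clade_tax))
      names_l <- c(names_l,
                   sprintf("%d\t|\tClade_%02d\t|\t\t|\tscientific name\t|",
                           clade_tax, i),
                   sprintf("%d\t|\tCladogenus_%02d\t|\t\t|\tscientific name\t|",
                           genus_tax, i))
      for (j in seq_len(spec$species_per_clade)) {
        sp_tax <- 1000L + 10L * i + j
        sp_name <- sprintf("Organism_%02d_%d", i, j)
        nodes <- c(nodes, sprintf("%d\t|\t%d\t|\tspecies\t|", sp_tax, genus_tax))
        names_l <- c(names_l, sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                                      sp_tax, sp_name))
        strain_tax <- NA_integer_
        if (stats::runif(1) < spec$strain_fraction) {
          strain_tax <- 10000L + sp_tax
          nodes <- c(nodes, sprintf("%d\t|\t%d\t|\tno rank\t|", strain_tax, sp_tax))
          names_l <- c(names_l, sprintf("%d\t|\t%s strain S1\t|\t\t|\tscientific name\t|",
                                        strain_tax, sp_name))
        }
        org[[length(org) + 1L]] <- data.frame(
          taxid = sp_tax, name = sp_name, clade = i, superkingdom = sk,
          strain_taxid = strain_tax, stringsAsFactors = FALSE)
      }
    }
  })
  list(nodes = nodes, names = names_l, organisms = do.call(rbind, org))
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Realise the presence draws and hit parameters of a spec
#'
#' Draws, deterministically from the spec's seed, which organisms are
#' present for which protein and the per-seed hit parameters (e-value,
#' subject length, coordinates, strain attribution, synthetic aligned
#' sequence). This realisation is the planted ground truth against which
#' pipeline recovery can be compared.
#'
#' @param spec a [presence_spec()].
#' @param taxonomy result of [make_taxonomy()] for the same spec.
#' @return data.frame with one row per (protein, seed, present organism):
#'   `protein`, `seed_id`, `organism` (species taxid), `subject_taxid`
#'   (species or strain), `subject_accession`, `evalue`, `subject_length`,
#'   `query_start`, `query_end`, `bitscore`, `aligned_subject_seq`.
#' @export
realize_presence <- function(spec, taxonomy = make_taxonomy(spec)) {
  orgs <- taxonomy$organisms
  rows <- list()
  with_fixture_seed(spec$seed, 1L, {
    for (p_idx in seq_along(spec$proteins)) {
      p_name <- names(spec$proteins)[p_idx]
      rule <- spec$proteins[[p_idx]]
      frac <- if (length(rule$fraction) == 1L) {
        rep(rule$fraction, spec$n_clades)
      } else {
        rule$fraction
      }
      present <- stats::runif(nrow(orgs)) < frac[orgs$clade]
      for (s in seq_len(spec$seeds_per_protein)) {
        seed_id <- sprintf("%s_seed%d", p_name, s)
        for (k in which(present)) {
          ev <- 10^stats::runif(1, log10(rule$evalue_range[1L]),
                                log10(rule$evalue_range[2L]))
          comp <- sample.int(length(rule$length_mean), 1L)
          len <- max(60L, as.integer(round(stats::rnorm(
            1, rule$length_mean[comp],
            rule$length_sd[min(comp, length(rule$length_sd))]))))
          subject <- orgs$taxid[k]
          if (!is.na(orgs$strain_taxid[k]) && stats::runif(1) < 0.5) {
            subject <- orgs$strain_taxid[k]
          }
          span <- as.integer(round(stats::runif(1, 0.5, 0.95) *
                                     min(len, spec$query_length)))
          span <- max(30L, span)
          qstart <- sample.int(spec$query_length - span + 1L, 1L)
          seq <- paste(sample(AA_ALPHABET, span, replace = TRUE), collapse = "")
          if (stats::runif(1) < 0.3) {  # occasional gapped segment
            at <- sample.int(span - 1L, 1L)
            seq <- paste0(substr(seq, 1L, at), "-", substr(seq, at + 1L, span))
          }
          rows[[length(rows) + 1L]] <- data.frame(
            protein = p_name, seed_id = seed_id, organism = orgs$taxid[k],
            subject_taxid = subject,
            subject_accession = sprintf("SYN_%s_%05d", p_name, orgs$taxid[k]),
            evalue = ev, subject_length = len,
            query_start = qstart, query_end = qstart + span - 1L,
            bitscore = round(max(35, -1.6 * log10(ev) + stats::rnorm(1, 0, 2)), 1),
            aligned_subject_seq = seq, stringsAsFactors = FALSE)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  if (spec$cross_hit && length(spec$proteins) >= 2L && !is.null(out)) {
    p1 <- names(spec$proteins)[1L]
    p2 <- names(spec$proteins)[2L]
    shared <- intersect(out$organism[out$protein == p1],
                        out$organism[out$protein == p2])
    if (length(shared)) {
      o <- min(shared)
      tmpl <- function(protein, evalue) {
        data.frame(protein = protein,
                   seed_id = sprintf("%s_seed1", protein), organism = o,
                   subject_taxid = o, subject_accession = "CROSSHIT_0001",
                   evalue = evalue, subject_length = 400L,
                   query_start = 1L, query_end = 400L,
                   bitscore = round(-1.6 * log10(evalue), 1),
                   aligned_subject_seq = paste(rep("M", 40L), collapse = ""),
                   stringsAsFactors = FALSE)
      }
      out <- rbind(out, tmpl(p1, 1e-60), tmpl(p2, 1e-45))
    }
  }
  rownames(out) <- NULL
  out
}

#' Planted per-protein organism sets
#'
#' The ground truth of a realisation: for each protein, the sorted unique
#' species taxids with at least one generated hit, optionally restricted
#' to hits at or below an e-value cutoff (the minimum over a protein's
#' occurrences of an accession decides, mirroring the combine step).
#'
#' @param realization a [realize_presence()] result.
#' @param evalue_cutoff optional inclusive cutoff.
#' @return named list, protein -> integer vector of organism taxids.
#' @export
planted_presence <- function(realization, evalue_cutoff = Inf) {
  out <- lapply(split(realization, realization$protein), function(df) {
    best <- tapply(df$evalue, df$organism, min)
    sort(as.integer(names(best)[best <= evalue_cutoff]))
  })
  out[unique(realization$protein)]
}

#' Generate a BLAST XML2 result document
#'
#' Formats the realised hits of one (protein, seed) pair as a BLAST XML2
#' document (single query; one `Hit` with one `Hsp` per present organism)
#' that [parse_blast_xml()] reads back losslessly.
#'
#' @param spec a [presence_spec()].
#' @param protein protein name present in the spec.
#' @param seed_index which seed of the protein (1-based).
#' @param realization optionally, a precomputed [realize_presence()]
#'   result (so several documents share one realisation).
#' @param taxonomy optionally, the matching [make_taxonomy()] result.
#' @return character vector of XML lines.
#' @export
make_blast_results <- function(spec, protein, seed_index = 1L,
                               realization = NULL,
                               taxonomy = make_taxonomy(spec)) {
  if (!(protein %in% names(spec$proteins))) {
    stop_validation(sprintf("unknown protein '%s' in spec", protein))
  }
  if (is.null(realization)) realization <- realize_presence(spec, taxonomy)
  seed_id <- sprintf("%s_seed%d", protein, seed_index)
  df <- realization[realization$protein == protein &
                      realization$seed_id == seed_id, , drop = FALSE]
  name_of <- stats::setNames(
    c(taxonomy$organisms$name,
      sprintf("%s strain S1", taxonomy$organisms$name)),
    c(taxonomy$organisms$taxid, taxonomy$organisms$strain_taxid))
  hits <- character(0)
  if (nrow(df)) {
    df <- df[order(df$evalue, df$subject_accession, method = "radix"), , drop = FALSE]
    for (i in seq_len(nrow(df))) {
      sci <- name_of[as.character(df$subject_taxid[i])]
      if (is.na(sci)) sci <- "synthetic organism"
      span <- nchar(gsub("-", "", df$aligned_subject_seq[i], fixed = TRUE))
      hits <- c(hits, c(
        "        <Hit>",
        sprintf("          <num>%d</num>", i),
        "          <description>",
        "            <HitDescr>",
        sprintf("              <id>gb|%s|</id>", df$subject_accession[i]),
        sprintf("              <accession>%s</accession>", df$subject_accession[i]),
        "              <title>synthetic protein</title>",
        sprintf("              <taxid>%d</taxid>", df$subject_taxid[i]),
        sprintf("              <sciname>%s</sciname>", sci),
        "            </HitDescr>",
        "          </description>",
        sprintf("          <len>%d</len>", df$subject_length[i]),
        "          <hsps>",
        "            <Hsp>",
        "              <num>1</num>",
        sprintf("              <bit-score>%s</bit-score>", fmt_num(df$bitscore[i])),
        sprintf("              <score>%d</score>", as.integer(round(df$bitscore[i] * 2))),
        sprintf("              <evalue>%s</evalue>", fmt_num(df$evalue[i])),
        sprintf("              <identity>%d</identity>", as.integer(round(span * 0.7))),
        sprintf("              <query-from>%d</query-from>", df$query_start[i]),
        sprintf("              <query-to>%d</query-to>", df$query_end[i]),
        "              <hit-from>1</hit-from>",
        sprintf("              <hit-to>%d</hit-to>", span),
        sprintf("              <align-len>%d</align-len>",
                nchar(df$aligned_subject_seq[i])),
        sprintf("              <qseq>%s</qseq>",
                strrep("A", nchar(df$aligned_subject_seq[i]))),
        sprintf("              <hseq>%s</hseq>", df$aligned_subject_seq[i]),
        "            </Hsp>",
        "          </hsps>",
        "        </Hit>"))
    }
  }
  c("<?xml version=\"1.0\"?>",
    "<BlastXML2 xmlns=\"http://www.ncbi.nlm.nih.gov\">",
    "<BlastOutput2>",
    "  <report><Report>",
    "    <program>blastp</program>",
    "    <version>synthetic fixture generator</version>",
    "    <results><Results><search><Search>",
    sprintf("      <query-id>Query_%d</query-id>", seed_index),
    sprintf("      <query-title>%s</query-title>", seed_id),
    sprintf("      <query-len>%d</query-len>", spec$query_length),
    "      <hits>",
    hits,
    "      </hits>",
    "    </Search></search></Results></results>",
    "  </Report></report>",
    "</BlastOutput2>",
    "</BlastXML2>")
}

#' Materialise a complete fixture workspace
#'
#' Initialises a workspace under `root` and fills it from the spec:
#' taxonomy dump under `taxonomy/`, seed FASTA files, per-seed BLAST XML2
#' documents in `blastresults/`, and the protein list and tree
#' configuration. Limits, heatmap and prune configurations are left at
#' their initialised templates (i.e. the documented defaults).
#'
#' @param root directory for the workspace.
#' @param spec a [presence_spec()].
#' @return list with `ws` (the [workspace()]), `spec`, `taxonomy` and
#'   `realization`.
#' @export
make_workspace_fixture <- function(root, spec = presence_spec()) {
  ws <- init_workspace(root)
  tax <- make_taxonomy(spec)
  dir.create(file.path(ws$root, "taxonomy"), showWarnings = FALSE)
  writeLines(tax$nodes, file.path(ws$root, "taxonomy", "nodes.dmp"))
  writeLines(tax$names, file.path(ws$root, "taxonomy", "names.dmp"))
  realization <- realize_presence(spec, tax)

  proteins <- names(spec$proteins)
  writeLines(sprintf("%s %s.fasta", proteins, proteins),
             ws$configs[["proteinlist.txt"]])
  with_fixture_seed(spec$seed, 2L, {
    for (p in proteins) {
      fasta <- character(0)
      for (s in seq_len(spec$seeds_per_protein)) {
        fasta <- c(fasta, sprintf(">%s_seed%d", p, s),
                   paste(sample(AA_ALPHABET, spec$query_length, replace = TRUE),
                         collapse = ""))
      }
      writeLines(fasta, file.path(ws$dirs$fastas, sprintf("%s.fasta", p)))
    }
  })
  for (p in proteins) {
    for (s in seq_len(spec$seeds_per_protein)) {
      writeLines(make_blast_results(spec, p, s, realization, tax),
                 file.path(ws$dirs$blastresults,
                           sprintf("%s__%s_seed%d.xml", p, p, s)))
    }
  }
  writeLines(sprintf("proteins = %s",
                     paste(utils::head(proteins, 3L), collapse = ",")),
             ws$configs[["tree_config.txt"]])
  list(ws = ws, spec = spec, taxonomy = tax, realization = realization)
}
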