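lin <- function(...) paste(..., sep = ";")
B <- "superkingdom:Bacteria"

sim_hit <- function(pid, bit, lineage, subject = "s") {
  data.frame(protein_id = pid, subject_id = subject, bit_score = bit,
             e_value = 1e-20, lineage = lineage, stringsAsFactors = FALSE)
}

test_that("lineage parsing enforces strictly ordered ranks", {
  l <- parse_lineage(lin(B, "phylum:Bacteroidetes", "genus:Prevotella"))
  expect_equal(l$rank, c("superkingdom", "phylum", "genus"))
  expect_error(parse_lineage(lin("genus:X", "phylum:Y")), "ordered")
  expect_error(parse_lineage("kingdomish:X"), "unknown")
  expect_equal(nrow(parse_lineage("")), 0L)
})

test_that("LCA of one hit is its full lineage; no hits leaves unassigned", {
  full <- lin(B, "phylum:Bacteroidetes", "class:Bacteroidia",
              "order:Bacteroidales", "family:Prevotellaceae",
              "genus:Prevotella", "species:Prevotella brevis")
  a <- lca(sim_hit("p1", 300, full))
  expect_equal(a$assigned_rank, "species")
  expect_equal(nrow(a$lineage), 7L)

  none <- lca(sim_hit("p", 1, "x")[0, ])
  expect_equal(none$assigned_rank, "unassigned")
})

test_that("hits to two genera of one order resolve to the order", {
  h <- rbind(
    sim_hit("p1", 300, lin(B, "phylum:Firmicutes", "class:Clostridia",
                           "order:Clostridiales", "family:Ruminococcaceae",
                           "genus:Ruminococcus")),
    sim_hit("p1", 295, lin(B, "phylum:Firmicutes", "class:Clostridia",
                           "order:Clostridiales", "family:Lachnospiraceae",
                           "genus:Butyrivibrio"))
  )
  a <- lca(h)
  expect_equal(a$assigned_rank, "order")
  expect_equal(a$assigned_taxon, "Clostridiales")
})

test_that("the bit-score window drops distant hits before the LCA", {
  h <- rbind(
    sim_hit("p1", 300, lin(B, "phylum:Bacteroidetes", "class:Bacteroidia",
                           "order:Bacteroidales")),
    sim_hit("p1", 100, lin(B, "phylum:Proteobacteria"))  # outside top 10%
  )
  expect_equal(lca(h)$assigned_rank, "order")
  expect_equal(lca(h, top_percent = 100)$assigned_rank, "superkingdom")
})

test_that("LCA equals the common-prefix oracle on exhaustive small fixtures", {
  ranks <- c("superkingdom", "phylum", "class", "order")
  taxa <- list(c("Bacteria"), c("PhyA", "PhyB"), c("ClsA", "ClsB"),
               c("OrdA", "OrdB", "OrdC"))
  make_lineage <- function(depth, picks) {
    paste(vapply(seq_len(depth), function(d)
      paste0(ranks[d], ":", taxa[[d]][picks[d]]), character(1)),
      collapse = ";")
  }
  set.seed(77)
  for (rep in 1:200) {
    n_leaves <- sample(1:6, 1)
    lineages <- vapply(seq_len(n_leaves), function(i) {
      depth <- sample(1:4, 1)
      picks <- vapply(seq_len(4), function(d)
        sample(seq_along(taxa[[d]]), 1), integer(1))
      make_lineage(depth, picks)
    }, character(1))
    h <- do.call(rbind, lapply(seq_along(lineages), function(i)
      sim_hit("p1", 300, lineages[i], subject = paste0("s", i))))
    a <- lca(h, top_percent = 100)
    oracle <- lca_prefix_oracle(lineages)
    if (!length(oracle)) {
      expect_equal(a$assigned_rank, "unassigned")
    } else {
      got <- paste(paste(a$lineage$rank, a$lineage$taxon, sep = ":"),
                   collapse = ";")
      expect_equal(got, paste(oracle, collapse = ";"))
    }
  }
})

test_that("raising top_percent never deepens an assignment", {
  set.seed(5)
  depth_of <- function(a) nrow(a$lineage)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    h <- do.call(rbind, lapply(seq_len(n), function(i) {
      phy <- sample(c("PhyA", "PhyB"), 1)
      cls <- sample(c("ClsA", "ClsB"), 1)
      sim_hit("p1", runif(1, 100, 300),
              lin(B, paste0("phylum:", phy), paste0("class:", cls)),
              subject = paste0("s", i))
    }))
    prev <- Inf
    for (tp in c(1, 10, 50, 100)) {
      d <- depth_of(lca(h, top_percent = tp))
      expect_lte(d, prev)
      prev <- d
    }
  }
})

test_that("category breakdown percentages sum to 100 per category", {
  sim <- simulate_metagenome(sim_config(seed = 19, noise_rate = 0))
  ann <- classify_cazymes(resolve_overlaps(filter_hits(sim$hits)),
                          sim$genes)
  assignments <- lca_assign(sim$sim_hits)
  bd <- taxon_breakdown(assignments, ann, rank = "phylum")
  for (cc in unique(bd$category))
    expect_equal(sum(bd$pct[bd$category == cc]), 100, tolerance = 0.1)
  # planted taxa drive the breakdown: cellulases come mostly from the
  # Firmicutes/Fibrobacteres archetypes in the default community
  cel <- bd[bd$category == "cellulases", ]
  expect_true(all(cel$taxon %in%
                    c("Bacteroidetes", "Firmicutes", "Fibrobacteres")))
})

test_that("structured contributions are recovered as percentages", {
  # 35 cellulase ORFs from phylum A, 35 from B, 10 from C, 20 split
  lins <- c(rep("superkingdom:Bacteria;phylum:A", 35),
            rep("superkingdom:Bacteria;phylum:B", 35),
            rep("superkingdom:Bacteria;phylum:C", 10),
            rep(c("superkingdom:Bacteria;phylum:D",
                  "superkingdom:Bacteria;phylum:E"), 10))
  genes <- make_genes(100)
  hits <- hits_for(genes, rep("GH5", 100))
  ann <- classify_cazymes(hits, genes)
  shits <- do.call(rbind, lapply(seq_len(100), function(i)
    sim_hit(genes$gene_id[i], 300, lins[i])))
  bd <- taxon_breakdown(lca_assign(shits), ann, rank = "phylum")
  cel <- bd[bd$category == "cellulases", ]
  expect_equal(cel$pct[cel$taxon == "A"], 35)
  expect_equal(cel$pct[cel$taxon == "B"], 35)
  expect_equal(cel$pct[cel$taxon == "C"], 10)
})
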