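# build genes + annotations from an ordered vector of family labels
# ("" = plain gene without any domain)
locus_fixture <- function(families, contig = "ctg1") {
  genes <- make_genes(length(families), contig = contig)
  idx <- which(nzchar(families))
  hits <- do.call(rbind, lapply(idx, function(i)
    make_hit(genes$gene_id[i], families[i])))
  if (is.null(hits)) hits <- empty_hits()
  ann <- classify_cazymes(hits, genes)
  list(genes = genes, ann = ann)
}

test_that("tandem SusC-SusD pairs respect the gap rule and order freedom", {
  fx <- locus_fixture(c("SusC", "SusD"))
  expect_equal(nrow(find_sus_pairs(fx$genes, fx$ann)), 1L)

  gap <- locus_fixture(c("SusC", "GH2", "SusD"))
  expect_equal(nrow(find_sus_pairs(gap$genes, gap$ann, 0L)), 0L)
  expect_equal(nrow(find_sus_pairs(gap$genes, gap$ann, 1L)), 1L)

  rev <- locus_fixture(c("SusD-like_2", "SusC"))   # either order, like = SusD
  p <- find_sus_pairs(rev$genes, rev$ann)
  expect_equal(p$susC_gene_id, rev$genes$gene_id[2])

  lone <- locus_fixture(c("SusC", "", "", "GH5"))
  expect_equal(nrow(find_sus_pairs(lone$genes, lone$ann)), 0L)
})

test_that("pairing is greedy left-to-right with each gene used once", {
  fx <- locus_fixture(c("SusC", "SusD", "SusC"))
  p <- find_sus_pairs(fx$genes, fx$ann)
  expect_equal(nrow(p), 1L)
  expect_equal(p$susC_gene_id, fx$genes$gene_id[1])
})

test_that("locus extension joins flanking CAZymes and stops at the window", {
  fx <- locus_fixture(c("GH2", "SusC", "SusD", "GH43"))
  pul <- extend_pul(find_sus_pairs(fx$genes, fx$ann)[1, ],
                    fx$genes, fx$ann)
  expect_equal(pul$member_gene_ids, fx$genes$gene_id)
  expect_setequal(setdiff(pul$cazyme_families, c("SusC", "SusD")),
                  c("GH2", "GH43"))
  expect_equal(pul$n_unknown_function, 0L)

  bare <- locus_fixture(c("", "SusC", "SusD", "", "", "", "", "", "", "GH5"))
  pul2 <- extend_pul(find_sus_pairs(bare$genes, bare$ann)[1, ],
                     bare$genes, bare$ann, window_genes = 5L)
  expect_equal(pul2$member_gene_ids, bare$genes$gene_id[2:3])

  # interior plain genes between the pair and a joining CAZyme are kept
  inner <- locus_fixture(c("SusC", "SusD", "", "", "GH5"))
  pul3 <- extend_pul(find_sus_pairs(inner$genes, inner$ann)[1, ],
                     inner$genes, inner$ann)
  expect_equal(pul3$member_gene_ids, inner$genes$gene_id)
  expect_equal(pul3$n_unknown_function, 2L)
})

test_that("multi-pair loci merge into one PUL with all families", {
  fams <- c("susC", "susD", "susC", "susD", "susE",
            "CE6", "GH10", "GH43", "GH67", "GH5")
  fams <- vapply(fams, function(f) switch(f, susC = "SusC", susD = "SusD",
                                          susE = "SusD-like", f),
                 character(1))
  fx <- locus_fixture(unname(fams))
  puls <- detect_puls(fx$genes, fx$ann)
  expect_equal(nrow(puls), 1L)
  expect_equal(puls$n_sus_pairs, 2L)
  expect_setequal(
    setdiff(strsplit(puls$cazyme_families, ";")[[1]],
            c("SusC", "SusD", "SusD-like")),
    c("CE6", "GH10", "GH43", "GH67", "GH5"))
  expect_equal(puls$n_genes, 10L)
})

test_that("merging honours the rank gap; distant loci stay distinct", {
  far <- locus_fixture(c("SusC", "SusD", rep("", 20), "SusC", "SusD"))
  puls <- detect_puls(far$genes, far$ann)
  expect_equal(nrow(puls), 2L)

  near <- locus_fixture(c("SusC", "SusD", "", "SusC", "SusD"))
  puls2 <- detect_puls(near$genes, near$ann, merge_gap_genes = 2L)
  expect_equal(nrow(puls2), 1L)
  expect_equal(puls2$n_sus_pairs, 2L)
  expect_equal(nrow(detect_puls(near$genes, near$ann, merge = FALSE)), 2L)

  expect_length(merge_puls(list()), 0L)
})

test_that("per-bin summaries list zero-PUL bins and aggregate correctly", {
  puls <- data.frame(pul_id = sprintf("P%02d", 1:37),
                     bin_id = c(rep("b1", 2), rep("b2", 35)),
                     stringsAsFactors = FALSE)
  bins <- data.frame(bin_id = c("b1", "b2", "b3"),
                     stringsAsFactors = FALSE)
  s <- summarize_puls(puls, bins)
  expect_equal(s$per_bin$n_puls, c(2L, 35L, 0L))
  expect_equal(s$min_puls, 2)
  expect_equal(s$max_puls, 35)
  expect_equal(s$mean_puls, 18.5)

  one <- summarize_puls(puls[1:7, ], bins[2, , drop = FALSE])
  expect_equal(one$min_puls, one$max_puls)

  expect_message(
    s0 <- summarize_puls(puls[0, ], bins), "no PULs")
  expect_true(all(s0$per_bin$n_puls == 0L))
  expect_true(is.na(s0$mean_puls))
})

test_that("planted loci are recovered exactly across seeds and K", {
  for (seed in 1:20) {
    k_bins <- seed %% 6L   # 0..5 Bacteroidetes bins -> 0..10 planted PULs
    counts <- c(bacteroidetes = k_bins, firmicutes = 1L)
    counts <- counts[counts > 0]
    sim <- simulate_metagenome(sim_config(seed = seed,
                                          archetype_counts = counts,
                                          noise_rate = 0))
    ann <- classify_cazymes(resolve_overlaps(filter_hits(sim$hits)),
                            sim$genes)
    puls <- detect_puls(sim$genes, ann, bin_map = sim$bin_map)
    expect_equal(nrow(puls), nrow(sim$truth$puls))
    if (nrow(puls)) {
      got <- pul_member_sets(puls)
      want <- pul_member_sets(
        data.frame(member_gene_ids = sim$truth$puls$gene_ids))
      expect_equal(got, want)
      expect_true(all(puls$n_sus_pairs >= 1L))
    }
  }
})

test_that("window and merge-gap parameters act monotonically", {
  fams <- c("SusC", "SusD", "", "", "GH5", "", "", "", "GH43",
            rep("", 4), "SusC", "SusD")
  fx <- locus_fixture(fams)
  prev_members <- -1L
  for (w in 1:8) {
    puls <- detect_puls(fx$genes, fx$ann, window_genes = w, merge = FALSE)
    m <- max(puls$n_genes)
    expect_gte(m, prev_members)
    prev_members <- m
  }
  prev_n <- Inf
  for (g in 0:8) {
    puls <- detect_puls(fx$genes, fx$ann, merge_gap_genes = g)
    expect_lte(nrow(puls), prev_n)
    prev_n <- nrow(puls)
    expect_true(all(puls$n_sus_pairs >= 1L))
  }
})
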