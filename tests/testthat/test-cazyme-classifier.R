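test_that("two-regime e-value filter honours the 80-residue boundary", {
  h <- rbind(
    make_hit("p1", "GH5", e_value = 1e-6, ali_end = 100, model_coverage = 0.4),
    make_hit("p2", "GH5", e_value = 1.0, ali_end = 100, model_coverage = 0.1),
    make_hit("p3", "GH5", e_value = 1e-4, ali_end = 80),   # short regime
    make_hit("p4", "GH5", e_value = 1e-4, ali_end = 81),   # long regime
    make_hit("p5", "GH5", e_value = 1e-10, model_coverage = 0.29)
  )
  kept <- filter_hits(h)$protein_id
  expect_setequal(kept, c("p1", "p3"))
})

test_that("filtering is idempotent and permutation-invariant", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 50
    h <- make_hit(sample(paste0("p", 1:8), n, replace = TRUE),
                  sample(c("GH5", "GH43", "CBM6", "dockerin"), n, TRUE),
                  e_value = 10^-runif(n, 0, 12),
                  bit_score = runif(n, 10, 300),
                  ali_start = s <- sample(1:150, n, TRUE),
                  ali_end = s + sample(40:150, n, TRUE),
                  model_coverage = runif(n))
    f1 <- filter_hits(h)
    expect_identical(filter_hits(f1), f1)
    perm <- h[sample(nrow(h)), ]
    fp <- filter_hits(perm)
    key <- function(x) x[do.call(order, x), ]
    expect_equal(key(fp), key(f1), ignore_attr = TRUE)
    r1 <- resolve_overlaps(f1)
    rp <- resolve_overlaps(fp)
    expect_equal(key(rp), key(r1), ignore_attr = TRUE)
  }
})

test_that("overlap resolution keeps the lower e-value hit and all disjoint hits", {
  overl <- rbind(
    make_hit("p1", "GH5", e_value = 1e-10, ali_start = 1, ali_end = 100),
    make_hit("p1", "GH9", e_value = 1e-5, ali_start = 50, ali_end = 150)
  )
  r <- resolve_overlaps(overl)
  expect_equal(r$family_id, "GH5")

  disj <- rbind(
    make_hit("p1", "GH5", e_value = 1e-10, ali_start = 1, ali_end = 100),
    make_hit("p1", "CBM6", e_value = 1e-5, ali_start = 120, ali_end = 200)
  )
  r2 <- resolve_overlaps(disj)
  expect_equal(nrow(r2), 2L)

  single <- make_hit("p1", "GH5")
  expect_equal(nrow(resolve_overlaps(single)), 1L)
})

test_that("resolved hits never overlap on any protein", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 60
    h <- make_hit(sample(paste0("p", 1:6), n, replace = TRUE),
                  "GH5",
                  e_value = 10^-runif(n, 5, 20),
                  bit_score = runif(n, 10, 300),
                  ali_start = s <- sample(1:200, n, TRUE),
                  ali_end = s + sample(20:120, n, TRUE))
    r <- resolve_overlaps(h)
    for (pid in unique(r$protein_id)) {
      x <- r[r$protein_id == pid, ]
      if (nrow(x) < 2) next
      pairs <- utils::combn(nrow(x), 2)
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1, k]; j <- pairs[2, k]
        expect_true(x$ali_end[i] < x$ali_start[j] ||
                      x$ali_end[j] < x$ali_start[i])
      }
    }
  }
})

test_that("primary class follows the lowest e-value with the fixed tie order", {
  genes <- make_genes(3)
  h <- rbind(
    make_hit(genes$gene_id[1], "GH5", e_value = 1e-20, ali_start = 1,
             ali_end = 100),
    make_hit(genes$gene_id[1], "CBM6", e_value = 1e-8, ali_start = 120,
             ali_end = 200),
    make_hit(genes$gene_id[2], "dockerin", e_value = 1e-9),
    # exact e-value and score tie: GH precedes CE in the class order
    make_hit(genes$gene_id[3], "CE1", e_value = 1e-7, ali_start = 120,
             ali_end = 200),
    make_hit(genes$gene_id[3], "GH43", e_value = 1e-7, ali_start = 1,
             ali_end = 100)
  )
  ann <- classify_cazymes(h, genes)
  expect_equal(ann$primary_class, c("GH", "cellulosome", "GH"))
  expect_true(ann$is_multidomain[1])
  expect_true(ann$has_dockerin[2])
  expect_error(classify_cazymes(make_hit("ghost", "GH5"), genes), "ghost")
})

test_that("GH-dockerin fusions carry both the GH class and the flag", {
  genes <- make_genes(1)
  h <- rbind(
    make_hit(genes$gene_id, "GH13", e_value = 1e-15, ali_start = 1,
             ali_end = 120),
    make_hit(genes$gene_id, "dockerin", e_value = 1e-6, ali_start = 150,
             ali_end = 220)
  )
  ann <- classify_cazymes(h, genes)
  expect_equal(ann$primary_class, "GH")
  expect_true(ann$has_dockerin)
})

test_that("substrate categories follow the best GH family", {
  genes <- make_genes(3)
  h <- rbind(make_hit(genes$gene_id[1], "GH5"),
             make_hit(genes$gene_id[2], "GH43"),
             make_hit(genes$gene_id[3], "GH57"))
  ann <- classify_cazymes(h, genes)
  cats <- categorize_gh(ann)
  expect_equal(cats$category,
               c("cellulases", "oligosaccharide_degrading", "uncategorized"))
  bad_map <- list(a = c("GH5"), b = c("GH5"))
  expect_error(categorize_gh(ann, bad_map), "disjoint")
})

test_that("scaffoldin calls combine the score cutoff and tandem cohesins", {
  genes <- make_genes(2)
  h <- rbind(
    make_hit(genes$gene_id[2], "cohesin", e_value = 1e-9, ali_start = 1,
             ali_end = 80),
    make_hit(genes$gene_id[2], "cohesin", e_value = 1e-8, ali_start = 100,
             ali_end = 180),
    make_hit(genes$gene_id[2], "cohesin", e_value = 1e-7, ali_start = 200,
             ali_end = 280)
  )
  ann <- classify_cazymes(h, genes)
  scores <- data.frame(protein_id = c(genes$gene_id[1], "pX"),
                       template_id = c("CipA", "ScaB"),
                       score = c(750, 699), stringsAsFactors = FALSE)
  calls <- call_scaffoldins(ann, scores)
  expect_setequal(calls$mode, c("score_cutoff", "multi_cohesin"))
  expect_false("pX" %in% calls$protein_id)    # 699 < 700, strict screen
  mc <- calls[calls$mode == "multi_cohesin", ]
  expect_equal(mc$evidence, 3)
})

test_that("planted families are recovered exactly on noiseless synthetic data", {
  sim <- simulate_metagenome(sim_config(seed = 3, noise_rate = 0))
  ann <- classify_cazymes(resolve_overlaps(filter_hits(sim$hits)),
                          sim$genes)
  got <- ann[ann$primary_class != "none", c("protein_id", "families")]
  planted <- vapply(
    split(sim$truth$annotations$family_id, sim$truth$annotations$protein_id),
    function(f) paste(sort(f), collapse = ";"), character(1))
  expect_setequal(got$protein_id, names(planted))
  got_sorted <- vapply(strsplit(got$families, ";", fixed = TRUE),
                       function(f) paste(sort(f), collapse = ";"),
                       character(1))
  expect_equal(got_sorted, unname(planted[got$protein_id]))
})
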