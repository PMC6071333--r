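# Archetype profiles emulate the broad statistical structure seen in
# fiber-adherent rumen communities: Bacteroidetes-like bins rich in
# oligosaccharide degraders (GH2/GH3/GH43) and carrying PULs;
# Firmicutes-like bins rich in cellulases (GH5/GH9) and starch enzymes
# (GH13) with cellulosome components and the buk butyrate route;
# Fibrobacteres-like bins with cellulases/hemicellulases but no
# dockerin/cohesin.  Counts are per-bin planted gene counts.
.default_archetypes <- function() {
  list(
    bacteroidetes = list(
      families = c(GH2 = 6, GH3 = 6, GH43 = 8, GH28 = 3, GH10 = 2,
                   GH53 = 2, GH51 = 2, GH78 = 2, GH5 = 1, GH9 = 1,
                   CE1 = 2, CE10 = 2, CBM50 = 1, GT2 = 2),
      fusions = list(),
      puls = list(c("GH2", "susC", "susD", "GH43"),
                  c("susC", "susD", "susC", "susD",
                    "GH10", "GH43", "GH67", "GH5", "CE6")),
      markers = c("acka", "pta", "mmda", "but"),
      gc = 0.47,
      lineage = paste0("superkingdom:Bacteria;phylum:Bacteroidetes;",
                       "class:Bacteroidia;order:Bacteroidales;",
                       "family:Prevotellaceae;genus:Prevotella;",
                       "species:Prevotella camelicola")
    ),
    firmicutes = list(
      families = c(GH5 = 4, GH9 = 3, GH13 = 5, GH2 = 2, GH3 = 3,
                   GH43 = 2, GH10 = 2, GH26 = 1, CE1 = 1, GT2 = 2,
                   CBM50 = 2, dockerin = 3, SLH = 1),
      fusions = list(c("GH5", "dockerin"),
                     c("cohesin", "cohesin", "cohesin")),
      puls = list(),
      markers = c("acka", "pta", "mmda", "buk"),
      gc = 0.44,
      lineage = paste0("superkingdom:Bacteria;phylum:Firmicutes;",
                       "class:Clostridia;order:Clostridiales;",
                       "family:Ruminococcaceae;genus:Ruminococcus;",
                       "species:Ruminococcus dromedarii")
    ),
    fibrobacteres = list(
      families = c(GH5 = 4, GH9 = 3, GH45 = 2, GH74 = 2, GH8 = 2,
                   GH10 = 3, GH11 = 2, GH26 = 2, GH53 = 2, CBM6 = 2,
                   PL1 = 2, CE1 = 1),
      fusions = list(),
      puls = list(),
      markers = c("acka", "pta", "mmda"),
      gc = 0.49,
      lineage = paste0("superkingdom:Bacteria;phylum:Fibrobacteres;",
                       "class:Fibrobacteria;order:Fibrobacterales;",
                       "family:Fibrobacteraceae;genus:Fibrobacter;",
                       "species:Fibrobacter succinogenes")
    )
  )
}

#' Simulation configuration for the synthetic metagenome generator
#'
#' @param seed integer seed; all randomness in [simulate_metagenome()]
#'   flows from it through one generator stream.
#' @param archetype_counts named integer vector: how many bins of each
#'   archetype (`bacteroidetes`, `firmicutes`, `fibrobacteres`).
#' @param contigs_per_bin integer range (min, max).
#' @param genes_per_contig integer range (min, max).
#' @param noise_rate per-protein probability of a decoy domain hit.
#' @param noise_pass_fraction fraction of decoys drawn to pass the
#'   filtering thresholds (the rest are drawn with model coverage below
#'   0.30 so they are guaranteed to fail).
#' @param pul_flank_genes plain genes planted between/around PUL templates
#'   (must exceed the detector's extension window for exact recovery).
#' @param total_reads total simulated clean reads for the abundance table.
#' @param archetypes archetype definitions; see source for the default
#'   community structure.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       archetype_counts = c(bacteroidetes = 3L,
                                            firmicutes = 2L,
                                            fibrobacteres = 1L),
                       contigs_per_bin = c(3L, 4L),
                       genes_per_contig = c(40L, 55L),
                       noise_rate = 0.1,
                       noise_pass_fraction = 0,
                       pul_flank_genes = 8L,
                       total_reads = 1e6,
                       archetypes = .default_archetypes()) {
  stopifnot(noise_rate >= 0, noise_rate <= 1,
            noise_pass_fraction >= 0, noise_pass_fraction <= 1,
            all(names(archetype_counts) %in% names(archetypes)))
  structure(list(
    seed = as.integer(seed),
    archetype_counts = archetype_counts,
    contigs_per_bin = contigs_per_bin,
    genes_per_contig = genes_per_contig,
    noise_rate = noise_rate,
    noise_pass_fraction = noise_pass_fraction,
    pul_flank_genes = as.integer(pul_flank_genes),
    total_reads = total_reads,
    archetypes = archetypes
  ), class = "sim_config")
}

# map a PUL template token to a domain family id
.template_family <- function(tok) {
  switch(tok, susC = "SusC", susD = "SusD", susE = "SusD-like", tok)
}

# one true domain hit row for a planted family on a protein; the alignment
# block is chosen so hits on one protein never overlap and always pass the
# dbCAN-style filter (e-value well below 1e-5, coverage >= 0.5)
.true_hit <- function(protein_id, family_id, block_start, block_end) {
  hmm_len <- 200L
  cov <- stats::runif(1, 0.5, 0.95)
  # cap the alignment at the block so hits on one protein never overlap
  len <- min(block_end - block_start + 1L,
             as.integer(stats::runif(1, 90, 200)))
  data.frame(
    protein_id = protein_id, family_id = family_id,
    e_value = 10^-stats::runif(1, 10, 25),
    bit_score = stats::runif(1, 80, 400),
    ali_start = block_start,
    ali_end = block_start + len - 1L,
    hmm_start = 1L, hmm_end = as.integer(round(cov * hmm_len)),
    hmm_length = hmm_len,
    stringsAsFactors = FALSE
  )
}

#' Generate a seeded synthetic metagenome with planted ground truth
#'
#' Emits the full set of tables the pipeline consumes — contigs, ordered
#' gene models, HMM domain hits (true hits always pass the filter; decoys
#' drawn at `noise_rate`, failing or passing the filter in the configured
#' proportion), planted SusC-SusD-anchored loci, per-bin marker-gene
#' inventories, bin QC/membership/read-count tables and taxonomy-annotated
#' similarity hits — together with the planted truth needed to verify every
#' downstream stage.  With `outdir` set, all files are also written in the
#' standard formats (FASTA, GFF3, TSV, plus `ground_truth.json`);
#' re-running with the same seed reproduces them byte-for-byte.
#'
#' @param config [sim_config()] object.
#' @param outdir optional directory to write files into.
#' @return list: `contigs`, `genes`, `hits` (domain hits incl. hmm
#'   columns), `bin_map`, `bin_qc`, `sim_hits` (similarity hits),
#'   `read_counts`, `total_reads`, `truth` (list: `annotations`,
#'   `census`, `puls`, `pathways`, `taxa`), `config`, and `files` (named
#'   paths) when `outdir` is given.
#' @export
simulate_metagenome <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  flank <- config$pul_flank_genes
  # pre-flight: every PUL template set must fit the largest allowed contig
  for (arch in names(config$archetype_counts)) {
    tpl <- config$archetypes[[arch]]$puls
    if (length(tpl)) {
      needed <- sum(lengths(tpl)) + flank * (length(tpl) + 1L)
      if (needed > config$genes_per_contig[2])
        stop("unsatisfiable PUL template set for archetype '", arch,
             "': needs ", needed, " genes, contigs allow at most ",
             config$genes_per_contig[2])
    }
  }
  bins <- rep(names(config$archetype_counts), config$archetype_counts)
  bin_ids <- sprintf("bin%02d", seq_along(bins))

  contigs <- list(); genes <- list(); hits <- list()
  truth_ann <- list(); truth_puls <- list(); truth_taxa <- list()
  sim_hits <- list(); bin_rows <- list()
  pathway_rows <- list()

  for (bi in seq_along(bins)) {
    arch_name <- bins[bi]
    arch <- config$archetypes[[arch_name]]
    bin_id <- bin_ids[bi]
    n_ctg <- sample(seq(config$contigs_per_bin[1],
                        config$contigs_per_bin[2]), 1)
    pul_tpl <- arch$puls
    ctg_meta <- list()
    free_slots <- list()   # non-PUL gene slots: (contig idx, gene idx)
    for (ci in seq_len(n_ctg)) {
      ctg_id <- sprintf("%s_c%02d", bin_id, ci)
      n_genes <- sample(seq(config$genes_per_contig[1],
                            config$genes_per_contig[2]), 1)
      on_pul_contig <- ci == 1L && length(pul_tpl) > 0L
      if (on_pul_contig) {
        needed <- sum(lengths(pul_tpl)) + flank * (length(pul_tpl) + 1L)
        n_genes <- max(n_genes, needed)
      }
      aa <- sample(150:400, n_genes, replace = TRUE)
      gaps <- sample(20:120, n_genes, replace = TRUE)
      width <- 3L * (aa + 1L)
      end <- cumsum(gaps + width)
      start <- end - width + 1L
      strand <- sample(c("+", "-"), n_genes, replace = TRUE)
      gid <- sprintf("%s_g%03d", ctg_id, seq_len(n_genes))
      fam_of <- vector("list", n_genes)   # planted families per gene
      if (on_pul_contig) {
        cursor <- flank + 1L
        for (ti in seq_along(pul_tpl)) {
          toks <- pul_tpl[[ti]]
          idx <- seq(cursor, cursor + length(toks) - 1L)
          for (k in seq_along(toks))
            fam_of[[idx[k]]] <- .template_family(toks[k])
          truth_puls[[length(truth_puls) + 1L]] <- data.frame(
            bin_id = bin_id, contig_id = ctg_id, template = ti,
            gene_ids = paste(gid[idx], collapse = ";"),
            stringsAsFactors = FALSE
          )
          cursor <- cursor + length(toks) + flank
        }
      } else {
        free_slots[[length(free_slots) + 1L]] <-
          data.frame(ci = ci, gi = seq_len(n_genes))
      }
      ctg_meta[[ci]] <- list(
        contig_id = ctg_id, gene_id = gid, aa = aa, start = start,
        end = end, strand = strand, fam_of = fam_of,
        symbols = character(n_genes),
        length_bp = end[n_genes] + 60L
      )
    }
    # scatter the family profile and fusion proteins over non-PUL contigs
    profile <- rep(names(arch$families), arch$families)
    slots <- do.call(rbind, free_slots)
    n_needed <- length(profile) + length(arch$fusions)
    if (n_needed + length(arch$markers) > nrow(slots))
      stop("bin ", bin_id, " has too few non-locus gene slots (",
           nrow(slots), ") for its family profile plus markers (",
           n_needed + length(arch$markers), "); increase contigs_per_bin ",
           "or genes_per_contig")
    pick <- slots[sample(nrow(slots), n_needed), , drop = FALSE]
    assignments <- c(as.list(profile), arch$fusions)
    for (k in seq_len(n_needed)) {
      ci <- pick$ci[k]; gi <- pick$gi[k]
      ctg_meta[[ci]]$fam_of[[gi]] <- assignments[[k]]
    }
    # markers on plain genes of non-PUL contigs
    remaining <- slots[!(paste(slots$ci, slots$gi) %in%
                           paste(pick$ci, pick$gi)), , drop = FALSE]
    mk_pick <- remaining[sample(nrow(remaining), length(arch$markers)), ,
                         drop = FALSE]
    for (k in seq_along(arch$markers)) {
      ci <- mk_pick$ci[k]; gi <- mk_pick$gi[k]
      ctg_meta[[ci]]$symbols[gi] <- arch$markers[k]
    }
    has <- function(m) m %in% arch$markers
    pathway_rows[[bi]] <- data.frame(
      bin_id = bin_id,
      acetate = has("acka") && has("pta"),
      propionate_succinate = has("mmda"),
      propionate_acrylate = has("lcda"),
      propionate_propanediol = has("pdup") || has("pduq"),
      butyrate_buk = has("buk"),
      butyrate_but = has("but"),
      stringsAsFactors = FALSE
    )
    # materialize tables for this bin
    for (ci in seq_len(n_ctg)) {
      m <- ctg_meta[[ci]]
      contigs[[length(contigs) + 1L]] <- data.frame(
        contig_id = m$contig_id, length_bp = m$length_bp,
        gc_fraction = arch$gc, bin_id = bin_id, stringsAsFactors = FALSE
      )
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = m$gene_id, contig_id = m$contig_id, start = m$start,
        end = m$end, strand = m$strand,
        rank_on_contig = seq_along(m$gene_id) - 1L,
        protein_length_aa = m$aa, gene_symbols = m$symbols,
        is_full_length = TRUE, stringsAsFactors = FALSE
      )
      for (gi in seq_along(m$gene_id)) {
        fams <- m$fam_of[[gi]]
        if (is.null(fams)) next
        # partition the protein into non-overlapping alignment blocks
        L <- m$aa[gi]
        bnd <- floor(seq(1, L + 1, length.out = length(fams) + 1L))
        for (k in seq_along(fams)) {
          hits[[length(hits) + 1L]] <-
            .true_hit(m$gene_id[gi], fams[k], bnd[k], bnd[k + 1L] - 1L)
        }
        truth_ann[[length(truth_ann) + 1L]] <- data.frame(
          protein_id = m$gene_id[gi],
          family_id = fams, stringsAsFactors = FALSE
        )
        truth_taxa[[length(truth_taxa) + 1L]] <- data.frame(
          protein_id = m$gene_id[gi], lineage = arch$lineage,
          stringsAsFactors = FALSE
        )
        # similarity hits: two near-best hits to the source species, one
        # distant hit outside the default top-10% bit-score window
        best <- stats::runif(1, 200, 400)
        sim_hits[[length(sim_hits) + 1L]] <- data.frame(
          protein_id = rep(m$gene_id[gi], 3L),
          subject_id = paste0(m$gene_id[gi], "_s", 1:3),
          bit_score = c(best, best * stats::runif(1, 0.92, 0.99),
                        best * 0.7),
          e_value = c(1e-30, 1e-25, 1e-10),
          lineage = c(arch$lineage, arch$lineage,
                      "superkingdom:Bacteria;phylum:Proteobacteria"),
          stringsAsFactors = FALSE
        )
      }
    }
    bin_rows[[bi]] <- data.frame(
      bin_id = bin_id,
      size_bp = sum(vapply(ctg_meta, `[[`, numeric(1), "length_bp")),
      gc_percent = 100 * arch$gc,
      n_contigs = n_ctg,
      completeness = round(stats::runif(1, 55, 99), 1),
      contamination = round(stats::runif(1, 0, 9), 2),
      strain_heterogeneity = round(stats::runif(1, 0, 50), 1),
      taxonomy_label = paste0(toupper(substring(arch_name, 1, 1)),
                              substring(arch_name, 2)),
      stringsAsFactors = FALSE
    )
  }

  contigs <- do.call(rbind, contigs)
  genes <- do.call(rbind, genes)
  hits <- do.call(rbind, hits)
  truth_ann <- do.call(rbind, truth_ann)
  truth_taxa <- do.call(rbind, truth_taxa)
  sim_hits <- do.call(rbind, sim_hits)
  bin_qc <- do.call(rbind, bin_rows)
  truth_pathways <- do.call(rbind, pathway_rows)
  truth_puls <- if (length(truth_puls)) do.call(rbind, truth_puls) else
    data.frame(bin_id = character(), contig_id = character(),
               template = integer(), gene_ids = character(),
               stringsAsFactors = FALSE)

  # decoy hits: per-protein Bernoulli(noise_rate); failing decoys get model
  # coverage < 0.30 (guaranteed rejection), passing decoys mimic true hits
  decoy_on <- genes$gene_id[stats::runif(nrow(genes)) < config$noise_rate]
  decoy_pool <- c(paste0("GH", c(13, 18, 23, 25, 31, 57, 77)),
                  paste0("CBM", c(4, 9, 20, 32)), "CE4", "GT4", "AA6")
  if (length(decoy_on)) {
    dec <- lapply(decoy_on, function(pid) {
      L <- genes$protein_length_aa[match(pid, genes$gene_id)]
      fam <- sample(decoy_pool, 1)
      passes <- stats::runif(1) < config$noise_pass_fraction
      if (passes) {
        .true_hit(pid, fam, 1L, L)
      } else {
        hmm_len <- 200L
        cov <- stats::runif(1, 0.05, 0.25)
        len <- min(L, 60L)
        data.frame(
          protein_id = pid, family_id = fam,
          e_value = 10^-stats::runif(1, 0, 8),
          bit_score = stats::runif(1, 10, 40),
          ali_start = 1L, ali_end = len,
          hmm_start = 1L, hmm_end = as.integer(round(cov * hmm_len)),
          hmm_length = hmm_len, stringsAsFactors = FALSE
        )
      }
    })
    hits <- rbind(hits, do.call(rbind, dec))
  }
  rownames(hits) <- NULL
  hits$model_coverage <- (hits$hmm_end - hits$hmm_start + 1) / hits$hmm_length

  bin_map <- unique(contigs[c("contig_id", "bin_id")])
  # mapped reads roughly proportional to bin size with noise
  rel <- bin_qc$size_bp * stats::runif(nrow(bin_qc), 0.5, 2)
  read_counts <- data.frame(
    bin_id = bin_qc$bin_id,
    mapped_reads = round(config$total_reads * 0.6 * rel / sum(rel)),
    stringsAsFactors = FALSE
  )

  # planted census: expected per-class / per-family protein counts at zero
  # passing noise, computed by direct counting over the planted table
  # (primary class = class of the lowest-e-value planted hit)
  best <- hits[order(hits$protein_id, hits$e_value), ]
  best <- best[best$protein_id %in% truth_ann$protein_id, ]
  best <- best[!duplicated(best$protein_id), ]
  per_class <- table(family_class(best$family_id))
  fam_pairs <- unique(truth_ann)
  truth_census <- list(
    n_cazyme_proteins = length(unique(truth_ann$protein_id)),
    per_class_counts = stats::setNames(as.integer(per_class),
                                       names(per_class)),
    per_family_counts = {
      tab <- table(fam_pairs$family_id)
      stats::setNames(as.integer(tab), names(tab))
    }
  )

  result <- list(
    contigs = contigs, genes = genes, hits = hits, bin_map = bin_map,
    bin_qc = bin_qc, sim_hits = sim_hits, read_counts = read_counts,
    total_reads = config$total_reads,
    truth = list(annotations = truth_ann, census = truth_census,
                 puls = truth_puls, pathways = truth_pathways,
                 taxa = truth_taxa),
    config = config
  )
  if (!is.null(outdir)) result$files <- .write_simulation(result, outdir)
  result
}

# write the standard-format file set; random contig sequences are generated
# here (lengths are fixed upstream, so files stay seed-deterministic)
.write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  # FASTA
  seqs <- vapply(sim$contigs$length_bp, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
  fa <- p("contigs.fasta")
  writeLines(paste0(">", sim$contigs$contig_id, "\n", seqs), fa)
  # GFF3
  g <- sim$genes
  gff_attr <- paste0("ID=", g$gene_id,
                     ifelse(nzchar(g$gene_symbols),
                            paste0(";gene=", g$gene_symbols), ""),
                     ";partial=00")
  gff <- p("genes.gff3")
  writeLines(c("##gff-version 3",
               paste(g$contig_id, "sim", "CDS", g$start, g$end, ".",
                     g$strand, "0", gff_attr, sep = "\t")), gff)
  # TSVs
  h <- sim$hits[c("protein_id", "family_id", "e_value", "bit_score",
                  "ali_start", "ali_end", "hmm_start", "hmm_end",
                  "hmm_length")]
  files <- list(
    contigs = fa, gff = gff,
    domain_hits = write_tsv(h, p("domain_hits.tsv")),
    bin_map = write_tsv(sim$bin_map, p("bin_map.tsv")),
    bin_qc = write_tsv(sim$bin_qc, p("bin_qc.tsv")),
    similarity_hits = write_tsv(sim$sim_hits, p("similarity_hits.tsv")),
    read_counts = write_tsv(sim$read_counts, p("read_counts.tsv"))
  )
  gt <- p("ground_truth.json")
  jsonlite::write_json(sim$truth, gt, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  files$ground_truth <- gt
  files
}

#' Draw a pair of null family-count profiles
#'
#' Both count tables are drawn from one shared multinomial (proportions
#' drawn once from a symmetric Dirichlet), so any family-level difference
#' between them is pure sampling noise; used for false-discovery-rate
#' calibration of [compare_profiles()].
#'
#' @param m_families number of families.
#' @param depth_a,depth_b total counts for the two profiles (> 0).
#' @param concentration Dirichlet concentration for the shared
#'   proportions (default 1).
#' @return data.frame `family_id`, `count_a`, `count_b`.
#' @export
null_profile_pair <- function(m_families, depth_a, depth_b,
                              concentration = 1) {
  if (depth_a <= 0 || depth_b <= 0) stop("depths must be > 0")
  stopifnot(m_families >= 1)
  w <- stats::rgamma(m_families, shape = concentration)
  pr <- w / sum(w)
  data.frame(
    family_id = sprintf("F%04d", seq_len(m_families)),
    count_a = as.integer(stats::rmultinom(1, depth_a, pr)),
    count_b = as.integer(stats::rmultinom(1, depth_b, pr)),
    stringsAsFactors = FALSE
  )
}
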