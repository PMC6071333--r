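#' Read contig records from a FASTA file
#'
#' Only headers and lengths are required downstream; sequences are used to
#' compute the GC fraction and then dropped.
#'
#' @param path FASTA file of assembly contigs/scaffolds.
#' @return data.frame with columns `contig_id`, `length_bp`, `gc_fraction`,
#'   `bin_id` (initialised to `NA`, filled by a bin map).
#' @export
read_contigs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicated contig_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gc <- Biostrings::letterFrequency(seqs, letters = "GC", as.prob = TRUE)[, 1]
  data.frame(
    contig_id = ids,
    length_bp = Biostrings::width(seqs),
    gc_fraction = as.numeric(gc),
    bin_id = NA_character_,
    stringsAsFactors = FALSE
  )
}

# parse the attribute column of a GFF3 line set: returns named value or ""
.gff_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else "", character(1))
}

#' Read gene calls from a GFF3 file
#'
#' Keeps CDS features only.  Coordinates are 1-based inclusive per the GFF3
#' standard.  Genes are ranked along each contig in (start, end, gene_id)
#' order.  Marker symbols are taken from the `gene=` attribute
#' (semicolon-within-attribute values are comma separated in GFF3; here any
#' of `,` is honoured), lowercased.  A gene is full length unless a
#' `partial=` attribute other than `00` is present.  Malformed rows
#' (end < start) are rejected with a warning and counted in the
#' `n_rejected` attribute of the result; a CDS on a contig absent from
#' `contigs` is an error.
#'
#' @param path GFF3 file.
#' @param contigs contig table from [read_contigs()] (or any data.frame with
#'   `contig_id` and `length_bp`).
#' @return data.frame with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`, `rank_on_contig` (0-based), `protein_length_aa`,
#'   `gene_symbols` (";"-collapsed, lowercase, "" if none),
#'   `is_full_length`; attribute `n_rejected`.
#' @export
read_gene_calls <- function(path, contigs) {
  stopifnot(all(c("contig_id", "length_bp") %in% names(contigs)))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    out <- .empty_gene_table()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok9 <- lengths(fields) == 9L
  n_rejected <- sum(!ok9)
  fields <- fields[ok9]
  mat <- do.call(rbind, fields)
  keep <- mat[, 3] == "CDS"
  mat <- mat[keep, , drop = FALSE]
  if (!nrow(mat)) {
    out <- .empty_gene_table()
    attr(out, "n_rejected") <- n_rejected
    return(out)
  }
  start <- suppressWarnings(as.integer(mat[, 4]))
  end <- suppressWarnings(as.integer(mat[, 5]))
  bad <- is.na(start) | is.na(end) | end < start
  if (any(bad)) {
    warning(sum(bad), " CDS row(s) with malformed coordinates rejected")
    n_rejected <- n_rejected + sum(bad)
  }
  mat <- mat[!bad, , drop = FALSE]
  start <- start[!bad]; end <- end[!bad]
  contig_id <- mat[, 1]
  unknown <- setdiff(unique(contig_id), contigs$contig_id)
  if (length(unknown))
    stop("gene calls reference unknown contig(s): ",
         paste(unknown, collapse = ", "))
  clen <- contigs$length_bp[match(contig_id, contigs$contig_id)]
  if (any(end > clen))
    stop("CDS end beyond contig length on: ",
         paste(unique(contig_id[end > clen]), collapse = ", "))
  attrs <- mat[, 9]
  gene_id <- .gff_attr(attrs, "ID")
  miss <- !nzchar(gene_id)
  gene_id[miss] <- paste0("gene_", which(miss))
  syms <- tolower(.gff_attr(attrs, "gene"))
  syms <- gsub(",", ";", syms, fixed = TRUE)
  partial <- .gff_attr(attrs, "partial")
  genes <- data.frame(
    gene_id = gene_id,
    contig_id = contig_id,
    start = start,
    end = end,
    strand = mat[, 7],
    rank_on_contig = NA_integer_,
    protein_length_aa = pmax(1L, (end - start + 1L) %/% 3L - 1L),
    gene_symbols = syms,
    is_full_length = !nzchar(partial) | partial == "00",
    stringsAsFactors = FALSE
  )
  ord <- order(genes$contig_id, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank_on_contig <- stats::ave(
    seq_len(nrow(genes)), genes$contig_id,
    FUN = function(i) seq_along(i) - 1L
  )
  rownames(genes) <- NULL
  attr(genes, "n_rejected") <- n_rejected
  genes
}

.empty_gene_table <- function() {
  data.frame(
    gene_id = character(), contig_id = character(),
    start = integer(), end = integer(), strand = character(),
    rank_on_contig = integer(), protein_length_aa = integer(),
    gene_symbols = character(), is_full_length = logical(),
    stringsAsFactors = FALSE
  )
}

#' Read an HMM domain-hit table
#'
#' Expects a TSV with a header row naming (at least) the columns
#' `protein_id`, `family_id`, `e_value`, `bit_score`, `ali_start`,
#' `ali_end`, `hmm_start`, `hmm_end`, `hmm_length` — the per-domain column
#' subset of a HMMER3 `domtblout` after comment stripping.  Lines beginning
#' with `#` are ignored.  Model coverage is computed as
#' `(hmm_end - hmm_start + 1) / hmm_length`.  Rows with a non-numeric
#' e-value or a `family_id` outside the catalog are rejected with a warning
#' and counted in the `n_rejected` attribute.  An empty file yields an
#' empty table.
#'
#' @param path TSV file.
#' @param catalog controlled vocabulary of family ids
#'   (default [cazy_family_catalog()]).
#' @return data.frame with columns `protein_id`, `family_id`, `e_value`,
#'   `bit_score`, `ali_start`, `ali_end`, `model_coverage`; attribute
#'   `n_rejected`.
#' @export
read_domain_hits <- function(path, catalog = cazy_family_catalog()) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) <= 1L) {
    out <- .empty_hit_table()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  df <- utils::read.delim(text = lines, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("protein_id", "family_id", "e_value", "bit_score",
            "ali_start", "ali_end", "hmm_start", "hmm_end", "hmm_length")
  if (!all(need %in% names(df)))
    stop("domain-hit table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  e <- suppressWarnings(as.numeric(df$e_value))
  num <- lapply(df[c("bit_score", "ali_start", "ali_end",
                     "hmm_start", "hmm_end", "hmm_length")],
                function(x) suppressWarnings(as.numeric(x)))
  bad_num <- is.na(e) | Reduce(`|`, lapply(num, is.na))
  bad_fam <- !(df$family_id %in% catalog)
  bad <- bad_num | bad_fam
  if (any(bad))
    warning(sum(bad), " domain-hit row(s) rejected (",
            sum(bad_num), " malformed, ", sum(bad_fam & !bad_num),
            " unknown family)")
  keep <- !bad
  out <- data.frame(
    protein_id = df$protein_id[keep],
    family_id = df$family_id[keep],
    e_value = e[keep],
    bit_score = num$bit_score[keep],
    ali_start = as.integer(num$ali_start[keep]),
    ali_end = as.integer(num$ali_end[keep]),
    model_coverage = (num$hmm_end[keep] - num$hmm_start[keep] + 1) /
      num$hmm_length[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

.empty_hit_table <- function() {
  data.frame(
    protein_id = character(), family_id = character(),
    e_value = numeric(), bit_score = numeric(),
    ali_start = integer(), ali_end = integer(),
    model_coverage = numeric(), stringsAsFactors = FALSE
  )
}

#' Read a similarity-hit table with taxonomic lineages
#'
#' Expects TSV columns `protein_id`, `subject_id`, `bit_score`, `e_value`,
#' `lineage`, where `lineage` is a semicolon-delimited list of `rank:name`
#' tokens ordered superkingdom to species (possibly truncated).  Hits are
#' filtered at `e_value <= max_evalue` and at most `max_targets` hits per
#' protein are kept (best bit scores), mirroring the usual BlastP screen
#' ahead of lowest-common-ancestor assignment.
#'
#' @param path TSV file.
#' @param max_evalue e-value ceiling (default 1e-3).
#' @param max_targets per-protein cap (default 20).
#' @return data.frame with the columns above.
#' @export
read_similarity_hits <- function(path, max_evalue = 1e-3, max_targets = 20L) {
  df <- .read_tsv(path)
  need <- c("protein_id", "subject_id", "bit_score", "e_value", "lineage")
  if (!all(need %in% names(df)))
    stop("similarity-hit table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$bit_score <- as.numeric(df$bit_score)
  df$e_value <- as.numeric(df$e_value)
  df <- df[df$e_value <= max_evalue, , drop = FALSE]
  if (nrow(df)) {
    ord <- order(df$protein_id, -df$bit_score, df$subject_id)
    df <- df[ord, , drop = FALSE]
    idx <- stats::ave(seq_len(nrow(df)), df$protein_id,
                      FUN = seq_along)
    df <- df[idx <= max_targets, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a bin QC table
#'
#' TSV columns: `bin_id`, `size_bp`, `gc_percent`, `n_contigs`,
#' `completeness`, `contamination`, `strain_heterogeneity`,
#' `taxonomy_label`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_bin_qc <- function(path) {
  df <- .read_tsv(path)
  need <- c("bin_id", "size_bp", "gc_percent", "n_contigs", "completeness",
            "contamination", "strain_heterogeneity", "taxonomy_label")
  if (!all(need %in% names(df)))
    stop("bin QC table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (col in c("size_bp", "gc_percent", "n_contigs", "completeness",
                "contamination", "strain_heterogeneity"))
    df[[col]] <- as.numeric(df[[col]])
  bad <- !is.finite(as.matrix(df[c("size_bp", "completeness",
                                   "contamination")]))
  if (any(bad)) stop("non-finite numeric field in bin QC table")
  df
}

#' Read a contig-to-bin membership map
#'
#' @param path TSV with columns `contig_id`, `bin_id`.
#' @return data.frame.
#' @export
read_bin_map <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("contig_id", "bin_id") %in% names(df)))
    stop("bin map must have columns contig_id, bin_id")
  df
}

#' Read a per-bin mapped read-count table
#'
#' @param path TSV with columns `bin_id`, `mapped_reads`.
#' @return data.frame.
#' @export
read_read_counts <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("bin_id", "mapped_reads") %in% names(df)))
    stop("read-count table must have columns bin_id, mapped_reads")
  df$mapped_reads <- as.numeric(df$mapped_reads)
  df
}

# shared TSV reader: header row, '#'-prefixed metadata lines skipped
.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a table as TSV with optional metadata lines
#'
#' Output tables carry a header line; metadata lines are `#`-prefixed and
#' ignored by [read_tsv()]-style readers, so write/read round-trips are
#' field-for-field identical.
#'
#' @param df data.frame.
#' @param path output path.
#' @param meta character vector of metadata lines (written `# `-prefixed).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_tsv <- function(path) .read_tsv(path)
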