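# split a ";"-collapsed symbol string into a lowercase token set
.symbol_tokens <- function(gene_symbols) {
  toks <- unlist(strsplit(gene_symbols, ";", fixed = TRUE))
  unique(tolower(toks[nzchar(toks)]))
}

#' Screen one genome bin for VFA fermentation pathway markers
#'
#' Marker logic, evaluated on whole annotation tokens (never substrings —
#' the butyrate transferase symbol `but` collides with an English word):
#' acetate requires both `ackA` (acetate kinase) and `pta`
#' (phosphoacetyltransferase); propionate via succinate requires `mmdA`
#' (methylmalonyl-CoA decarboxylase); via acrylate, `lcdA`; via
#' propanediol, `pduP` or `pduQ`; butyrate via butyrate kinase, `buk`; via
#' butyryl-CoA:acetate CoA-transferase, `but`.
#'
#' @param genes gene table restricted to one bin (uses `gene_id`,
#'   `gene_symbols`).
#' @param bin_id label carried into the result.
#' @return list of class `pathway_call`: `bin_id`, logical flags
#'   `acetate`, `propionate_succinate`, `propionate_acrylate`,
#'   `propionate_propanediol`, `butyrate_buk`, `butyrate_but`, and
#'   `evidence` (marker -> gene_ids).
#' @export
vfa_screen <- function(genes, bin_id = "bin") {
  markers <- c("acka", "pta", "mmda", "lcda", "pdup", "pduq", "buk", "but")
  evidence <- stats::setNames(vector("list", length(markers)), markers)
  for (i in seq_len(nrow(genes))) {
    toks <- .symbol_tokens(genes$gene_symbols[i])
    for (m in intersect(toks, markers))
      evidence[[m]] <- c(evidence[[m]], genes$gene_id[i])
  }
  has <- vapply(evidence, function(x) length(x) > 0, logical(1))
  structure(list(
    bin_id = bin_id,
    acetate = has[["acka"]] && has[["pta"]],
    propionate_succinate = has[["mmda"]],
    propionate_acrylate = has[["lcda"]],
    propionate_propanediol = has[["pdup"]] || has[["pduq"]],
    butyrate_buk = has[["buk"]],
    butyrate_but = has[["but"]],
    evidence = evidence[has]
  ), class = "pathway_call")
}

#' Screen all bins for VFA pathway markers
#'
#' @param genes gene table.
#' @param bin_map data.frame `contig_id`, `bin_id`.
#' @return data.frame with one row per bin and the logical pathway flags;
#'   attribute `calls` holds the per-bin `pathway_call` objects with
#'   evidence.
#' @export
vfa_screen_bins <- function(genes, bin_map) {
  bin_of <- .gene_bins(genes, bin_map)
  bins <- sort(unique(bin_map$bin_id))
  calls <- lapply(bins, function(b)
    vfa_screen(genes[bin_of == b, , drop = FALSE], bin_id = b))
  flags <- c("acetate", "propionate_succinate", "propionate_acrylate",
             "propionate_propanediol", "butyrate_buk", "butyrate_but")
  out <- data.frame(bin_id = bins, stringsAsFactors = FALSE)
  for (f in flags)
    out[[f]] <- vapply(calls, `[[`, logical(1), f)
  attr(out, "calls") <- stats::setNames(calls, bins)
  out
}

#' Per-phylum summary of VFA pathway capabilities
#'
#' Counts, per phylum, the bins carrying each capability, and reports the
#' dominant butyrate route (`buk` vs `but`; tie with both present ->
#' `"mixed"`, neither -> `"none"`).
#'
#' @param calls table from [vfa_screen_bins()].
#' @param taxonomy data.frame `bin_id`, `phylum`.
#' @return data.frame with one row per phylum: `phylum`, `n_bins`, one
#'   count column per capability, `dominant_butyrate_route`.
#' @export
pathway_summary <- function(calls, taxonomy) {
  phy <- taxonomy$phylum[match(calls$bin_id, taxonomy$bin_id)]
  if (anyNA(phy))
    stop("bins without taxonomy label: ",
         paste(calls$bin_id[is.na(phy)], collapse = ", "))
  flags <- c("acetate", "propionate_succinate", "propionate_acrylate",
             "propionate_propanediol", "butyrate_buk", "butyrate_but")
  out <- do.call(rbind, lapply(sort(unique(phy)), function(p) {
    sub <- calls[phy == p, , drop = FALSE]
    counts <- vapply(flags, function(f) sum(sub[[f]]), integer(1))
    n_buk <- counts[["butyrate_buk"]]; n_but <- counts[["butyrate_but"]]
    route <- if (n_buk == 0 && n_but == 0) "none"
             else if (n_buk > n_but) "buk"
             else if (n_but > n_buk) "but"
             else "mixed"
    cbind(data.frame(phylum = p, n_bins = nrow(sub),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)),
          data.frame(dominant_butyrate_route = route,
                     stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}
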