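#' Fisher's exact test for one family between two metagenomes
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `[[count_a, total_a - count_a], [count_b, total_b - count_b]]`, with the
#' p-value computed by summation of hypergeometric probabilities at most
#' that of the observed table (via [stats::fisher.test()]).  The reported
#' odds ratio is the sample odds ratio
#' `(count_a * (total_b - count_b)) / ((total_a - count_a) * count_b)`,
#' with conventions 0/0 -> 1 and x/0 -> Inf.
#'
#' @param count_a,total_a family count and margin in metagenome A.
#' @param count_b,total_b family count and margin in metagenome B.
#' @return list `odds_ratio`, `p_value`.
#' @export
#' @examples
#' fisher_family(5, 100, 5, 100)  # odds_ratio 1, p 1
fisher_family <- function(count_a, total_a, count_b, total_b) {
  if (count_a > total_a || count_b > total_b)
    stop("count exceeds total")
  if (total_a <= 0 || total_b <= 0) stop("totals must be > 0")
  tab <- matrix(c(count_a, total_a - count_a,
                  count_b, total_b - count_b),
                nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  num <- count_a * (total_b - count_b)
  den <- (total_a - count_a) * count_b
  or <- if (den == 0) {
    if (num == 0) 1 else Inf
  } else num / den
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Compare CAZyme family profiles between two metagenomes
#'
#' One two-sided Fisher's exact test per family, Benjamini-Hochberg FDR
#' adjustment over the family set, and significance tiers on the adjusted
#' values: `***` q < 0.001, `**` q < 0.01, `*` q < 0.05, else `ns`.
#' Direction compares `count_a / total_a` with `count_b / total_b`.
#'
#' @param counts data.frame with columns `family_id`, `count_a`, `count_b`
#'   (or a named list family -> c(count_a, count_b)).
#' @param total_a,total_b margins for the two metagenomes (e.g. predicted
#'   ORFs on contigs >= 1 kb, or total CAZyme genes — stated by the caller).
#' @return data.frame with columns `family_id`, `count_a`, `count_b`,
#'   `total_a`, `total_b`, `odds_ratio`, `p_value`, `q_value`, `tier`,
#'   `direction`.
#' @export
compare_profiles <- function(counts, total_a, total_b) {
  if (is.list(counts) && !is.data.frame(counts)) {
    counts <- data.frame(
      family_id = names(counts),
      count_a = vapply(counts, `[`, numeric(1), 1),
      count_b = vapply(counts, `[`, numeric(1), 2),
      stringsAsFactors = FALSE
    )
  }
  if (!nrow(counts)) stop("family set must be non-empty")
  if (total_a <= 0 || total_b <= 0) stop("totals must be > 0")
  res <- lapply(seq_len(nrow(counts)), function(i)
    fisher_family(counts$count_a[i], total_a, counts$count_b[i], total_b))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  q <- stats::p.adjust(p, method = "BH")
  prop_a <- counts$count_a / total_a
  prop_b <- counts$count_b / total_b
  out <- data.frame(
    family_id = counts$family_id,
    count_a = counts$count_a,
    count_b = counts$count_b,
    total_a = total_a,
    total_b = total_b,
    odds_ratio = vapply(res, `[[`, numeric(1), "odds_ratio"),
    p_value = p,
    q_value = q,
    tier = ifelse(q < 0.001, "***",
           ifelse(q < 0.01, "**",
           ifelse(q < 0.05, "*", "ns"))),
    direction = ifelse(prop_a > prop_b, "over_in_a",
                ifelse(prop_a < prop_b, "under_in_a", "equal")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
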