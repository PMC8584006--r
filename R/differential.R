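# Differential phosphosite calling and the descriptive summaries of a
# site-level phosphoproteomics study.

#' Per-site log2 fold change and Student's t-test
#'
#' For each site, the log2 fold change is the difference of mean log2
#' intensities (numerator minus denominator condition) and the p-value comes
#' from a two-sided two-sample t-test on log2 intensities (pooled variance by
#' default, Welch with `var_equal = FALSE`). Sites with zero pooled variance
#' get t = 0 / p = 1 when the means are equal and p = 0 otherwise.
#'
#' @param quant a [quant_table()].
#' @param comparison character vector `c(numerator, denominator)` of
#'   condition labels.
#' @param var_equal pooled-variance Student's t (default) or Welch.
#' @return data.frame with columns `site_id`, `log2fc`, `p`.
#' @export
log2_ratio_and_test <- function(quant, comparison, var_equal = TRUE) {
  stopifnot(inherits(quant, "quant_table"), length(comparison) == 2L)
  if (!all(comparison %in% quant$design)) {
    stop_pf("comparison conditions not in design: %s",
            paste(setdiff(comparison, quant$design), collapse = ", "))
  }
  i1 <- which(quant$design == comparison[1])
  i2 <- which(quant$design == comparison[2])
  if (length(i1) < 2L || length(i2) < 2L) {
    stop_pf("need >= 2 replicates per condition for a t-test (%s: %d, %s: %d)",
            comparison[1], length(i1), comparison[2], length(i2))
  }
  x <- log2(quant$intensities[, i1, drop = FALSE])
  y <- log2(quant$intensities[, i2, drop = FALSE])
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1L, stats::var); v2 <- apply(y, 1L, stats::var)
  d <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(d))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- d / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se == 0
  p[degenerate & d == 0] <- 1
  p[degenerate & d != 0] <- 0
  data.frame(site_id = rownames(quant$intensities), log2fc = unname(d),
             p = unname(p), stringsAsFactors = FALSE)
}

#' Classify sites as up / down / not significant
#'
#' The conventional dual gate: `up` iff ratio >= `fc_threshold` and
#' p < `alpha`; `down` iff ratio <= 1/`fc_threshold` and p < `alpha`;
#' otherwise `ns`. The ratio gate is applied as `|log2fc| >= log2(fc)`, so a
#' ratio exactly on the threshold counts as differential.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param p numeric vector of p-values.
#' @param fc_threshold fold-change threshold on the raw ratio scale (> 1).
#' @param alpha p-value threshold.
#' @return character vector in `{"up", "down", "ns"}`.
#' @export
classify <- function(log2fc, p, fc_threshold = 1.5, alpha = 0.05) {
  stopifnot(fc_threshold > 1, alpha > 0, alpha < 1)
  lfc <- log2(fc_threshold)
  ifelse(log2fc >= lfc & p < alpha, "up",
         ifelse(log2fc <= -lfc & p < alpha, "down", "ns"))
}

#' Differential phosphosite analysis for one comparison
#'
#' Runs [log2_ratio_and_test()], attaches raw ratios, BH-adjusted q-values
#' (reported, never used for selection) and [classify()] status.
#'
#' @inheritParams log2_ratio_and_test
#' @inheritParams classify
#' @return data.frame of class `phos_diff` with columns `site_id`, `log2fc`,
#'   `ratio`, `p`, `q`, `status`; attributes `comparison`, `fc_threshold`,
#'   `alpha`.
#' @export
phospho_diff <- function(quant, comparison, fc_threshold = 1.5, alpha = 0.05,
                         var_equal = TRUE) {
  res <- log2_ratio_and_test(quant, comparison, var_equal = var_equal)
  res$ratio <- 2^res$log2fc
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$status <- classify(res$log2fc, res$p, fc_threshold, alpha)
  res <- res[, c("site_id", "log2fc", "ratio", "p", "q", "status")]
  pf_log("differential", "%s vs %s: %d sites, %d up, %d down (ratio %.3g, alpha %.3g)",
         comparison[1], comparison[2], nrow(res), sum(res$status == "up"),
         sum(res$status == "down"), fc_threshold, alpha)
  structure(res, comparison = comparison, fc_threshold = fc_threshold,
            alpha = alpha, class = c("phos_diff", "data.frame"))
}

#' @export
print.phos_diff <- function(x, ...) {
  cmp <- attr(x, "comparison")
  cat(sprintf("Differential phosphosites: %s vs %s\n", cmp[1], cmp[2]))
  cat(sprintf("  %d sites: %d up, %d down, %d ns (ratio >= %.3g, p < %.3g)\n",
              nrow(x), sum(x$status == "up"), sum(x$status == "down"),
              sum(x$status == "ns"), attr(x, "fc_threshold"), attr(x, "alpha")))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' S/T/Y residue distribution of a site list
#'
#' @param sites site data.frame with a `residue` column (or a character
#'   vector of residues).
#' @return data.frame with `residue`, `count` and integer-rounded `percent`
#'   for S, T and Y.
#' @export
residue_distribution <- function(sites) {
  res <- if (is.data.frame(sites)) sites$residue else sites
  if (length(res) == 0L) stop_pf("empty site list")
  counts <- vapply(STY, function(r) sum(res == r), integer(1))
  data.frame(residue = STY, count = unname(counts),
             percent = unname(round_half_up(100 * counts / sum(counts))),
             stringsAsFactors = FALSE)
}

#' Sites-per-protein histogram
#'
#' Bins proteins by their number of phosphosites into `{1, 2, >=3}` (a
#' partition) and additionally reports the `>=7` tail; percentages to one
#' decimal.
#'
#' @param sites site data.frame with a `protein_id` column.
#' @return data.frame with `bin`, `count`, `percent` rows `1`, `2`, `>=3`,
#'   `>=7`.
#' @export
sites_per_protein_histogram <- function(sites) {
  if (nrow(sites) == 0L) stop_pf("empty site list")
  per <- table(sites$protein_id)
  n <- length(per)
  counts <- c(`1` = sum(per == 1L), `2` = sum(per == 2L),
              `>=3` = sum(per >= 3L), `>=7` = sum(per >= 7L))
  data.frame(bin = names(counts), count = as.integer(counts),
             percent = unname(round_half_up(100 * as.integer(counts) / n, 1)),
             stringsAsFactors = FALSE)
}

#' Venn cell counts of significant items across comparisons
#'
#' Counts items (sites or proteins) with `status != "ns"` in each comparison
#' and tabulates every Venn region: cells are named by the `/`-joined labels
#' of the comparisons an item is significant in, e.g. `"A"` (exclusive to A)
#' or `"A&B&C"`.
#'
#' @param results named list of 2 or 3 [phospho_diff()] results (or of
#'   character vectors of significant ids).
#' @return named integer vector of exclusive Venn cell counts, plus
#'   attribute `sets` with the per-comparison significant-set sizes.
#' @export
overlap_counts <- function(results) {
  if (length(results) < 2L || length(results) > 3L) {
    stop_pf("overlap_counts needs 2 or 3 comparisons")
  }
  if (is.null(names(results))) names(results) <- paste0("G", seq_along(results))
  sets <- lapply(results, function(r) {
    if (is.data.frame(r)) r$site_id[r$status != "ns"] else as.character(r)
  })
  items <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) items %in% s, logical(length(items)))
  if (length(items) == 1L) memb <- matrix(memb, nrow = 1,
                                          dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1L, function(row) paste(names(sets)[row], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(names(sets), k, paste, collapse = "&")
  }))
  out <- stats::setNames(integer(length(combos)), combos)
  tab <- table(key)
  out[names(tab)] <- as.integer(tab)
  attr(out, "sets") <- vapply(sets, length, integer(1))
  out
}

#' Size of the union of two identification sets
#'
#' @param n_a,n_b set sizes.
#' @param n_shared size of the intersection.
#' @return `n_a + n_b - n_shared`.
#' @examples
#' union_size(6965, 2327, 1436)  # 7856
#' @export
union_size <- function(n_a, n_b, n_shared) {
  if (n_shared > min(n_a, n_b) || any(c(n_a, n_b, n_shared) < 0)) {
    stop_pf("n_shared must be <= min(n_a, n_b) and sizes non-negative")
  }
  n_a + n_b - n_shared
}
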