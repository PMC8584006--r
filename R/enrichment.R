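# Annotation-term enrichment of differential protein lists by two-tailed
# Fisher's exact test.

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]`: the summed
#' probability of all tables with the same margins whose hypergeometric
#' probability does not exceed the observed one (with the conventional tiny
#' slack factor for floating-point ties).
#'
#' @param a,b,c,d non-negative integer cell counts; `a` = hits in the term,
#'   `b` = hits outside it, `c` = non-hits in the term, `d` = the rest.
#' @return the two-tailed p-value.
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_pf("cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop_pf("all-zero table")
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

#' Term enrichment of a protein hit list
#'
#' For every annotation term, counts the 2x2 overlap of `hits` vs the term's
#' members within `universe`, computes the fold enrichment and a two-tailed
#' Fisher p-value, and reports BH-adjusted q-values alongside (selection is
#' on raw p). Terms are returned sorted by increasing p.
#'
#' @param hits character vector of differential protein ids (subset of
#'   `universe`).
#' @param universe character vector of all quantified protein ids.
#' @param annotations an `annotation_table` (long data.frame with `term_id`,
#'   `term_name`, `namespace`, `protein_id`).
#' @param alpha significance threshold on the raw p-value.
#' @return data.frame of class `phos_enrichment`: `term_id`, `term_name`,
#'   `namespace`, `n_hits`, `n_term`, `fold_enrichment`, `p`, `q`,
#'   `significant`.
#' @export
enrich <- function(hits, universe, annotations, alpha = 0.05) {
  hits <- unique(hits); universe <- unique(universe)
  if (length(universe) == 0L) stop_pf("empty universe")
  if (length(hits) == 0L) stop_pf("empty hit list")
  if (!all(hits %in% universe)) stop_pf("hits must be a subset of the universe")
  ann <- annotations[annotations$protein_id %in% universe, , drop = FALSE]
  terms <- split(ann, ann$term_id)
  n_u <- length(universe); n_h <- length(hits)
  rows <- lapply(terms, function(d) {
    members <- unique(d$protein_id)
    a <- sum(members %in% hits)
    b <- n_h - a
    cc <- length(members) - a
    dd <- n_u - n_h - cc
    data.frame(term_id = d$term_id[1], term_name = d$term_name[1],
               namespace = d$namespace[1], n_hits = a,
               n_term = length(members),
               fold_enrichment = (a / n_h) / (length(members) / n_u),
               p = fisher_two_tailed(a, b, cc, dd), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  pf_log("enrichment", "%d terms tested (%d hits / %d universe), %d significant at p < %.3g",
         nrow(out), n_h, n_u, sum(out$significant), alpha)
  structure(out, alpha = alpha, class = c("phos_enrichment", "data.frame"))
}

#' @export
print.phos_enrichment <- function(x, top = 20L, ...) {
  cat(sprintf("Term enrichment: %d terms, %d significant (p < %.3g)\n",
              nrow(x), sum(x$significant), attr(x, "alpha")))
  print.data.frame(utils::head(as.data.frame(x), top), digits = 4,
                   row.names = FALSE)
  invisible(x)
}
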