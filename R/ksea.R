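# Kinase-activity inference by gene-set enrichment of substrate sites in a
# ranked phosphosite list (KSEA). The enrichment score is the classic
# weighted Kolmogorov-Smirnov running-sum statistic; activity is its
# normalised form (NES) with gene-set permutation significance.

#' Ranked phosphosite list for enrichment
#'
#' Builds the ranked list substrates are scored against: in comparison mode
#' (a [phospho_diff()] result) sites are ranked by log2 fold change; in
#' per-sample mode (a [quant_table()] plus `sample`) by the z-score of the
#' site's log2 intensity across sites within that sample. Descending order,
#' ties broken by `site_id` (lexicographic).
#'
#' @param x a `phos_diff` or `quant_table`.
#' @param sample sample id, required for `quant_table` input.
#' @return named numeric vector, sorted descending.
#' @export
rank_metric <- function(x, sample = NULL) {
  if (inherits(x, "phos_diff")) {
    v <- stats::setNames(x$log2fc, x$site_id)
  } else if (inherits(x, "quant_table")) {
    if (is.null(sample) || !sample %in% x$samples) {
      stop_pf("per-sample ranking needs a valid sample id")
    }
    l <- log2(x$intensities[, sample])
    v <- stats::setNames((l - mean(l)) / stats::sd(l), x$sites)
  } else {
    stop_pf("rank_metric expects a phos_diff or quant_table")
  }
  v[order(-v, names(v), method = "radix")]
}

# ES of the index set `idx` in a ranked list with |value|^w weights `aw`;
# returns the signed extremum of the running sum (first extremum on ties)
.es_indices <- function(aw, idx, N, full = FALSE) {
  m <- length(idx)
  step <- if (m < N) rep(-1 / (N - m), N) else rep(0, N)
  sumw <- sum(aw[idx])
  step[idx] <- if (sumw > 0) aw[idx] / sumw else 1 / m
  rs <- cumsum(step)
  es <- rs[which.max(abs(rs))]
  if (full) list(es = es, running_sum = rs) else es
}

#' GSEA enrichment score of a substrate set
#'
#' Walks the ranked list: a substrate ("hit") increments the running sum by
#' its weight `|value|^weight_exponent` normalised by the summed hit
#' weights; every other site decrements by `1/(N - n_hits)`. The enrichment
#' score is the signed extremum of the running sum.
#'
#' @param ranked named numeric vector from [rank_metric()].
#' @param substrate_set character vector of site ids.
#' @param weight_exponent 1 for the weighted statistic (default), 0 for the
#'   unweighted Kolmogorov-Smirnov form.
#' @return list with `es` and `running_sum`.
#' @export
enrichment_score <- function(ranked, substrate_set, weight_exponent = 1) {
  idx <- which(names(ranked) %in% substrate_set)
  if (length(idx) == 0L) stop_pf("substrate set does not intersect the ranked list")
  aw <- abs(ranked)^weight_exponent
  .es_indices(aw, idx, length(ranked), full = TRUE)
}

#' Normalise an enrichment score and test it by permutation
#'
#' Builds a gene-set permutation null by re-drawing `n_permutations` random
#' site sets of the same size from the ranked list. The NES divides the
#' observed score by the mean magnitude of same-sign null scores; the
#' permutation p-value is the fraction of same-sign null magnitudes at least
#' as large as the observed one, with the +1/(n+1) correction. Fully seeded.
#'
#' @inheritParams enrichment_score
#' @param es observed enrichment score.
#' @param n_permutations number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @return list with `nes`, `p_perm`, `n_same_sign`; `nes` is `NA` (flagged,
#'   not dropped) if no permutation shares the sign of `es`.
#' @export
normalize_and_test <- function(es, ranked, substrate_set, n_permutations = 1000L,
                               seed = 1L, weight_exponent = 1) {
  if (n_permutations < 100L) stop_pf("need >= 100 permutations")
  m <- sum(names(ranked) %in% substrate_set)
  set.seed(seed)
  null <- ksea_null(ranked, m, n_permutations, weight_exponent)
  .nes_from_null(es, null)
}

ksea_null <- function(ranked, set_size, n_permutations, weight_exponent = 1) {
  aw <- abs(ranked)^weight_exponent
  N <- length(ranked)
  vapply(seq_len(n_permutations), function(i) {
    .es_indices(aw, sample.int(N, set_size), N)
  }, numeric(1))
}

.nes_from_null <- function(es, null) {
  if (es == 0) return(list(nes = 0, p_perm = 1, n_same_sign = 0L))
  ss <- null[sign(null) == sign(es)]
  if (length(ss) == 0L) {
    return(list(nes = NA_real_, p_perm = NA_real_, n_same_sign = 0L))
  }
  list(nes = es / mean(abs(ss)),
       p_perm = (1 + sum(abs(ss) >= abs(es))) / (1 + length(ss)),
       n_same_sign = length(ss))
}

#' Classify kinase state from its activity score
#'
#' A kinase whose substrate phosphorylation predominantly rises scores
#' NES >= +1 and is called activated; NES <= -1 is called inhibited; scores
#' strictly between are indeterminate (symmetric reading of the activity
#' rule). `NA` scores stay indeterminate.
#'
#' @param nes numeric vector of normalised enrichment scores.
#' @return character vector in `{"activated", "inhibited", "indeterminate"}`.
#' @export
classify_state <- function(nes) {
  out <- rep("indeterminate", length(nes))
  out[!is.na(nes) & nes >= 1] <- "activated"
  out[!is.na(nes) & nes <= -1] <- "inhibited"
  out
}

#' Fit kinase activities by substrate-set enrichment (KSEA)
#'
#' The central model of the package: for every kinase, the enrichment score
#' of its substrate sites in the ranked phosphosite list of a context (a
#' condition comparison, or a single sample), normalised against a seeded
#' gene-set permutation null and classified as activated / inhibited /
#' indeterminate. Kinases whose substrate set intersects the ranked list in
#' fewer than `min_set_size` sites are reported as skipped, keeping output
#' row counts auditable. Null score distributions depend only on set size
#' and are therefore drawn once per distinct size.
#'
#' @param x a [phospho_diff()] result (comparison mode) or [quant_table()]
#'   (per-sample mode, with `sample`).
#' @param substrate_sets named list of site-id vectors per kinase, or a
#'   relations data.frame with `kinase_id` and `site_id` columns (e.g. from
#'   [predict_relations()] or the simulator's ground-truth edges).
#' @param sample sample id for per-sample mode.
#' @param n_permutations permutations per null (default 1000).
#' @param weight_exponent GSEA weight (default 1).
#' @param min_set_size minimal substrate-set overlap with the ranked list
#'   (default 3).
#' @param seed integer seed; results are bit-for-bit reproducible.
#' @return an object of class `ksea` with components `table` (kinase, es,
#'   nes, p_perm, n_substrates, state), `skipped`, `context`, `ranked` and
#'   the call parameters. Methods: `print`, `summary`, `coef`, `plot`.
#' @examples
#' study <- simulate_phospho_study(sim_config(seed = 7, n_proteins = 150))
#' d <- phospho_diff(study$quant, c("AC-B4", "AC-MG"))
#' fit <- ksea(d, study$truth$edges, n_permutations = 200, seed = 1)
#' fit
#' @export
ksea <- function(x, substrate_sets, sample = NULL, n_permutations = 1000L,
                 weight_exponent = 1, min_set_size = 3L, seed = 1L) {
  ranked <- rank_metric(x, sample = sample)
  context <- if (inherits(x, "phos_diff")) {
    paste(attr(x, "comparison"), collapse = "/")
  } else {
    sample
  }
  if (is.data.frame(substrate_sets)) {
    kcol <- substrate_sets$kinase_id %||% substrate_sets$kinase
    substrate_sets <- split(substrate_sets$site_id, kcol)
  }
  sizes <- vapply(substrate_sets, function(s) sum(names(ranked) %in% s),
                  integer(1))
  keep <- sizes >= min_set_size
  skipped <- data.frame(kinase = names(substrate_sets)[!keep],
                        n_in_rank = sizes[!keep],
                        reason = rep(sprintf("substrate overlap < %d", min_set_size),
                                     sum(!keep)),
                        stringsAsFactors = FALSE)
  for (k in skipped$kinase) pf_log("kinase_activity", "skipping %s: %s", k,
                                   skipped$reason[skipped$kinase == k])

  aw <- abs(ranked)^weight_exponent
  N <- length(ranked)
  set.seed(seed)
  nulls <- lapply(stats::setNames(nm = sort(unique(sizes[keep]))), function(m) {
    ksea_null(ranked, as.integer(m), n_permutations, weight_exponent)
  })
  rows <- lapply(names(substrate_sets)[keep], function(k) {
    idx <- which(names(ranked) %in% substrate_sets[[k]])
    es <- .es_indices(aw, idx, N)
    nt <- .nes_from_null(es, nulls[[as.character(length(idx))]])
    data.frame(kinase = k, es = es, nes = nt$nes, p_perm = nt$p_perm,
               n_substrates = length(idx), state = classify_state(nt$nes),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kinase = character(0), es = numeric(0), nes = numeric(0),
               p_perm = numeric(0), n_substrates = integer(0),
               state = character(0))
  pf_log("kinase_activity", "%s: %d kinases scored (%d skipped), %d activated, %d inhibited",
         context, nrow(tab), nrow(skipped), sum(tab$state == "activated"),
         sum(tab$state == "inhibited"))
  structure(list(table = tab, skipped = skipped, context = context,
                 ranked = ranked, n_permutations = n_permutations,
                 weight_exponent = weight_exponent,
                 min_set_size = min_set_size, seed = seed),
            class = "ksea")
}

#' @export
print.ksea <- function(x, ...) {
  cat(sprintf("KSEA kinase activities - context %s\n", x$context))
  cat(sprintf("  %d kinases (%d skipped), %d permutations, weight %g\n",
              nrow(x$table), nrow(x$skipped), x$n_permutations,
              x$weight_exponent))
  tab <- x$table[order(-abs(ifelse(is.na(x$table$nes), 0, x$table$nes))), ]
  print(utils::head(tab, 8), row.names = FALSE, digits = 4)
  if (nrow(tab) > 8) cat(sprintf("  ... %d more kinases\n", nrow(tab) - 8))
  invisible(x)
}

#' Top activated and inhibited kinases of a KSEA fit
#'
#' @param object a [ksea()] fit.
#' @param top_k kinases per direction (default 10, the usual figure layout).
#' @param ... unused.
#' @return list of class `summary.ksea` with `activated` and `inhibited`
#'   tables sorted by NES.
#' @method summary ksea
#' @export
summary.ksea <- function(object, top_k = 10L, ...) {
  tab <- object$table[!is.na(object$table$nes), ]
  act <- tab[tab$state == "activated", ]
  inh <- tab[tab$state == "inhibited", ]
  structure(list(
    context = object$context,
    activated = utils::head(act[order(-act$nes), ], top_k),
    inhibited = utils::head(inh[order(inh$nes), ], top_k)),
    class = "summary.ksea")
}

#' @export
print.summary.ksea <- function(x, ...) {
  cat(sprintf("Top kinase activities - context %s\n", x$context))
  cat("activated:\n"); print(x$activated, row.names = FALSE, digits = 4)
  cat("inhibited:\n"); print(x$inhibited, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @method coef ksea
#' @export
coef.ksea <- function(object, ...) {
  stats::setNames(object$table$nes, object$table$kinase)
}

#' Bar plot of kinase activity scores
#'
#' Horizontal bars of the top activated (red) and inhibited (blue) kinases,
#' mirroring the usual per-context kinase-activity panel.
#'
#' @param x a [ksea()] fit.
#' @param top_k kinases per direction.
#' @param ... passed to [graphics::barplot()].
#' @method plot ksea
#' @export
plot.ksea <- function(x, top_k = 10L, ...) {
  s <- summary(x, top_k = top_k)
  tab <- rbind(s$inhibited[order(s$inhibited$nes), ],
               s$activated[order(s$activated$nes), ])
  if (nrow(tab) == 0L) {
    graphics::plot.new()
    graphics::title(main = sprintf("KSEA %s: no classified kinases", x$context))
    return(invisible(x))
  }
  graphics::barplot(tab$nes, names.arg = tab$kinase, horiz = TRUE, las = 1,
                    col = ifelse(tab$nes >= 0, "firebrick", "steelblue"),
                    xlab = "kinase activity score (NES)",
                    main = sprintf("KSEA - %s", x$context), ...)
  graphics::abline(v = c(-1, 1), lty = 2, col = "grey40")
  invisible(x)
}
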