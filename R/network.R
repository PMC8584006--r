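# Bipartite kinase-substrate regulatory network: significantly active or
# inhibited kinases wired to significantly differential phosphosites.

#' Assemble the kinase-substrate regulatory network
#'
#' Keeps kinases with a determinate state (|NES| >= 1) and permutation
#' p < `p_threshold`, sites with differential status `up`/`down`, and the
#' predicted relations whose endpoints both survive; isolated nodes are
#' dropped. An empty network is a valid result.
#'
#' @param activities a [ksea()] fit.
#' @param comparison_result a [phospho_diff()] result from the same context.
#' @param relations relations data.frame (`kinase_id`, `site_id`, optional
#'   `score`), e.g. from [predict_relations()].
#' @param p_threshold permutation p-value gate for kinase inclusion.
#' @param require_significance set `FALSE` to include kinases on state
#'   alone, without the p-value gate.
#' @return object of class `ks_network` with `kinases`, `sites` and `edges`
#'   data.frames.
#' @export
build_network <- function(activities, comparison_result, relations,
                          p_threshold = 0.05, require_significance = TRUE) {
  stopifnot(inherits(activities, "ksea"))
  ktab <- activities$table
  keep_k <- ktab$state != "indeterminate" & !is.na(ktab$nes)
  if (require_significance) {
    keep_k <- keep_k & !is.na(ktab$p_perm) & ktab$p_perm < p_threshold
  }
  kin <- ktab[keep_k, c("kinase", "nes", "p_perm", "state")]
  sit <- comparison_result[comparison_result$status != "ns",
                           c("site_id", "log2fc", "status")]
  if (is.null(relations$score)) relations$score <- NA_real_
  ed <- relations[relations$kinase_id %in% kin$kinase &
                    relations$site_id %in% sit$site_id,
                  c("kinase_id", "site_id", "score")]
  ed <- ed[order(ed$kinase_id, ed$site_id), , drop = FALSE]
  rownames(ed) <- NULL
  kin <- kin[kin$kinase %in% ed$kinase_id, , drop = FALSE]
  sit <- sit[sit$site_id %in% ed$site_id, , drop = FALSE]
  rownames(kin) <- rownames(sit) <- NULL
  pf_log("network", "%d kinase nodes, %d site nodes, %d edges",
         nrow(kin), nrow(sit), nrow(ed))
  structure(list(kinases = kin, sites = sit, edges = ed,
                 context = activities$context, p_threshold = p_threshold),
            class = "ks_network")
}

#' @export
print.ks_network <- function(x, ...) {
  cat(sprintf("Kinase-substrate network (%s): %d kinases -> %d sites, %d edges\n",
              x$context, nrow(x$kinases), nrow(x$sites), nrow(x$edges)))
  invisible(x)
}

#' Degree summary of a kinase-substrate network
#'
#' @param network a [build_network()] result.
#' @param top_k rows per table.
#' @return list with `kinases` (by out-degree) and `sites` (by in-degree),
#'   stably ranked with ties broken by id.
#' @export
degree_summary <- function(network, top_k = 10L) {
  if (nrow(network$edges) == 0L) {
    empty_k <- data.frame(kinase = character(0), degree = integer(0))
    empty_s <- data.frame(site = character(0), degree = integer(0))
    return(list(kinases = empty_k, sites = empty_s))
  }
  kd <- as.data.frame(table(kinase = network$edges$kinase_id),
                      stringsAsFactors = FALSE)
  sd_ <- as.data.frame(table(site = network$edges$site_id),
                       stringsAsFactors = FALSE)
  names(kd)[2] <- names(sd_)[2] <- "degree"
  kd <- kd[order(-kd$degree, kd$kinase), , drop = FALSE]
  sd_ <- sd_[order(-sd_$degree, sd_$site), , drop = FALSE]
  rownames(kd) <- rownames(sd_) <- NULL
  list(kinases = utils::head(kd, top_k), sites = utils::head(sd_, top_k))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a kinase-substrate network
#'
#' SIF rows are `kinase TAB regulates TAB site_id`, sorted by (kinase, site)
#' for stable output. GraphML carries node `type` (kinase/site), `state`
#' (activated/inhibited for kinases, up/down for sites), `nes`/`log2fc` and
#' the edge `score`, and loads directly into Cytoscape.
#'
#' @param network a [build_network()] result.
#' @param path output file.
#' @param format `"SIF"` or `"GraphML"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("SIF", "GraphML")) {
  format <- match.arg(format)
  ed <- network$edges[order(network$edges$kinase_id, network$edges$site_id), ,
                      drop = FALSE]
  if (format == "SIF") {
    lines <- if (nrow(ed)) {
      paste(ed$kinase_id, "regulates", ed$site_id, sep = "\t")
    } else {
      character(0)
    }
    writeLines(lines, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="type" for="node" attr.name="type" attr.type="string"/>')
  w('  <key id="state" for="node" attr.name="state" attr.type="string"/>')
  w('  <key id="value" for="node" attr.name="value" attr.type="double"/>')
  w('  <key id="score" for="edge" attr.name="score" attr.type="double"/>')
  w('  <graph id="ksn" edgedefault="directed">')
  for (i in seq_len(nrow(network$kinases))) {
    k <- network$kinases[i, ]
    w('    <node id="%s"><data key="type">kinase</data><data key="state">%s</data><data key="value">%.6g</data></node>',
      xml_escape(k$kinase), k$state, k$nes)
  }
  for (i in seq_len(nrow(network$sites))) {
    s <- network$sites[i, ]
    w('    <node id="%s"><data key="type">site</data><data key="state">%s</data><data key="value">%.6g</data></node>',
      xml_escape(s$site_id), s$status, s$log2fc)
  }
  for (i in seq_len(nrow(ed))) {
    w('    <edge source="%s" target="%s"><data key="score">%.6g</data></edge>',
      xml_escape(ed$kinase_id[i]), xml_escape(ed$site_id[i]), ed$score[i])
  }
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}
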