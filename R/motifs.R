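# Iterative phospho-motif discovery over 13-mer windows (motif-x style):
# repeatedly fix the (offset, residue) pair with the smallest binomial tail
# p-value against background frequencies, restrict both window sets to the
# matching subset, and accept motifs passing the support threshold.

MOTIF_OFFSETS <- c(-6:-1, 1:6)

#' Upper binomial tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, the step statistic of iterative
#' motif enrichment, computed with the stable survival function.
#'
#' @param k observed successes (0 <= k <= n).
#' @param n trials.
#' @param p0 success probability (0 < p0 < 1).
#' @return the tail probability.
#' @export
binomial_tail <- function(k, n, p0) {
  if (any(k < 0 | k > n) || any(p0 <= 0 | p0 >= 1)) {
    stop_pf("binomial_tail requires 0 <= k <= n and 0 < p0 < 1")
  }
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

motif_pattern <- function(central, fixed) {
  chars <- rep("x", 13L)
  chars[7L] <- central
  if (length(fixed)) {
    chars[as.integer(names(fixed)) + 7L] <- unname(fixed)
  }
  first <- min(7L, if (length(fixed)) min(as.integer(names(fixed)) + 7L) else 7L)
  last <- max(7L, if (length(fixed)) max(as.integer(names(fixed)) + 7L) else 7L)
  paste(chars[first:last], collapse = "")
}

check_windows <- function(windows, central_residue, what) {
  if (length(windows) == 0L) stop_pf("empty %s window set", what)
  if (any(nchar(windows) != 13L)) stop_pf("%s windows must be 13-mers", what)
  centers <- substring(windows, 7L, 7L)
  if (any(centers != central_residue)) {
    stop_pf("%s windows must be centred on %s", what, central_residue)
  }
  invisible(windows)
}

# per-offset residue counts (rows AA20, cols the 12 offsets) and valid
# (non-pad) totals, from a window character matrix
offset_counts <- function(wm) {
  cols <- MOTIF_OFFSETS + 7L
  counts <- vapply(cols, function(j) {
    tabulate(factor(wm[, j], levels = AA20), nbins = 20L)
  }, integer(20L))
  dimnames(counts) <- list(AA20, as.character(MOTIF_OFFSETS))
  list(counts = counts, valid = colSums(counts))
}

# pick the most significant (offset, residue) pair; deterministic tie-break:
# smallest p, then largest foreground count, then smallest |offset|, then
# lexicographic residue
best_pair <- function(fg, bg, exclude, p_threshold) {
  fg_oc <- offset_counts(fg)
  bg_oc <- offset_counts(bg)
  best <- NULL
  for (j in seq_along(MOTIF_OFFSETS)) {
    off <- MOTIF_OFFSETS[j]
    if (off %in% exclude) next
    n <- fg_oc$valid[[j]]
    n_bg <- bg_oc$valid[[j]]
    if (n == 0L || n_bg == 0L) next
    for (a in AA20) {
      k <- fg_oc$counts[a, j]
      p0 <- bg_oc$counts[a, j] / n_bg
      if (p0 <= 0 || p0 >= 1) next     # p undefined at the extremes
      p <- binomial_tail(k, n, p0)
      if (p >= p_threshold) next
      cand <- list(offset = off, residue = a, p = p, k = k, n = n, p0 = p0)
      if (is.null(best) ||
          p < best$p ||
          (p == best$p && k > best$k) ||
          (p == best$p && k == best$k && abs(off) < abs(best$offset)) ||
          (p == best$p && k == best$k && abs(off) == abs(best$offset) &&
             a < best$residue)) {
        best <- cand
      }
    }
  }
  best
}

matches_pair <- function(wm, offset, residue) {
  wm[, offset + 7L] == residue
}

#' Iterative motif discovery (motif-x style)
#'
#' Starting from all foreground windows of one central residue, repeatedly:
#' (1) compute the binomial tail p of every unfixed (offset, residue) pair,
#' with the foreground count as successes and the background residue
#' frequency at that offset (among currently matching background windows,
#' pads excluded) as the null rate; (2) fix the most significant pair if its
#' p-value beats `p_threshold`; (3) restrict foreground and background to the
#' matching windows and repeat. A motif is accepted when no further pair
#' passes, at least one position is fixed, and the final foreground support
#' is at least `min_occurrences`; its matched windows are then removed from
#' the foreground and the search restarts for the next motif.
#'
#' @param foreground 13-mer windows of identified sites (central residue
#'   `central_residue`).
#' @param background 13-mer null-population windows of the same central
#'   residue (typically every such window in the proteome).
#' @param central_residue `"S"`, `"T"` or `"Y"`.
#' @param p_threshold per-step binomial p-value threshold (default `1e-6`).
#' @param min_occurrences minimal foreground support of an accepted motif;
#'   the default 21 reads the conventional "more than 20 peptides" strictly.
#' @return object of class `phos_motifs`: a list of motifs, each with
#'   `pattern`, `central_residue`, `fixed` (per-step data.frame of offset,
#'   residue, k, n, p0, p), `n_foreground_matches`, `n_background_matches`
#'   and `score` (sum of -log10 step p-values).
#' @export
motif_x <- function(foreground, background, central_residue,
                    p_threshold = 1e-6, min_occurrences = 21L) {
  check_windows(foreground, central_residue, "foreground")
  check_windows(background, central_residue, "background")
  fg_all <- window_matrix(foreground)
  bg_all <- window_matrix(background)

  motifs <- list()
  active <- rep(TRUE, nrow(fg_all))
  repeat {
    fg <- fg_all[active, , drop = FALSE]
    if (nrow(fg) == 0L) break
    bg <- bg_all
    fixed <- list()
    repeat {
      pair <- best_pair(fg, bg, exclude = vapply(fixed, `[[`, integer(1), "offset"),
                        p_threshold = p_threshold)
      if (is.null(pair)) break
      fixed[[length(fixed) + 1L]] <- pair
      keep_fg <- matches_pair(fg, pair$offset, pair$residue)
      keep_bg <- matches_pair(bg, pair$offset, pair$residue)
      fg <- fg[keep_fg, , drop = FALSE]
      bg <- bg[keep_bg, , drop = FALSE]
    }
    if (length(fixed) == 0L || nrow(fg) < min_occurrences) break

    fixed_df <- do.call(rbind, lapply(fixed, as.data.frame))
    fv <- stats::setNames(fixed_df$residue, fixed_df$offset)
    motifs[[length(motifs) + 1L]] <- list(
      pattern = motif_pattern(central_residue, fv),
      central_residue = central_residue,
      fixed = fixed_df,
      n_foreground_matches = nrow(fg),
      n_background_matches = nrow(bg),
      score = sum(-log10(fixed_df$p))
    )
    # drop this motif's matched windows from the foreground and restart
    idx <- which(active)
    m <- rep(TRUE, length(idx))
    for (pr in fixed) {
      m <- m & matches_pair(fg_all[idx, , drop = FALSE], pr$offset, pr$residue)
    }
    active[idx[m]] <- FALSE
  }
  pf_log("motifs", "central %s: %d motif(s) from %d foreground / %d background windows",
         central_residue, length(motifs), length(foreground), length(background))
  structure(motifs, class = "phos_motifs",
            central_residue = central_residue, p_threshold = p_threshold,
            min_occurrences = min_occurrences)
}

#' @export
print.phos_motifs <- function(x, ...) {
  cat(sprintf("Enriched phosphorylation motifs (central %s): %d found\n",
              attr(x, "central_residue"), length(x)))
  if (length(x)) print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @method as.data.frame phos_motifs
#' @export
as.data.frame.phos_motifs <- function(x, ...) {
  if (length(x) == 0L) {
    return(data.frame(pattern = character(0), central = character(0),
                      n_foreground = integer(0), n_background = integer(0),
                      score = numeric(0)))
  }
  data.frame(
    pattern = vapply(x, `[[`, character(1), "pattern"),
    central = vapply(x, `[[`, character(1), "central_residue"),
    n_foreground = vapply(x, `[[`, numeric(1), "n_foreground_matches"),
    n_background = vapply(x, `[[`, numeric(1), "n_background_matches"),
    score = vapply(x, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
}

#' Does a window match a motif?
#'
#' @param windows character vector of 13-mers.
#' @param motif one element of a [motif_x()] result (or any list with a
#'   `fixed` data.frame of offsets and residues and a `central_residue`).
#' @return logical vector.
#' @export
motif_matches <- function(windows, motif) {
  wm <- window_matrix(windows)
  ok <- wm[, 7L] == motif$central_residue
  for (i in seq_len(nrow(motif$fixed))) {
    ok <- ok & wm[, motif$fixed$offset[i] + 7L] == motif$fixed$residue[i]
  }
  ok
}

#' Position-residue enrichment heatmap
#'
#' Log2 ratio of foreground to background residue frequencies at every
#' flanking offset (pads excluded from denominators), with a pseudo-count
#' `epsilon` on both frequencies. Positive cells mark residues enriched near
#' the modification site, negative cells depleted ones.
#'
#' @inheritParams motif_x
#' @param epsilon pseudo-count added to both frequencies (default `1e-4`).
#' @return 20 x 12 numeric matrix (residues x offsets -6..-1, +1..+6) of
#'   log2 enrichments.
#' @export
position_residue_heatmap <- function(foreground, background, central_residue,
                                     epsilon = 1e-4) {
  check_windows(foreground, central_residue, "foreground")
  check_windows(background, central_residue, "background")
  fg <- offset_counts(window_matrix(foreground))
  bg <- offset_counts(window_matrix(background))
  fg_freq <- sweep(fg$counts, 2L, pmax(fg$valid, 1L), "/")
  bg_freq <- sweep(bg$counts, 2L, pmax(bg$valid, 1L), "/")
  log2((fg_freq + epsilon) / (bg_freq + epsilon))
}

#' Extract all windows of a central residue from a proteome
#'
#' The default motif background: every 13-mer window of the proteome centred
#' on `residue`.
#'
#' @param proteome named character vector of sequences.
#' @param residue central residue.
#' @return character vector of 13-mer windows.
#' @export
proteome_windows <- function(proteome, residue) {
  unlist(lapply(proteome, function(s) {
    pos <- which(strsplit(s, "", fixed = TRUE)[[1]] == residue)
    if (length(pos) == 0L) return(character(0))
    extract_window(s, pos)
  }), use.names = FALSE)
}
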