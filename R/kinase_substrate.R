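# Kinase-substrate prediction by similarity of a site's flanking window to a
# kinase's exemplar substrate peptides (BLOSUM62 position sums, threshold
# calibrated to a target false-positive rate on background windows), with
# optional PPI filtering of the emitted relations.

.pf_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pf_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pf_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pf_cache$BLOSUM62
}

#' Construct a kinase profile
#'
#' @param kinase_id protein id of the kinase.
#' @param exemplar_windows one or more 13-mer substrate windows.
#' @param family hierarchical family label (free text).
#' @param threshold score cutoff; usually set by [calibrate_threshold()].
#' @param fpr the false-positive rate the threshold was calibrated to.
#' @return object of class `kinase_profile`.
#' @export
kinase_profile <- function(kinase_id, exemplar_windows, family = "",
                           threshold = NA_real_, fpr = NA_real_) {
  if (length(exemplar_windows) == 0L) stop_pf("kinase %s has no exemplars", kinase_id)
  if (any(nchar(exemplar_windows) != 13L)) {
    stop_pf("exemplar windows must be 13-mers (kinase %s)", kinase_id)
  }
  structure(list(kinase_id = kinase_id, family = family,
                 exemplar_windows = exemplar_windows,
                 central_residue = substring(exemplar_windows[1], 7L, 7L),
                 threshold = threshold, fpr = fpr),
            class = "kinase_profile")
}

#' @export
print.kinase_profile <- function(x, ...) {
  cat(sprintf("kinase_profile %s (%s): %d exemplars, threshold %s\n",
              x$kinase_id, x$central_residue, length(x$exemplar_windows),
              ifelse(is.na(x$threshold), "uncalibrated",
                     sprintf("%.2f (fpr %.3g)", x$threshold, x$fpr))))
  invisible(x)
}

#' Read kinase exemplar profiles from TSV
#'
#' Expects columns `kinase_id`, `family`, `window`, one row per exemplar.
#'
#' @param path TSV path.
#' @return named list of [kinase_profile()] objects.
#' @export
read_kinase_profiles <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lst <- lapply(split(tab, tab$kinase_id), function(d) {
    kinase_profile(d$kinase_id[1], d$window, family = d$family[1])
  })
  lst[order(names(lst))]
}

# vectorised scorer: mean over exemplars of the position-summed BLOSUM62
# similarity; any position where either side is a pad contributes 0
score_windows <- function(profile, windows) {
  B <- blosum62()
  wm <- window_matrix(windows)
  total <- numeric(length(windows))
  for (ex in profile$exemplar_windows) {
    e <- strsplit(ex, "", fixed = TRUE)[[1]]
    s <- numeric(length(windows))
    for (j in 1:13) {
      if (e[j] == PAD_CHAR) next
      col <- wm[, j]
      ok <- col != PAD_CHAR
      if (any(ok)) s[ok] <- s[ok] + B[cbind(col[ok], e[j])]
    }
    total <- total + s
  }
  total / length(profile$exemplar_windows)
}

#' Score one site window against a kinase profile
#'
#' The score is the mean over the kinase's exemplar substrate windows of the
#' position-summed BLOSUM62 similarity between the window and the exemplar;
#' pad positions (`"_"`, on either side) score 0. Higher means more similar
#' to the kinase's known substrates.
#'
#' @param kinase a [kinase_profile()].
#' @param window a 13-mer window.
#' @return numeric score.
#' @export
score_site <- function(kinase, window) {
  stopifnot(inherits(kinase, "kinase_profile"), nchar(window) == 13L)
  score_windows(kinase, window)
}

#' Calibrate a kinase score threshold to a background false-positive rate
#'
#' Scores background windows of the kinase's central residue class and sets
#' the threshold to the smallest observed score whose pass rate
#' (`score >= threshold`) does not exceed `fpr` — the empirical `1 - fpr`
#' quantile. `fpr = 1` passes everything (threshold = min score);
#' `fpr -> 0` converges to the maximum background score.
#'
#' @param kinase a [kinase_profile()].
#' @param background_windows at least 200 13-mer windows of the null
#'   population (any central residue; the kinase's class is selected
#'   internally).
#' @param fpr target false-positive rate; the default 0.05 operationalises a
#'   "medium" prediction stringency.
#' @return the calibrated [kinase_profile()] (threshold and fpr filled in).
#' @export
calibrate_threshold <- function(kinase, background_windows, fpr = 0.05) {
  centers <- substring(background_windows, 7L, 7L)
  bg <- background_windows[centers == kinase$central_residue]
  if (length(bg) < 200L) {
    stop_pf("need >= 200 background windows of central residue %s (have %d)",
            kinase$central_residue, length(bg))
  }
  scores <- sort(score_windows(kinase, bg))
  n <- length(scores)
  pass_rate <- (n - seq_len(n) + 1L) / n   # rate of score >= scores[i]
  ok <- which(pass_rate <= fpr)
  kinase$threshold <- if (length(ok)) scores[ok[1]] else scores[n]
  kinase$fpr <- fpr
  kinase
}

#' Predict kinase-substrate relations
#'
#' Emits every (kinase, site) pair whose similarity score reaches the
#' kinase's calibrated threshold; with `require_ppi = TRUE` (default) the
#' unordered protein pair (kinase protein, site's protein) must additionally
#' have a PPI edge — self-pairs (a kinase phosphorylating its own protein)
#' always pass.
#'
#' @param kinases list of calibrated [kinase_profile()] objects.
#' @param sites site data.frame with `site_id`, `protein_id`, `window`.
#' @param ppi_edges data.frame with `protein_a`, `protein_b` (undirected);
#'   may be empty.
#' @param require_ppi drop relations without PPI support (default `TRUE`).
#' @return data.frame with `kinase_id`, `site_id`, `score`, `passed_ppi`.
#' @export
predict_relations <- function(kinases, sites, ppi_edges = NULL,
                              require_ppi = TRUE) {
  ppi_keys <- character(0)
  if (!is.null(ppi_edges) && nrow(ppi_edges)) {
    ppi_keys <- unique(c(paste(ppi_edges$protein_a, ppi_edges$protein_b),
                         paste(ppi_edges$protein_b, ppi_edges$protein_a)))
  }
  out <- lapply(kinases, function(kp) {
    if (is.na(kp$threshold)) {
      stop_pf("kinase %s is not calibrated", kp$kinase_id)
    }
    sc <- score_windows(kp, sites$window)
    hit <- sc >= kp$threshold
    if (!any(hit)) return(NULL)
    d <- data.frame(kinase_id = kp$kinase_id, site_id = sites$site_id[hit],
                    score = sc[hit], stringsAsFactors = FALSE)
    prot <- sites$protein_id[hit]
    d$passed_ppi <- prot == kp$kinase_id |
      paste(kp$kinase_id, prot) %in% ppi_keys
    d
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(kinase_id = character(0), site_id = character(0),
                      score = numeric(0), passed_ppi = logical(0))
  }
  rownames(out) <- NULL
  pf_log("kinase_substrate", "%d score-passing relations, %d with PPI support (require_ppi=%s)",
         nrow(out), sum(out$passed_ppi), require_ppi)
  if (require_ppi) out[out$passed_ppi, , drop = FALSE] else out
}

#' Census detected proteins against a kinase/phosphatase catalogue
#'
#' @param proteins_detected character vector of detected protein ids (e.g.
#'   all phosphoproteins of the study).
#' @param catalogue data.frame with `protein_id` and `family` (e.g. an
#'   iTAK-style group-family-subfamily label).
#' @return list of class `kinase_census`: `families` (per-family annotated
#'   count, detected count, detected percentage of the annotated family to 2
#'   decimals, and the family's share of all detected members to 1 decimal),
#'   `n_detected_members`, `pct_of_detected` (share of detected proteins that
#'   are catalogue members, 1 decimal) and `pct_of_catalogue` (share of the
#'   catalogue that was detected, 1 decimal).
#' @export
kinase_census <- function(proteins_detected, catalogue) {
  stopifnot(all(c("protein_id", "family") %in% names(catalogue)))
  catalogue <- unique(catalogue[, c("protein_id", "family")])
  det <- unique(proteins_detected)
  members <- det[det %in% catalogue$protein_id]
  fam_tot <- table(catalogue$family)
  fam_det <- table(factor(catalogue$family[match(members, catalogue$protein_id)],
                          levels = names(fam_tot)))
  families <- data.frame(
    family = names(fam_tot),
    annotated = as.integer(fam_tot),
    detected = as.integer(fam_det),
    percent = round_half_up(100 * as.integer(fam_det) / as.integer(fam_tot), 2),
    share_of_detected = if (length(members)) {
      round_half_up(100 * as.integer(fam_det) / length(members), 1)
    } else {
      rep(0, length(fam_tot))
    },
    stringsAsFactors = FALSE)
  structure(list(
    families = families,
    n_detected_members = length(members),
    pct_of_detected = round_half_up(100 * length(members) / length(det), 1),
    pct_of_catalogue = round_half_up(
      100 * length(members) / nrow(catalogue), 1)),
    class = "kinase_census")
}

#' @export
print.kinase_census <- function(x, ...) {
  cat(sprintf("Catalogue census: %d detected members (%.1f%% of detected proteins, %.1f%% of the catalogue)\n",
              x$n_detected_members, x$pct_of_detected, x$pct_of_catalogue))
  print(utils::head(x$families[order(-x$families$percent), ], 10), row.names = FALSE)
  invisible(x)
}
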