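# Synthetic phosphoproteomics study generator.
#
# The generator plants everything the downstream stages try to recover:
# site residues at a realistic S/T/Y mix, a sites-per-protein distribution
# matching published tomato phosphoproteome summaries, kinase consensus
# motifs written into substrate flanking sequence, and per-kinase activity
# shifts that propagate to substrate-site intensities on the log2 scale.

# background amino-acid frequencies (approx. UniProt averages, renormalised)
default_aa_frequencies <- function() {
  f <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.7,
         G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
         P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
  f / sum(f)
}

# sites-per-protein pmf over 1..10 sites: 56.1% single-site, 21.7% two-site,
# 22.2% three-or-more with ~4% mass at >= 7 sites
default_sites_pmf <- function() {
  c(`1` = 0.561, `2` = 0.217, `3` = 0.080, `4` = 0.050, `5` = 0.030,
    `6` = 0.022, `7` = 0.015, `8` = 0.010, `9` = 0.008, `10` = 0.007)
}

#' Default kinase motif library
#'
#' A library of single-determinant consensus motifs over 13-mer windows,
#' patterned on the motif classes that dominate plant phosphoproteomes:
#' proline-directed `[SP]`/`[TP]` (CDK/MAPK-like), basophilic `[RxxS]`
#' (CaMK/SnRK-like), `[GS]`, acidophilic `[SD]`/`[SxxE]` (CK2-like) and
#' relatives. Offsets are relative to the central residue (position 0).
#'
#' @param n_kinases number of kinases to draw motifs for (library entries are
#'   recycled if larger than the base set of 20).
#' @return list of motif specs: `central` residue, `fixed` named vector
#'   (names = signed offsets, values = required residues), `pattern` string.
#' @export
default_motif_library <- function(n_kinases = 20L) {
  base <- list(
    list(central = "S", fixed = c(`1` = "P")),   # SP  (x3: CDK/MAPK-like)
    list(central = "S", fixed = c(`1` = "P")),
    list(central = "S", fixed = c(`1` = "P")),
    list(central = "S", fixed = c(`-3` = "R")),  # RxxS (x3: CaMK-like)
    list(central = "S", fixed = c(`-3` = "R")),
    list(central = "S", fixed = c(`-3` = "R")),
    list(central = "S", fixed = c(`-1` = "G")),  # GS
    list(central = "S", fixed = c(`-1` = "G")),
    list(central = "S", fixed = c(`3` = "E")),   # SxxE (CK2-like)
    list(central = "S", fixed = c(`3` = "E")),
    list(central = "S", fixed = c(`1` = "D")),   # SD
    list(central = "S", fixed = c(`2` = "D")),   # SxD
    list(central = "S", fixed = c(`-3` = "K")),  # KxxS
    list(central = "S", fixed = c(`-2` = "R")),  # RxS
    list(central = "S", fixed = c(`1` = "L")),   # SL
    list(central = "S", fixed = c(`-1` = "L")),  # LS
    list(central = "T", fixed = c(`1` = "P")),   # TP (x2)
    list(central = "T", fixed = c(`1` = "P")),
    list(central = "T", fixed = c(`-3` = "R")),  # RxxT
    list(central = "Y", fixed = c(`-1` = "D"))   # DY
  )
  out <- rep(base, length.out = n_kinases)
  lapply(out, function(m) {
    m$pattern <- motif_pattern(m$central, m$fixed)
    m
  })
}

#' Multi-determinant kinase motif library
#'
#' Consensus motifs with three fixed flank positions each, emulating kinases
#' with several substrate determinants (as in full consensus sequences like
#' S-P-x-K). With more determinants the similarity scorer separates true
#' substrates sharply from background, making this library the right study
#' condition for kinase-substrate prediction recovery; the single-determinant
#' [default_motif_library()] is the right condition for motif discovery.
#'
#' @param n_kinases number of kinases (base set of 10, recycled if larger).
#' @return list of motif specs as in [default_motif_library()].
#' @export
multi_determinant_motif_library <- function(n_kinases = 10L) {
  base <- list(
    list(central = "S", fixed = c(`-3` = "R", `1` = "P", `3` = "K")),
    list(central = "S", fixed = c(`-3` = "K", `-2` = "R", `2` = "L")),
    list(central = "S", fixed = c(`1` = "D", `2` = "E", `3` = "E")),
    list(central = "S", fixed = c(`-5` = "R", `-3` = "R", `1` = "L")),
    list(central = "S", fixed = c(`-1` = "G", `1` = "G", `2` = "R")),
    list(central = "T", fixed = c(`1` = "P", `2` = "P", `-2` = "R")),
    list(central = "S", fixed = c(`-2` = "P", `1` = "P", `4` = "R")),
    list(central = "S", fixed = c(`-6` = "R", `-3` = "H", `1` = "F")),
    list(central = "Y", fixed = c(`-1` = "D", `1` = "E", `3` = "P")),
    list(central = "S", fixed = c(`-4` = "K", `-3` = "K", `1` = "N"))
  )
  out <- rep(base, length.out = n_kinases)
  lapply(out, function(m) {
    m$pattern <- motif_pattern(m$central, m$fixed)
    m
  })
}

default_planted_activities <- function() {
  cmp <- c("AC-B4", "AC-MG")
  list(
    list(kinase = 1L, comparison = cmp, ratio = 2.0),
    list(kinase = 2L, comparison = cmp, ratio = 1.8),
    list(kinase = 4L, comparison = cmp, ratio = 1.6),
    list(kinase = 5L, comparison = cmp, ratio = 0.50),
    list(kinase = 7L, comparison = cmp, ratio = 0.55)
  )
}

#' Configuration of a synthetic phosphoproteomics study
#'
#' Collects every knob of the generator with defaults emulating a three-stage
#' tomato fruit-ripening TMT design: conditions AC-MG, AC-B4 and rin-B4 with
#' 3 replicates each, ~83/12/5 pSer/pThr/pTyr, 56.1%/21.7%/22.2% of proteins
#' with 1/2/3+ sites, 20 kinases with 30 substrates each, and 5 kinases
#' planted with activity shifts of ratio >= 1.5 on the AC-B4 vs AC-MG
#' comparison.
#'
#' @param seed integer seed; the study is byte-identical given equal config.
#' @param n_proteins number of proteins to simulate.
#' @param protein_length mean and sd of protein length (normal, truncated
#'   below at 50 residues).
#' @param aa_frequencies named 20-vector of residue frequencies (sums to 1).
#' @param residue_mix probabilities of (S, T, Y) site residues.
#' @param sites_per_protein_pmf named probability vector over site counts.
#' @param n_kinases number of kinases (the first `n_kinases` proteins).
#' @param motif_library per-kinase consensus motifs, see
#'   [default_motif_library()].
#' @param substrates_per_kinase planted true substrates per kinase.
#' @param conditions condition labels.
#' @param replicates_per_condition replicates per condition (>= 2 for any
#'   comparison submitted to a t-test).
#' @param baseline_log_intensity mean and sd of per-site baseline log2
#'   intensity.
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param planted_activities list of `list(kinase=, comparison=c(num, den),
#'   ratio=)` activity shifts; `ratio` multiplies substrate-site intensity in
#'   the numerator condition (> 1 activated, < 1 inhibited).
#' @param n_exemplars substrate windows exported per kinase as exemplars for
#'   the similarity scorer.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 1000L,
                       protein_length = c(mean = 300, sd = 80),
                       aa_frequencies = default_aa_frequencies(),
                       residue_mix = c(S = 0.83, T = 0.12, Y = 0.05),
                       sites_per_protein_pmf = default_sites_pmf(),
                       n_kinases = 20L,
                       motif_library = default_motif_library(n_kinases),
                       substrates_per_kinase = 30L,
                       conditions = c("AC-MG", "AC-B4", "rin-B4"),
                       replicates_per_condition = 3L,
                       baseline_log_intensity = c(mean = 20, sd = 2),
                       noise_sd = 0.25,
                       planted_activities = default_planted_activities(),
                       n_exemplars = 5L) {
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              protein_length = protein_length,
              aa_frequencies = aa_frequencies, residue_mix = residue_mix,
              sites_per_protein_pmf = sites_per_protein_pmf,
              n_kinases = as.integer(n_kinases),
              motif_library = motif_library,
              substrates_per_kinase = as.integer(substrates_per_kinase),
              conditions = conditions,
              replicates_per_condition = as.integer(replicates_per_condition),
              baseline_log_intensity = baseline_log_intensity,
              noise_sd = noise_sd,
              planted_activities = planted_activities,
              n_exemplars = as.integer(n_exemplars))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (nm in c("aa_frequencies", "residue_mix", "sites_per_protein_pmf")) {
    v <- cfg[[nm]]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop_pf("%s must be non-negative and sum to 1 (got %.12f)", nm, sum(v))
    }
  }
  if (!setequal(names(cfg$aa_frequencies), AA20)) {
    stop_pf("aa_frequencies must be named by the 20 standard amino acids")
  }
  if (length(cfg$motif_library) < cfg$n_kinases) {
    stop_pf("motif_library shorter than n_kinases")
  }
  for (pa in cfg$planted_activities) {
    if (pa$ratio <= 0) stop_pf("planted activity ratios must be > 0")
    if (!all(pa$comparison %in% cfg$conditions)) {
      stop_pf("planted activity comparison uses unknown condition")
    }
  }
  invisible(cfg)
}

#' Simulate a proteome
#'
#' Draws `n_proteins` sequences of i.i.d. residues from `aa_frequencies`,
#' with lengths from a truncated normal (minimum 50). Deterministic given
#' the config seed.
#'
#' @param config a [sim_config()].
#' @return named character vector of sequences (ids `P0001`, ...).
#' @export
simulate_proteome <- function(config) {
  set.seed(config$seed)
  n <- config$n_proteins
  len <- pmax(50L, as.integer(round(stats::rnorm(
    n, config$protein_length[["mean"]], config$protein_length[["sd"]]))))
  chars <- sample(names(config$aa_frequencies), sum(len), replace = TRUE,
                  prob = config$aa_frequencies)
  idx <- rep.int(seq_len(n), len)
  seqs <- vapply(split(chars, idx), paste0, character(1), collapse = "")
  names(seqs) <- sprintf("P%04d", seq_len(n))
  seqs
}

#' Plant phosphosites and kinase motifs into a proteome
#'
#' Per protein, draws a site count from `sites_per_protein_pmf` and residues
#' from `residue_mix`, overwriting the sequence at the chosen positions. The
#' first `n_kinases` proteins act as kinases; each receives
#' `substrates_per_kinase` true substrate sites of its motif's central
#' residue, whose flanking sequence is overwritten to the consensus.
#' Substrate sites are disjoint across kinases and flank overwrites never
#' touch another site's central residue.
#'
#' @param config a [sim_config()].
#' @param proteome from [simulate_proteome()].
#' @return list with `proteome` (motif-edited sequences), `sites` (data.frame
#'   site_id/protein_id/position/residue/window) and `truth` (ground truth:
#'   `edges`, `effects`, `kinases`).
#' @export
plant_sites_and_motifs <- function(config, proteome) {
  set.seed(config$seed + 1L)
  n <- length(proteome)
  lens <- nchar(proteome)
  chars <- strsplit(proteome, "", fixed = TRUE)

  counts_support <- as.integer(names(config$sites_per_protein_pmf))
  k_sites <- if (length(counts_support) == 1L) {
    rep(counts_support, n)
  } else {
    sample(counts_support, n, replace = TRUE,
           prob = config$sites_per_protein_pmf)
  }
  k_sites <- pmin(k_sites, lens %/% 2L)  # never more sites than half a protein

  prot_ids <- names(proteome)
  pos_list <- lapply(seq_len(n), function(i) sort(sample.int(lens[i], k_sites[i])))
  res_list <- lapply(k_sites, function(k) {
    sample(STY, k, replace = TRUE, prob = config$residue_mix)
  })
  for (i in seq_len(n)) {
    chars[[i]][pos_list[[i]]] <- res_list[[i]]
  }

  sites <- data.frame(
    protein_id = rep.int(prot_ids, k_sites),
    position = unlist(pos_list, use.names = FALSE),
    residue = unlist(res_list, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  sites$site_id <- site_id(sites$protein_id, sites$position, sites$residue)

  # positions that must never be overwritten by a motif flank
  is_center <- new.env(parent = emptyenv())
  for (j in seq_len(nrow(sites))) {
    assign(paste0(sites$protein_id[j], ":", sites$position[j]), TRUE, is_center)
  }
  is_planted <- new.env(parent = emptyenv())

  kin_ids <- prot_ids[seq_len(config$n_kinases)]
  assigned <- rep(NA_character_, nrow(sites))
  edges <- list()
  for (j in seq_len(config$n_kinases)) {
    motif <- config$motif_library[[j]]
    offs <- as.integer(names(motif$fixed))
    cand <- which(is.na(assigned) & sites$residue == motif$central)
    ok <- vapply(cand, function(s) {
      pid <- sites$protein_id[s]; pos <- sites$position[s]
      L <- lens[[match(pid, prot_ids)]]
      for (o in offs) {
        p <- pos + o
        if (p < 1L || p > L) return(FALSE)
        key <- paste0(pid, ":", p)
        if (!is.null(is_center[[key]]) || !is.null(is_planted[[key]])) {
          return(FALSE)
        }
      }
      TRUE
    }, logical(1))
    cand <- cand[ok]
    take <- config$substrates_per_kinase
    if (length(cand) < take) {
      warning(sprintf("kinase %s: only %d eligible substrate sites (wanted %d)",
                      kin_ids[j], length(cand), take))
      take <- length(cand)
    }
    chosen <- if (length(cand) > 1L) sample(cand, take) else cand
    for (s in chosen) {
      pid <- sites$protein_id[s]; pos <- sites$position[s]
      i <- match(pid, prot_ids)
      for (oi in seq_along(offs)) {
        p <- pos + offs[oi]
        chars[[i]][p] <- unname(motif$fixed[oi])
        assign(paste0(pid, ":", p), TRUE, is_planted)
      }
    }
    assigned[chosen] <- kin_ids[j]
    edges[[j]] <- data.frame(kinase = kin_ids[j],
                             site_id = sites$site_id[chosen],
                             stringsAsFactors = FALSE)
  }

  proteome_out <- vapply(chars, paste0, character(1), collapse = "")
  names(proteome_out) <- prot_ids
  sites$window <- vapply(seq_len(nrow(sites)), function(s) {
    extract_window(proteome_out[[sites$protein_id[s]]], sites$position[s])
  }, character(1))
  sites <- sites[, c("site_id", "protein_id", "position", "residue", "window")]

  # resolve planted activities to kinase protein ids
  planted <- lapply(config$planted_activities, function(pa) {
    kid <- if (is.numeric(pa$kinase)) kin_ids[pa$kinase] else pa$kinase
    list(kinase = kid, comparison = pa$comparison, ratio = pa$ratio)
  })
  nk <- length(kin_ids)
  kin_states <- data.frame(kinase = kin_ids,
                           comparison = rep(NA_character_, nk),
                           ratio = rep(1, nk), state = rep("null", nk),
                           stringsAsFactors = FALSE)
  eff <- list()
  for (pa in planted) {
    i <- match(pa$kinase, kin_states$kinase)
    kin_states$comparison[i] <- paste(pa$comparison, collapse = "/")
    kin_states$ratio[i] <- pa$ratio
    kin_states$state[i] <- if (pa$ratio > 1) "activated" else "inhibited"
    subs <- edges[[i]]$site_id
    if (length(subs)) {
      eff[[length(eff) + 1L]] <- data.frame(
        site_id = subs,
        comparison = paste(pa$comparison, collapse = "/"),
        condition = pa$comparison[1],
        true_log2fc = log2(pa$ratio),
        kinase = pa$kinase, stringsAsFactors = FALSE)
    }
  }
  effects <- if (length(eff)) do.call(rbind, eff) else
    data.frame(site_id = character(0), comparison = character(0),
               condition = character(0), true_log2fc = numeric(0),
               kinase = character(0))

  edges_df <- if (length(edges)) do.call(rbind, edges) else
    data.frame(kinase = character(0), site_id = character(0))
  rownames(edges_df) <- NULL
  truth <- list(edges = edges_df, effects = effects, kinases = kin_states)
  list(proteome = proteome_out, sites = sites, truth = truth)
}

#' Simulate TMT-like intensities
#'
#' Per replicate sample, log2 intensity = per-site baseline + condition
#' effect (the planted log2 ratio for substrate sites of shifted kinases,
#' 0 otherwise) + N(0, noise_sd); exponentiated to the raw intensity scale.
#'
#' @param config a [sim_config()].
#' @param sites site data.frame from [plant_sites_and_motifs()].
#' @param truth ground truth from [plant_sites_and_motifs()].
#' @return a [quant_table()].
#' @export
simulate_intensities <- function(config, sites, truth) {
  set.seed(config$seed + 2L)
  ns <- nrow(sites)
  conds <- config$conditions
  reps <- config$replicates_per_condition
  baseline <- stats::rnorm(ns, config$baseline_log_intensity[["mean"]],
                           config$baseline_log_intensity[["sd"]])
  effect <- matrix(0, ns, length(conds), dimnames = list(sites$site_id, conds))
  if (nrow(truth$effects)) {
    i <- match(truth$effects$site_id, sites$site_id)
    effect[cbind(i, match(truth$effects$condition, conds))] <-
      truth$effects$true_log2fc
  }
  samples <- as.vector(t(outer(conds, seq_len(reps), function(c, r) {
    paste0(c, "_R", r)
  })))
  design <- stats::setNames(rep(conds, each = reps), samples)
  logi <- matrix(NA_real_, ns, length(samples),
                 dimnames = list(sites$site_id, samples))
  for (j in seq_along(samples)) {
    logi[, j] <- baseline + effect[, design[[samples[j]]]] +
      stats::rnorm(ns, 0, config$noise_sd)
  }
  quant_table(2^logi, design)
}

simulate_annotations <- function(config, proteome, n_terms = 50L,
                                 mean_terms_per_protein = 2) {
  set.seed(config$seed + 3L)
  terms <- sprintf("TERM%03d", seq_len(n_terms))
  k <- pmax(1L, stats::rpois(length(proteome), mean_terms_per_protein))
  k <- pmin(k, n_terms)
  memb <- lapply(k, function(m) sample(terms, m))
  ann <- data.frame(
    term_id = unlist(memb, use.names = FALSE),
    term_name = paste0("synthetic process ",
                       sub("TERM", "", unlist(memb, use.names = FALSE))),
    namespace = "synthetic",
    protein_id = rep.int(names(proteome), k),
    stringsAsFactors = FALSE
  )
  structure(ann, class = c("annotation_table", "data.frame"))
}

#' Build a PPI edge table from ground truth plus random pairs
#'
#' The study-level PPI evidence used to filter kinase-substrate predictions:
#' every true kinase-substrate protein pair, plus `random_fraction` times as
#' many random protein pairs (decoys).
#'
#' @param truth ground truth from [plant_sites_and_motifs()].
#' @param sites site data.frame.
#' @param proteome named sequences.
#' @param random_fraction decoy pairs as a fraction of true pairs.
#' @param seed RNG seed for the decoys.
#' @return data.frame with columns `protein_a`, `protein_b`.
#' @export
simulate_ppi <- function(truth, sites, proteome, random_fraction = 0.1,
                         seed = 1L) {
  set.seed(seed)
  sub_prot <- sites$protein_id[match(truth$edges$site_id, sites$site_id)]
  true_pairs <- unique(data.frame(protein_a = truth$edges$kinase,
                                  protein_b = sub_prot,
                                  stringsAsFactors = FALSE))
  n_rand <- ceiling(random_fraction * nrow(true_pairs))
  rand <- data.frame(protein_a = sample(names(proteome), n_rand, replace = TRUE),
                     protein_b = sample(names(proteome), n_rand, replace = TRUE),
                     stringsAsFactors = FALSE)
  unique(rbind(true_pairs, rand))
}

#' Simulate a complete synthetic phosphoproteomics study
#'
#' Runs [simulate_proteome()], [plant_sites_and_motifs()] and
#' [simulate_intensities()] under the config seed and assembles the full
#' study: proteome, sites, quantification, ground truth, kinase exemplar
#' windows, PPI edges and a synthetic annotation table. Byte-identical
#' across runs with an equal config.
#'
#' @param config a [sim_config()].
#' @return an object of class `phospho_study`.
#' @export
simulate_phospho_study <- function(config = sim_config()) {
  validate_sim_config(config)
  proteome0 <- simulate_proteome(config)
  planted <- plant_sites_and_motifs(config, proteome0)
  quant <- simulate_intensities(config, planted$sites, planted$truth)
  ann <- simulate_annotations(config, planted$proteome)
  ppi <- simulate_ppi(planted$truth, planted$sites, planted$proteome,
                      seed = config$seed + 4L)

  # kinase exemplars: the first n_exemplars substrate windows per kinase
  ed <- planted$truth$edges
  ex <- do.call(rbind, lapply(split(ed, ed$kinase), function(d) {
    take <- utils::head(d$site_id, config$n_exemplars)
    data.frame(kinase_id = d$kinase[1], family = "synthetic",
               window = planted$sites$window[match(take, planted$sites$site_id)],
               stringsAsFactors = FALSE)
  }))
  if (is.null(ex)) {
    ex <- data.frame(kinase_id = character(0), family = character(0),
                     window = character(0))
  }
  rownames(ex) <- NULL

  structure(list(proteome = planted$proteome, sites = planted$sites,
                 quant = quant, truth = planted$truth, exemplars = ex,
                 ppi = ppi, annotations = ann, config = config),
            class = "phospho_study")
}

#' @export
print.phospho_study <- function(x, ...) {
  cat(sprintf(paste0("Synthetic phosphoproteomics study\n",
                     "  proteins: %d   sites: %d   kinases: %d\n",
                     "  conditions: %s (%d replicates each)\n",
                     "  planted kinase shifts: %d\n"),
              length(x$proteome), nrow(x$sites), x$config$n_kinases,
              paste(x$config$conditions, collapse = ", "),
              x$config$replicates_per_condition,
              sum(x$truth$kinases$state != "null")))
  invisible(x)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Writes `proteome.fasta`, `sites.tsv`, `design.tsv`, `truth_edges.tsv`,
#' `truth_effects.tsv`, `kinase_profiles.tsv`, `ppi.tsv` and
#' `annotations.tsv`.
#'
#' @param study a `phospho_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(study$proteome, file.path(dir, "proteome.fasta"))
  write_site_table(study$sites, study$quant, file.path(dir, "sites.tsv"),
                   file.path(dir, "design.tsv"))
  wt <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(study$truth$edges, "truth_edges.tsv")
  wt(study$truth$effects, "truth_effects.tsv")
  wt(study$truth$kinases, "truth_kinases.tsv")
  wt(study$exemplars, "kinase_profiles.tsv")
  wt(study$ppi, "ppi.tsv")
  wt(study$annotations, "annotations.tsv")
  invisible(dir)
}
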