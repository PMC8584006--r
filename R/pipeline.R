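# End-to-end pipeline over declared files: every stage reads its inputs from
# the output directory and writes TSV/SIF/GraphML/JSON artifacts, so stages
# can be re-run individually.

#' Default pipeline configuration
#'
#' Nested list mirroring every tunable of the pipeline; all thresholds
#' default to the study values (ratio 1.5, p 0.05, motif p 1e-6 with
#' support > 20, prediction fpr 0.05, 1000 permutations, |NES| >= 1).
#'
#' @return named nested list with entries `sim` (arguments of
#'   [sim_config()]), `comparisons`, and `thresholds`.
#' @export
default_pipeline_config <- function() {
  list(
    sim = list(),   # overrides for sim_config()
    comparisons = list(c("AC-B4", "AC-MG"), c("AC-B4", "rin-B4"),
                       c("AC-MG", "rin-B4")),
    thresholds = list(
      fc_threshold = 1.5, alpha = 0.05,
      motif_p_threshold = 1e-6, min_occurrences = 21L,
      fpr = 0.05, require_ppi = TRUE,
      n_permutations = 1000L, weight_exponent = 1, min_set_size = 3L,
      network_p_threshold = 0.05, enrich_alpha = 0.05)
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    full <- paste0(path, k)
    if (!k %in% names(base)) stop_pf("unknown config key: %s", full)
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(full, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param config `NULL` (defaults), a YAML file path, or a nested list of
#'   overrides. Unknown keys are rejected before any stage runs. `sim`
#'   entries are passed to [sim_config()] and validated there.
#' @return validated nested configuration list.
#' @export
load_pipeline_config <- function(config = NULL) {
  base <- default_pipeline_config()
  if (is.null(config)) return(base)
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_pf("config must be NULL, a path, or a list")
  cfg <- merge_config(base, config)
  bad <- setdiff(names(cfg$sim), names(formals(sim_config)))
  if (length(bad)) stop_pf("unknown sim config key: %s", paste(bad, collapse = ", "))
  cfg
}

cmp_tag <- function(cmp) paste0(cmp[1], "_vs_", cmp[2])

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_study_dir <- function(out_dir) {
  d <- file.path(out_dir, "sim")
  proteome <- read_fasta(file.path(d, "proteome.fasta"))
  st <- read_site_table(file.path(d, "sites.tsv"), proteome,
                        file.path(d, "design.tsv"))
  list(proteome = proteome, sites = st$sites, quant = st$quant, dir = d)
}

#' Run the full synthetic-study pipeline
#'
#' Chains `simulate -> diff -> motifs -> predict-ks -> kinase-activity ->
#' network -> enrich` over files under `out_dir`, writing a `manifest.json`
#' with the configuration, the seed, and per-stage row counts. Stage k of
#' the pipeline derives its RNG seed as `seed + k`, so every stage is
#' individually reproducible.
#'
#' @param config see [load_pipeline_config()].
#' @param seed global integer seed.
#' @param out_dir output directory.
#' @param stages subset of stages to run (defaults to all, in order); later
#'   stages read the files earlier stages wrote.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = NULL, seed = 1L, out_dir = "phosflow_out",
                         stages = c("simulate", "diff", "motifs", "predict-ks",
                                    "kinase-activity", "network", "enrich")) {
  cfg <- load_pipeline_config(config)
  th <- cfg$thresholds
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  if ("simulate" %in% stages) {
    sim_args <- cfg$sim
    sim_args$seed <- seed + 1L
    study <- do.call(sim_config, sim_args)
    study <- simulate_phospho_study(study)
    write_study(study, file.path(out_dir, "sim"))
    counts$simulate <- c(proteins = length(study$proteome),
                         sites = nrow(study$sites))
    pf_log("pipeline", "simulate: %d proteins, %d sites",
           length(study$proteome), nrow(study$sites))
  }

  if (any(c("diff", "motifs", "predict-ks", "kinase-activity", "network",
            "enrich") %in% stages)) {
    sd <- read_study_dir(out_dir)
  }

  if ("diff" %in% stages) {
    venn_input <- list()
    for (cmp in cfg$comparisons) {
      d <- phospho_diff(sd$quant, cmp, fc_threshold = th$fc_threshold,
                        alpha = th$alpha)
      write_tsv(as.data.frame(d), file.path(out_dir, paste0("diff_", cmp_tag(cmp), ".tsv")))
      venn_input[[cmp_tag(cmp)]] <- d
      counts[[paste0("diff_", cmp_tag(cmp))]] <-
        c(up = sum(d$status == "up"), down = sum(d$status == "down"))
    }
    rd <- residue_distribution(sd$sites)
    hist <- sites_per_protein_histogram(sd$sites)
    venn <- overlap_counts(venn_input)
    summary <- list(
      n_proteins = length(sd$proteome),
      n_phosphoproteins = length(unique(sd$sites$protein_id)),
      n_sites = nrow(sd$sites),
      union_proteins = union_size(length(sd$proteome),
                                  length(unique(sd$sites$protein_id)),
                                  sum(unique(sd$sites$protein_id) %in% names(sd$proteome))),
      residue_distribution = rd,
      sites_per_protein = hist,
      venn_cells = as.list(venn))
    jsonlite::write_json(summary, file.path(out_dir, "diff_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("motifs" %in% stages) {
    all_motifs <- list()
    for (res in STY) {
      fg <- sd$sites$window[sd$sites$residue == res]
      if (length(fg) < th$min_occurrences) next
      bg <- proteome_windows(sd$proteome, res)
      m <- motif_x(fg, bg, res, p_threshold = th$motif_p_threshold,
                   min_occurrences = th$min_occurrences)
      if (length(m)) all_motifs[[res]] <- as.data.frame(m)
    }
    mo <- if (length(all_motifs)) do.call(rbind, all_motifs) else
      as.data.frame(structure(list(), class = "phos_motifs"))
    write_tsv(mo, file.path(out_dir, "motifs.tsv"))
    counts$motifs <- c(motifs = nrow(mo))
  }

  if ("predict-ks" %in% stages) {
    profiles <- read_kinase_profiles(file.path(sd$dir, "kinase_profiles.tsv"))
    ppi <- read_ppi(file.path(sd$dir, "ppi.tsv"))
    bg <- unlist(lapply(STY, proteome_windows, proteome = sd$proteome))
    profiles <- lapply(profiles, calibrate_threshold, background_windows = bg,
                       fpr = th$fpr)
    rel <- predict_relations(profiles, sd$sites, ppi,
                             require_ppi = th$require_ppi)
    write_tsv(rel, file.path(out_dir, "relations.tsv"))
    counts$predict_ks <- c(relations = nrow(rel))
  }

  if (any(c("kinase-activity", "network") %in% stages)) {
    rel <- utils::read.delim(file.path(out_dir, "relations.tsv"),
                             stringsAsFactors = FALSE)
  }

  if ("kinase-activity" %in% stages) {
    for (i in seq_along(cfg$comparisons)) {
      cmp <- cfg$comparisons[[i]]
      d <- phospho_diff(sd$quant, cmp, fc_threshold = th$fc_threshold,
                        alpha = th$alpha)
      fit <- ksea(d, rel, n_permutations = th$n_permutations,
                  weight_exponent = th$weight_exponent,
                  min_set_size = th$min_set_size, seed = seed + 100L + i)
      write_tsv(fit$table, file.path(out_dir, paste0("activity_", cmp_tag(cmp), ".tsv")))
      counts[[paste0("activity_", cmp_tag(cmp))]] <-
        c(kinases = nrow(fit$table), skipped = nrow(fit$skipped))
    }
  }

  if ("network" %in% stages) {
    for (i in seq_along(cfg$comparisons)) {
      cmp <- cfg$comparisons[[i]]
      d <- phospho_diff(sd$quant, cmp, fc_threshold = th$fc_threshold,
                        alpha = th$alpha)
      atab <- utils::read.delim(
        file.path(out_dir, paste0("activity_", cmp_tag(cmp), ".tsv")),
        stringsAsFactors = FALSE)
      fit <- structure(list(table = atab, context = cmp_tag(cmp)),
                       class = "ksea")
      net <- build_network(fit, d, rel, p_threshold = th$network_p_threshold)
      write_network(net, file.path(out_dir, paste0("network_", cmp_tag(cmp), ".sif")), "SIF")
      write_network(net, file.path(out_dir, paste0("network_", cmp_tag(cmp), ".graphml")), "GraphML")
      write_tsv(degree_summary(net, top_k = 1e9)$kinases,
                file.path(out_dir, paste0("degree_", cmp_tag(cmp), ".tsv")))
      counts[[paste0("network_", cmp_tag(cmp))]] <-
        c(kinases = nrow(net$kinases), sites = nrow(net$sites),
          edges = nrow(net$edges))
    }
  }

  if ("enrich" %in% stages) {
    ann <- read_annotations(file.path(sd$dir, "annotations.tsv"))
    universe <- unique(sd$sites$protein_id)
    for (cmp in cfg$comparisons) {
      d <- phospho_diff(sd$quant, cmp, fc_threshold = th$fc_threshold,
                        alpha = th$alpha)
      hit_prot <- unique(sd$sites$protein_id[match(d$site_id[d$status != "ns"],
                                                   sd$sites$site_id)])
      if (length(hit_prot) == 0L) next
      e <- enrich(hit_prot, universe, ann, alpha = th$enrich_alpha)
      write_tsv(as.data.frame(e), file.path(out_dir, paste0("enrichment_", cmp_tag(cmp), ".tsv")))
      write_tsv(utils::head(as.data.frame(e), 20),
                file.path(out_dir, paste0("enrichment_top20_", cmp_tag(cmp), ".tsv")))
      counts[[paste0("enrich_", cmp_tag(cmp))]] <-
        c(terms = nrow(e), significant = sum(e$significant))
    }
  }

  manifest <- list(seed = seed, stages = stages, config = cfg,
                   package_version = as.character(utils::packageVersion("phosflow")),
                   counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
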