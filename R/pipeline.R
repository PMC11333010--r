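# End-to-end orchestration: enumerate and classify topologies, compute OFHT
# over a supplied or synthetic classification table, run the lattice
# designability analysis, and collect the figure-level tables plus a run
# manifest.  All stages are deterministic given the configuration.

#' Pipeline configuration
#'
#' Defaults reproduce the study settings: strand counts 3--6, chain length
#' 16, eps_HH = 1.0, eps_penalty = 2.0 with robustness sweep
#' \{0.1, 0.5, 1.0, 3.0, 4.0\}, high-designability threshold 100.
#'
#' @param n_min,n_max Strand count range for topology enumeration.
#' @param lattice_length Lattice chain length.
#' @param eps_hh,eps_penalty Energy parameters of the main scan.
#' @param eps_penalty_sweep Penalty values for the robustness sweep (used by
#'   the `"sweep"` stage).
#' @param threshold High-designability cutoff on N_s.
#' @param table Optional ECOD-like table for the OFHT stage; when `NULL` a
#'   synthetic table is generated from `table_spec`.
#' @param table_spec [synthetic_table_spec()] used when `table` is `NULL`.
#' @param seed Integer seed forwarded to the synthetic generator.
#' @return List of class `run_config`.
#' @export
run_config <- function(n_min = 3L, n_max = 6L, lattice_length = 16L,
                       eps_hh = 1.0, eps_penalty = 2.0,
                       eps_penalty_sweep = c(0.1, 0.5, 1.0, 3.0, 4.0),
                       threshold = 100, table = NULL, table_spec = NULL,
                       seed = 1L) {
  if (is.null(table_spec)) table_spec <- synthetic_table_spec(seed = seed)
  stopifnot(n_min >= 2L, n_max >= n_min, lattice_length >= 2L,
            eps_hh >= 0, eps_penalty >= 0, threshold >= 0)
  structure(list(n_min = as.integer(n_min), n_max = as.integer(n_max),
                 lattice_length = as.integer(lattice_length),
                 eps_hh = eps_hh, eps_penalty = eps_penalty,
                 eps_penalty_sweep = eps_penalty_sweep,
                 threshold = threshold, table = table,
                 table_spec = table_spec, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order and returns a report
#' bundle: the topology classification with its frustration grid and edge
#' statistics, the OFHT table with fold categories and the
#' superfold-versus-reverse pair report, the lattice annotations,
#' designability scan and grid, the optional penalty sweep, and a manifest
#' of headline counts and parameters.
#'
#' @param config A [run_config()].
#' @param stages Subset of `c("topologies", "ofht", "lattice", "sweep")`.
#' @param out_dir Optional directory; when given, TSV tables and a JSON
#'   manifest are written into it.
#' @param verbose Log stage progress to stderr.
#' @return List of class `report_bundle`.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("topologies", "ofht", "lattice"),
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, c("topologies", "ofht", "lattice", "sweep"),
                      several.ok = TRUE)
  say <- function(...) if (verbose) message("[frustfree] ", ...)
  bundle <- list(config = config)
  manifest <- list(
    n_min = config$n_min, n_max = config$n_max,
    lattice_length = config$lattice_length,
    eps_hh = config$eps_hh, eps_penalty = config$eps_penalty,
    threshold = config$threshold, seed = config$seed, stages = stages)

  need_topologies <- length(intersect(stages, c("topologies", "ofht"))) > 0L
  if (need_topologies) {
    say("enumerating topologies ", config$n_min, "-", config$n_max)
    topologies <- enumerate_topologies(config$n_min, config$n_max)
    cls <- classify_topologies(topologies)
    summary_cf <- summarize_topology_set(cls, clash_free_only = TRUE)
    bundle$topology <- list(classification = cls, clash_free = summary_cf)
    manifest$n_topologies <- nrow(cls)
    manifest$n_clash_free <- sum(cls$clash_free)
    manifest$n_frustration_free <- length(summary_cf$frustration_free)
    manifest$reverse_asymmetric_pairs <- summary_cf$pair_count
    manifest$edge_percent <- as.list(summary_cf$edge_percent)
  }

  if ("ofht" %in% stages) {
    say("computing OFHT")
    table <- config$table
    if (is.null(table)) table <- generate_ecod_like_table(config$table_spec)
    universe <- Filter(is_clash_free, topologies)
    ofht <- compute_ofht(table)
    cats <- categorize_folds(ofht, universe)
    pairs <- reverse_pair_report(ofht, universe)
    bundle$ofht <- list(table = table, ofht = ofht, categories = cats,
                        reverse_pairs = pairs)
    manifest$n_h_groups <- attr(ofht, "n_h_groups")
    manifest$fold_counts <- as.list(cats$counts)
  }

  if (length(intersect(stages, c("lattice", "sweep")))) {
    say("enumerating walks of length ", config$lattice_length)
    saws <- enumerate_saws(config$lattice_length)
    motifs <- lattice_motifs()
    ann <- annotate_saws(saws, motifs)
    manifest$n_conformations <- saws$n
  }

  if ("lattice" %in% stages) {
    say("designability scan at eps_penalty = ", config$eps_penalty)
    params <- energy_params(config$eps_hh, config$eps_penalty)
    scan <- designability_scan(saws, params, motifs, annotations = ann)
    grid <- grid_summary(ann, scan, saws, threshold = config$threshold)
    bundle$lattice <- list(saws = saws, annotations = ann, scan = scan,
                           grid = grid)
    manifest$protein_like_count <- scan$protein_like_count
    manifest$max_n_s <- max(scan$n_s)
    manifest$n_highly_designable <- sum(scan$n_s >= config$threshold)
  }

  if ("sweep" %in% stages) {
    bundle$sweep <- lapply(config$eps_penalty_sweep, function(ep) {
      say("sweep: eps_penalty = ", ep)
      params <- energy_params(config$eps_hh, ep)
      scan <- designability_scan(saws, params, motifs, annotations = ann)
      list(eps_penalty = ep, scan = scan,
           grid = grid_summary(ann, scan, saws, threshold = config$threshold))
    })
    manifest$sweep_eps_penalty <- config$eps_penalty_sweep
  }

  bundle$manifest <- manifest
  class(bundle) <- "report_bundle"
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  m <- x$manifest
  cat("frustfree report bundle\n")
  if (!is.null(m$n_topologies))
    cat("  topologies: ", m$n_topologies, " (", m$n_clash_free,
        " clash-free, ", m$n_frustration_free, " frustration-free)\n", sep = "")
  if (!is.null(m$n_conformations))
    cat("  lattice: ", m$n_conformations, " conformations\n", sep = "")
  if (!is.null(m$protein_like_count))
    cat("  protein-like sequences: ", m$protein_like_count,
        ", max N_s = ", m$max_n_s, "\n", sep = "")
  invisible(x)
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$topology))
    write_topology_table(bundle$topology$classification,
                         file.path(out_dir, "topologies.tsv"))
  if (!is.null(bundle$ofht)) {
    write_ecod_table(bundle$ofht$table, file.path(out_dir, "ecod_like_table.tsv"))
    utils::write.table(bundle$ofht$ofht, file.path(out_dir, "ofht.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bundle$ofht$reverse_pairs,
                       file.path(out_dir, "ofht_reverse_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$lattice)) {
    ann <- bundle$lattice$annotations
    ann$n_s <- bundle$lattice$scan$n_s
    utils::write.table(cbind(structure_id = seq_len(nrow(ann)), ann),
                       file.path(out_dir, "lattice_structures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
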