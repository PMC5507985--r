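# Orchestration: simulate -> analyze -> report, with file outputs and a run
# manifest so identical inputs + seed reproduce identical results.

sim_file_names <- c(
  timecourse_expression = "timecourse_expression.tsv",
  timecourse_meta = "timecourse_samples.tsv",
  control_expression = "control_expression.tsv",
  control_meta = "control_samples.tsv",
  annotation = "annotation.tsv",
  truth = "truth.tsv",
  transcripts = "transcripts.fasta"
)

#' Read a simulation scenario file
#'
#' A scenario is a flat YAML mapping whose keys are
#' \code{\link{sim_config}} arguments; unknown keys are an error naming the
#' key.
#'
#' @param path YAML file.
#' @return A \code{sim_config}.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) fail("unknown scenario key(s): %s", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

run_manifest <- function(seed, config, inputs = character(0), outputs = character(0)) {
  digest <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
  }
  list(tool = "mirdeg",
       version = as.character(utils::packageVersion("mirdeg")),
       seed = seed,
       config = unclass(config),
       input_digests = digest(inputs),
       outputs = digest(outputs))
}

#' Simulate a full degradation study to disk
#'
#' Draws one shared ground truth and writes the time-course experiment
#' (48 samples), the control experiment (24 samples), the annotation and
#' truth tables, a transcript set with the artifact-class mature sequences
#' planted as exact substrings, and a run manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param scenario A \code{\link{sim_config}} or the path of a YAML scenario
#'   file.
#' @param decay_models Decay models for the time course.
#' @param seed Seed override; defaults to the scenario's seed.
#' @return Named character vector of the written file paths, invisibly.
#' @export
pipeline_simulate <- function(out_dir, scenario = sim_config(),
                              decay_models = default_decay_models(),
                              seed = NULL) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  if (!inherits(scenario, "sim_config")) fail("scenario must be a sim_config or a YAML path")
  seed <- as.integer(seed %||% scenario$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) fail("cannot create output directory: %s", out_dir)
  truth <- simulate_truth(scenario, seed = seed)
  tc <- simulate_timecourse(scenario, decay_models, truth = truth, seed = seed)
  ctrl <- simulate_control_experiment(scenario, truth = truth, seed = seed)
  tx <- simulate_transcripts(tc$annotation,
                             embed_ids = truth$mirna_id[truth$klass == "artifact"],
                             seed = seed + 7L)
  paths <- file.path(out_dir, sim_file_names)
  names(paths) <- names(sim_file_names)
  write_expression_matrix(tc$expression, paths["timecourse_expression"])
  write_sample_metadata(tc$meta, paths["timecourse_meta"])
  write_expression_matrix(ctrl$expression, paths["control_expression"])
  write_sample_metadata(ctrl$meta, paths["control_meta"])
  write_mirbase_annotation(tc$annotation, paths["annotation"])
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_transcripts(tx, paths["transcripts"])
  all_out <- c(paths, paste0(paths[c("timecourse_expression", "control_expression")],
                             ".flags"))
  manifest <- run_manifest(seed, scenario, outputs = all_out)
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(paths)
}

#' Run the full degradation-bias analysis
#'
#' Reads the experiment files (layout as written by
#' \code{\link{pipeline_simulate}}), then runs normalization, detection
#' filtering, the RIN and storage-time correlation screens, liver high- vs
#' low-integrity differential expression, sample and miRNA clustering, the
#' evidence-based classification and (when transcripts are present) the
#' homology screen. Writes one TSV per stage plus \code{summary.json} and a
#' manifest.
#'
#' @param in_dir Directory holding the input files.
#' @param out_dir Output directory.
#' @param cfg An \code{\link{analysis_config}}.
#' @return The summary list, invisibly.
#' @export
pipeline_analyze <- function(in_dir, out_dir, cfg = analysis_config()) {
  paths <- file.path(in_dir, sim_file_names)
  names(paths) <- names(sim_file_names)
  need <- c("timecourse_expression", "timecourse_meta",
            "control_expression", "control_meta", "annotation")
  miss <- need[!file.exists(paths[need])]
  if (length(miss)) fail("missing input file(s): %s", paste(sim_file_names[miss], collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tc <- read_expression_matrix(paths["timecourse_expression"])
  tc_meta <- read_sample_metadata(paths["timecourse_meta"])
  ctrl <- read_expression_matrix(paths["control_expression"])
  ctrl_meta <- read_sample_metadata(paths["control_meta"])
  ann <- read_mirbase_annotation(paths["annotation"])

  # explicit quality exclusions only
  keep <- !colnames(tc$values) %in% cfg$exclude_samples
  tc <- tc[, keep]
  tc_meta <- tc_meta[tc_meta$sample_id %in% colnames(tc$values), ]

  tc_norm <- detection_filter(glog_normalize(tc, calibrate = cfg$calibrate_timecourse),
                              cfg$min_detect_samples)
  ctrl_norm <- detection_filter(glog_normalize(ctrl, calibrate = cfg$calibrate_control),
                                cfg$min_detect_samples)

  screens <- lapply(c("rin", "time_4C", "time_RT"), function(cv) {
    correlation_screen(tc_norm, tc_meta, cv, cfg)
  })
  names(screens) <- c("rin", "time_4C", "time_RT")

  liver <- tc_meta$sample_id[tc_meta$tissue == "liver"]
  de <- differential_expression(tc_norm[, colnames(tc_norm$values) %in% liver],
                                tc_meta, cfg$rin_cutoff, cfg$fold_change,
                                cfg$alpha, cfg$de_center)

  era_counts <- detected_counts_by_era(tc_norm, ann, cfg$era_bins,
                                       samples = liver)

  sample_dend <- complete_linkage(euclidean_distances(tc_norm, "samples"))
  mirna_dend <- complete_linkage(euclidean_distances(ctrl_norm, "mirnas"))
  clusters <- cut_tree(mirna_dend, cfg$n_clusters)
  cl_summary <- cluster_version_summary(clusters, ann)

  evidence <- build_evidence(ctrl_norm, ctrl_meta, timecourse = tc_norm)
  classification <- classify_mirnas(evidence, cfg$fold_change, annotation = ann)
  vbias <- version_bias_summary(classification, cfg$era_bins)

  homology <- NULL
  if (file.exists(paths["transcripts"])) {
    hom_ann <- ann[ann$mirna_id %in% classification$mirna_id, ]
    homology <- homology_screen(hom_ann, read_transcripts(paths["transcripts"]),
                                cfg$homology_min_frac, cfg$homology_max_mismatch)
  }

  # stage outputs
  out <- function(f) file.path(out_dir, f)
  for (cv in names(screens)) {
    utils::write.table(screens[[cv]], out(sprintf("correlation_%s.tsv", cv)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(de, out("de_liver.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(era = rownames(era_counts), era_counts,
                                check.names = FALSE),
                     out("detected_by_era.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dendrogram_newick(sample_dend, out("sample_dendrogram.nwk"))
  utils::write.table(data.frame(mirna_id = names(clusters), cluster = clusters),
                     out("mirna_clusters.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cl_summary$table, out("cluster_version_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(classification), out("classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(homology)) {
    utils::write.table(homology$hits, out("homology_hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(mirna_id = names(homology$flags),
                                  flagged = homology$flags),
                       out("homology_flags.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  summary <- analysis_summary(tc, tc_norm, screens, de, era_counts, clusters,
                              classification, homology)
  write_json_file(summary, out("summary.json"))
  manifest <- run_manifest(cfg$seed, cfg,
                           inputs = c(paths, paste0(paths["timecourse_expression"], ".flags"),
                                      paste0(paths["control_expression"], ".flags")),
                           outputs = list.files(out_dir, full.names = TRUE))
  write_json_file(manifest, out("manifest.json"))
  invisible(summary)
}

analysis_summary <- function(tc_raw, tc_norm, screens, de, era_counts,
                             clusters, classification, homology) {
  screen_counts <- lapply(screens, function(s) {
    list(n_significant = sum(s$call != "ns"),
         n_positive = sum(s$call == "positive"),
         n_negative = sum(s$call == "negative"))
  })
  label_counts <- as.list(table(factor(classification$label, levels = mirna_labels)))
  hom <- if (is.null(homology)) NULL else {
    fr <- group_homology_fraction(
      homology$flags,
      stats::setNames(classification$label, classification$mirna_id))
    list(n_flagged = sum(homology$flags), fraction_by_label = as.list(fr))
  }
  list(
    n_mirnas_input = nrow(tc_raw$values),
    n_mirnas_filtered = nrow(tc_norm$values),
    correlation = screen_counts,
    differential_expression = list(
      n_significant = sum(de$significant),
      n_up_in_low = sum(de$significant & de$log2fc > 0),
      n_down_in_low = sum(de$significant & de$log2fc < 0)),
    detected_by_era = list(eras = rownames(era_counts),
                           samples = colnames(era_counts),
                           counts = unname(apply(era_counts, 2, as.list))),
    cluster_sizes = as.list(table(clusters)),
    classification = label_counts,
    homology = hom
  )
}

#' Assemble a human-readable analysis report
#'
#' Renders a markdown report from the files an analysis run wrote. Stages
#' whose outputs are missing are marked "not run" and the returned status is
#' \code{"partial"}.
#'
#' @param out_dir Directory holding analysis outputs.
#' @param path Report path (default \code{<out_dir>/report.md}).
#' @return List with \code{status} ("ok" or "partial") and \code{path}.
#' @export
pipeline_report <- function(out_dir, path = file.path(out_dir, "report.md")) {
  sfile <- file.path(out_dir, "summary.json")
  if (!file.exists(sfile)) fail("no summary.json in %s; run pipeline_analyze first", out_dir)
  s <- jsonlite::read_json(sfile)
  lines <- c("# Degradation-bias analysis report", "")
  partial <- FALSE
  section <- function(title, body) c(sprintf("## %s", title), "", body, "")
  tsv_table <- function(f, max_rows = 10L) {
    d <- utils::read.delim(file.path(out_dir, f), check.names = FALSE)
    d <- utils::head(d, max_rows)
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) signif(x, 4))
    c(paste(names(d), collapse = " | "),
      paste(rep("---", ncol(d)), collapse = " | "),
      apply(d, 1, paste, collapse = " | "))
  }
  lines <- c(lines, section("Preprocessing", c(
    sprintf("- miRNAs on array: %d", s$n_mirnas_input),
    sprintf("- miRNAs after detection filter: %d", s$n_mirnas_filtered))))
  corr_body <- unlist(lapply(names(s$correlation), function(cv) {
    cc <- s$correlation[[cv]]
    sprintf("- %s: %d significant (%d positive, %d negative)", cv,
            cc$n_significant, cc$n_positive, cc$n_negative)
  }))
  lines <- c(lines, section("Correlation screens", corr_body))
  de <- s$differential_expression
  lines <- c(lines, section("Differential expression (liver, high vs low RIN)", c(
    sprintf("- significant: %d (%d up in low-integrity, %d down)",
            de$n_significant, de$n_up_in_low, de$n_down_in_low),
    "", tsv_table("de_liver.tsv"))))
  lines <- c(lines, section("Detected miRNAs by annotation era", tsv_table("detected_by_era.tsv", 4L)))
  lines <- c(lines, section("Clustering", c(
    sprintf("- miRNA cluster sizes (control experiment): %s",
            paste(sprintf("%s:%s", names(s$cluster_sizes), unlist(s$cluster_sizes)),
                  collapse = ", ")),
    "", tsv_table("cluster_version_summary.tsv"))))
  lines <- c(lines, section("Classification", sprintf("- %s: %s",
    names(s$classification), unlist(s$classification))))
  if (is.null(s$homology)) {
    partial <- TRUE
    lines <- c(lines, section("Homology screen", "not run"))
  } else {
    lines <- c(lines, section("Homology screen", c(
      sprintf("- miRNAs with transcript homology: %d", s$homology$n_flagged),
      sprintf("- fraction by label: %s",
              paste(sprintf("%s=%.3g", names(s$homology$fraction_by_label),
                            as.numeric(unlist(s$homology$fraction_by_label))),
                    collapse = ", ")))))
  }
  writeLines(lines, path)
  list(status = if (partial) "partial" else "ok", path = path)
}
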