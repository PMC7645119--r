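#' Run configuration for the pipeline commands
#'
#' All published thresholds are defaults here, never hard-coded downstream:
#' 0.9 clustering identity, bit-score cutoffs 50 (screen) and 300
#' (shortlist), top-25 percent coverage, 6 folds, 100 CV iterations.
#'
#' @param task `"temperature"` or `"pH"`.
#' @param descriptor_config A [descriptor_config()].
#' @param ensemble_config An [ensemble_config()].
#' @param cluster_identity Greedy-clustering identity threshold.
#' @param selection_k,alpha Feature-selection settings.
#' @param smote_k SMOTE neighbour count.
#' @param folds,iterations Cross-validation settings.
#' @param alignment_params An [alignment_params()].
#' @param bit_cutoff,bit_floor,coverage_quantile Screening thresholds.
#' @param seed Master seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(task = "temperature",
                       descriptor_config = cellopt::descriptor_config(),
                       ensemble_config = cellopt::ensemble_config(),
                       cluster_identity = 0.9, selection_k = "auto",
                       alpha = 0.05, smote_k = 5L, folds = 6L,
                       iterations = 100L,
                       alignment_params = cellopt::alignment_params(),
                       bit_cutoff = 50, bit_floor = 300,
                       coverage_quantile = 0.75, seed = 1L) {
  stopifnot(task %in% c("temperature", "pH"),
            cluster_identity > 0, cluster_identity <= 1,
            folds >= 2L, iterations >= 1L, smote_k >= 1L,
            bit_cutoff >= 0, bit_floor >= 0,
            coverage_quantile > 0, coverage_quantile <= 1)
  structure(list(task = task, descriptor_config = descriptor_config,
                 ensemble_config = ensemble_config,
                 cluster_identity = cluster_identity,
                 selection_k = selection_k, alpha = alpha,
                 smote_k = smote_k, folds = folds, iterations = iterations,
                 alignment_params = alignment_params,
                 bit_cutoff = bit_cutoff, bit_floor = bit_floor,
                 coverage_quantile = coverage_quantile, seed = seed),
            class = "run_config")
}

#' Read a label table (TSV: id, t_opt, ph_opt; blanks allowed)
#'
#' @param path TSV path.
#' @return `data.frame` with `id` and numeric `t_opt`, `ph_opt` (NA where
#'   blank).
#' @export
read_label_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(tab)) stop("label table needs an 'id' column")
  for (col in c("t_opt", "ph_opt"))
    if (col %in% names(tab)) tab[[col]] <- as.numeric(tab[[col]])
  tab
}

# Shared training core: records + per-id optima -> fitted bundle.
train_model <- function(records, optima, config) {
  task <- config$task
  records$seq <- clean_sequence(setNames(records$seq, records$id))
  reps <- greedy_cluster(records, config$cluster_identity)
  col <- if (task == "temperature") "t_opt" else "ph_opt"
  if (!col %in% names(optima)) stop("label table lacks column ", col)
  vals <- optima[[col]][match(reps$id, optima$id)]
  keep <- !is.na(vals)
  if (!any(keep)) stop("no records with a reported optimum for task ", task)
  reps <- reps[keep, , drop = FALSE]
  vals <- vals[keep]
  labels <- if (task == "temperature") label_temperature(vals)
            else label_ph(vals)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("fewer than 2 classes present")

  fm <- featurize(reps, config$descriptor_config)
  fm <- drop_duplicate_columns(fm)
  columns <- colnames(fm$data)
  scaler <- fit_scaler(fm)
  fm <- apply_scaler(scaler, fm)
  sel <- select_k_best(fm, labels, K = config$selection_k,
                       alpha = config$alpha)
  fm <- apply_selection(sel, fm)
  sm <- smote_resample(fm, labels, k = config$smote_k, seed = config$seed)
  ens <- fit_ensemble(sm$features$data, sm$labels, config$ensemble_config,
                      seed = config$seed)
  model_bundle(task, ens, scaler, sel, columns, config$descriptor_config,
               config$ensemble_config, seed = config$seed)
}

write_manifest <- function(out_dir, command, config, inputs) {
  manifest <- list(command = command,
                   package_version = as.character(
                     utils::packageVersion("cellopt")),
                   seed = config$seed, task = config$task,
                   inputs = lapply(inputs, function(p)
                     list(path = p, md5 = unname(tools::md5sum(p)))),
                   thresholds = list(
                     cluster_identity = config$cluster_identity,
                     selection_k = config$selection_k, alpha = config$alpha,
                     smote_k = config$smote_k, folds = config$folds,
                     iterations = config$iterations,
                     bit_cutoff = config$bit_cutoff,
                     bit_floor = config$bit_floor,
                     coverage_quantile = config$coverage_quantile))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Train a model bundle from a FASTA and a label table
#'
#' Pipeline: clean, greedy-cluster at the configured identity, label,
#' featurize, deduplicate columns, scale, select, SMOTE, fit the ensemble;
#' writes the bundle, its metadata and a run manifest to `out_dir`.
#'
#' @param fasta Protein FASTA path.
#' @param label_table TSV path (`id`, `t_opt`, `ph_opt`).
#' @param out_dir Output directory (created if missing).
#' @param config A [run_config()].
#' @return The fitted `model_bundle`, invisibly; written to
#'   `<out_dir>/bundle_<task>.rds`.
#' @export
cmd_train <- function(fasta, label_table, out_dir,
                      config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_fasta(fasta, "protein")
  optima <- read_label_table(label_table)
  bundle <- train_model(records, optima, config)
  save_bundle(bundle, file.path(out_dir,
                                paste0("bundle_", config$task, ".rds")))
  write_manifest(out_dir, "train", config, c(fasta, label_table))
  invisible(bundle)
}

#' Cross-validate the pipeline on a labeled FASTA
#'
#' @inheritParams cmd_train
#' @return The `cv_report`, invisibly; per-fold TSV and JSON aggregate are
#'   written under `out_dir`.
#' @export
cmd_evaluate <- function(fasta, label_table, out_dir,
                         config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_fasta(fasta, "protein")
  records$seq <- clean_sequence(setNames(records$seq, records$id))
  optima <- read_label_table(label_table)
  col <- if (config$task == "temperature") "t_opt" else "ph_opt"
  vals <- optima[[col]][match(records$id, optima$id)]
  keep <- !is.na(vals)
  records <- records[keep, , drop = FALSE]
  labels <- if (config$task == "temperature")
    label_temperature(vals[keep]) else label_ph(vals[keep])
  report <- repeated_cv(records, labels, config$descriptor_config,
                        config$ensemble_config, folds = config$folds,
                        iterations = config$iterations,
                        base_seed = config$seed,
                        selection_k = config$selection_k,
                        alpha = config$alpha, smote_k = config$smote_k)
  write_cv_report(report, file.path(out_dir,
                                    paste0("cv_", config$task)))
  write_manifest(out_dir, "evaluate", config, c(fasta, label_table))
  invisible(report)
}

#' Predict classes for a protein FASTA with a trained bundle
#'
#' @param fasta Protein FASTA path.
#' @param bundle_path Path to a saved bundle (`.rds`).
#' @param out_tsv Output TSV path.
#' @return The prediction `data.frame`, invisibly.
#' @export
cmd_predict <- function(fasta, bundle_path, out_tsv) {
  if (!file.exists(bundle_path)) stop("bundle not found: ", bundle_path)
  bundle <- load_bundle(bundle_path)
  records <- read_fasta(fasta, "protein")
  records$seq <- clean_sequence(setNames(records$seq, records$id))
  pred <- predict(bundle, records)
  write.table(pred, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pred)
}

#' Screen a contig FASTA against a reference protein FASTA
#'
#' @param contig_fasta,reference_fasta Input FASTA paths.
#' @param out_tsv Output TSV path for the hit table.
#' @param coverage_tsv Optional TSV (`contig_id`, `mapped_reads`); when
#'   given, the shortlist columns are appended.
#' @param config A [run_config()].
#' @return The hit (or candidate) `data.frame`, invisibly.
#' @export
cmd_screen <- function(contig_fasta, reference_fasta, out_tsv,
                       coverage_tsv = NULL, config = run_config()) {
  contigs <- read_fasta(contig_fasta, "nucleotide")
  refs <- read_fasta(reference_fasta, "protein")
  refs$seq <- clean_sequence(setNames(refs$seq, refs$id))
  hits <- screen_contigs(contigs, refs, config$alignment_params,
                         cutoff_bits = config$bit_cutoff)
  if (!is.null(coverage_tsv)) {
    coverage <- read.delim(coverage_tsv, stringsAsFactors = FALSE)
    hits <- shortlist_candidates(hits, coverage,
                                 bit_floor = config$bit_floor,
                                 coverage_quantile = config$coverage_quantile)
  }
  write.table(hits, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(hits)
}

#' Screen contigs and characterize hits with trained bundles
#'
#' @inheritParams cmd_screen
#' @param bundle_T_path,bundle_pH_path Paths to saved bundles.
#' @return The annotated `data.frame`, invisibly.
#' @export
cmd_characterize <- function(contig_fasta, reference_fasta, bundle_T_path,
                             bundle_pH_path, out_tsv,
                             config = run_config()) {
  for (p in c(bundle_T_path, bundle_pH_path))
    if (!file.exists(p)) stop("bundle not found: ", p)
  bundle_T <- load_bundle(bundle_T_path)
  bundle_pH <- load_bundle(bundle_pH_path)
  contigs <- read_fasta(contig_fasta, "nucleotide")
  refs <- read_fasta(reference_fasta, "protein")
  refs$seq <- clean_sequence(setNames(refs$seq, refs$id))
  ann <- characterize(contigs, refs, bundle_T, bundle_pH,
                      config$alignment_params,
                      cutoff_bits = config$bit_cutoff)
  write.table(ann, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ann)
}

#' Write a synthetic labeled dataset and contig set to disk
#'
#' Produces pipeline-ready files: protein FASTA + label TSV for the chosen
#' task, and contig FASTA + truth TSV with genes planted from the generated
#' proteins.
#'
#' @param out_dir Output directory.
#' @param spec A [synthetic_spec()].
#' @param contigs A [contig_spec()] or NULL to skip contig generation.
#' @return Named vector of written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, spec = synthetic_spec(),
                         contigs = contig_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_labeled_dataset(spec)
  paths <- c(proteins = file.path(out_dir, "proteins.fasta"),
             labels = file.path(out_dir, "labels.tsv"))
  write_fasta(ds$records, paths[["proteins"]])
  lab <- data.frame(id = ds$optima$id,
                    t_opt = if (spec$task == "temperature")
                      ds$optima$t_opt else NA,
                    ph_opt = if (spec$task == "pH") ds$optima$ph_opt else NA)
  write.table(lab, paths[["labels"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(contigs)) {
    cg <- generate_contigs(contigs, ds$records)
    paths <- c(paths, contigs = file.path(out_dir, "contigs.fasta"),
               truth = file.path(out_dir, "truth.tsv"))
    write_fasta(cg$contigs, paths[["contigs"]])
    write.table(cg$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
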