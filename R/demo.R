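#' Experiment configuration
#'
#' One nested configuration object covering the whole pipeline (cohort,
#' preprocessing, augmentation, training, evaluation). Round-trips through
#' YAML bit-exactly via [write_experiment_config()] /
#' [read_experiment_config()]; every run writes its resolved copy next to
#' its artifacts.
#'
#' @param n_patients,exams_per_patient,vendor_policy,split,followup_fraction
#'   Cohort settings, see [cohort_spec()].
#' @param epochs,batch_size,sam_rho,embed_dim,head_hidden,deploy_head
#'   Training settings, see [train_config()].
#' @param augment Logical: apply the training augmentation pipeline.
#' @param transversal_factor,transversal_prob RandomTransversalScaling
#'   settings, see [augment_config()].
#' @param ks Rank cutoffs for the evaluation report.
#' @param master_seed Integer master seed for every stage.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_patients = 60, exams_per_patient = 3,
                              vendor_policy = "random",
                              split = c(train = 0.5, test = 0.5),
                              followup_fraction = 1, epochs = 30,
                              batch_size = 20, sam_rho = 0, embed_dim = 32,
                              head_hidden = 64, deploy_head = TRUE,
                              augment = TRUE, transversal_factor = 1.04,
                              transversal_prob = 0.25, ks = c(1, 10),
                              master_seed = 1) {
  structure(as.list(environment()), class = "experiment_config")
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @param path YAML file path.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$split <- as.list(x$split)   # keep names through YAML
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(experiment_config, list())
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (nm == "split") v <- unlist(v)
    cfg[[nm]] <- v
  }
  cfg
}

as_cohort_spec <- function(cfg) {
  cohort_spec(n_patients = cfg$n_patients,
              exams_per_patient = cfg$exams_per_patient,
              vendor_policy = cfg$vendor_policy, split = cfg$split,
              followup_fraction = cfg$followup_fraction,
              master_seed = cfg$master_seed)
}

as_train_config <- function(cfg) {
  train_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
               sam_rho = cfg$sam_rho, embed_dim = cfg$embed_dim,
               head_hidden = cfg$head_hidden, deploy_head = cfg$deploy_head,
               augment = if (isTRUE(cfg$augment))
                 augment_config(transversal_factor = cfg$transversal_factor,
                                transversal_prob = cfg$transversal_prob)
               else NULL,
               track_history = 5, seed = cfg$master_seed)
}

#' Evaluate a trained extractor on a dataset's test split
#'
#' Enrolls the baseline image of every test patient as the gallery,
#' extracts follow-up embeddings as queries, and runs the stratified
#' evaluation protocol.
#'
#' @param model A trained `reid_extractor`.
#' @param dataset A [prepare_reid_dataset()] object.
#' @param ks Rank cutoffs.
#' @return An `eval_report`.
#' @export
evaluate_extractor <- function(model, dataset, ks = c(1, 10)) {
  te <- dataset$test
  bi <- which(te$roles == "baseline")
  qi <- which(te$roles == "follow-up")
  if (!length(bi) || !length(qi))
    stop("test split needs baseline and follow-up images")
  G <- extract_embeddings(model, te$x[bi])
  Q <- extract_embeddings(model, te$x[qi])
  gal <- build_gallery(G, te$labels[bi], te$vendors[bi])
  S <- cosine_similarity_matrix(Q, gal)
  stratified_eval(S, te$labels[qi], gal$patient_ids, te$vendors[qi],
                  gal$vendors, ks = ks)
}

#' Run the full demonstration pipeline
#'
#' Generate a phantom cohort, preprocess it, train the extractor, enroll
#' baselines, match follow-ups and evaluate — the complete three-step
#' re-identification workflow at desk scale. Every artifact is
#' reproducible from `(config, master_seed)`. When `out_dir` is given,
#' writes the manifest (CSV), the resolved configuration (YAML), the
#' training history and CMC curve (CSV), the evaluation report (JSON) and
#' the model checkpoint (RDS).
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory, or `NULL` for no artifacts.
#' @param cohort Optional pre-generated cohort (to share renders between
#'   paired runs).
#' @param quiet Suppress progress messages.
#' @return List with `model`, `report`, `dataset`, `manifest`, `config`.
#' @export
run_demo <- function(config = experiment_config(), out_dir = NULL,
                     cohort = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- "generate"
  res <- tryCatch({
    if (is.null(cohort)) {
      say("[generate] rendering phantom cohort (n=", config$n_patients, ")")
      cohort <- generate_cohort(as_cohort_spec(config))
    }
    stage <- "preprocess"
    say("[preprocess] resample / crop / 8-bit")
    ds <- prepare_reid_dataset(cohort)
    stage <- "train"
    say("[train] ", config$epochs, " epochs on ",
        length(ds$train$x), " images")
    model <- train_extractor(ds, desk_backbone(), as_train_config(config))
    stage <- "evaluate"
    say("[evaluate] gallery matching + stratified report")
    report <- evaluate_extractor(model, ds, ks = config$ks)
    list(model = model, report = report, dataset = ds,
         manifest = cohort$manifest, config = config)
  }, error = function(e) {
    stop("demo failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    write_experiment_config(config, file.path(out_dir, "config.yaml"))
    utils::write.csv(res$model$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(K = seq_along(res$report$cmc),
                                accuracy = res$report$cmc),
                     file.path(out_dir, "cmc.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(overall = as.list(res$report$overall),
           groups = as.data.frame(res$report$groups),
           cells = as.data.frame(res$report$cells),
           scores = res$report$scores, note = res$report$note),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    saveRDS(res$model, file.path(out_dir, "checkpoint.rds"))
  }
  res
}

#' Paired augmentation experiment
#'
#' The package's core comparison: train the extractor with and without the
#' RandomTransversalScaling layer on the same phantom cohort(s) and report
#' the stratified accuracies side by side, one row per (seed, condition).
#' The other augmentation layers (perspective, rotation, center crop)
#' remain active in both arms — the contrast isolates the width-scaling
#' layer, mirroring a factor sweep where factor 1.0 means no scaling.
#' Renders are shared between the paired runs, so the two conditions see
#' identical images and differ only in that one augmentation layer.
#'
#' @param seeds Integer vector of master seeds (one cohort per seed).
#' @param config Base [experiment_config()]; its `transversal_prob` field
#'   is overridden per condition (`augment` is forced on in both arms).
#' @param quiet Suppress progress messages.
#' @return data.frame with per-run accuracies (overall, same-vendor,
#'   different-vendor) and impostor-mean history diagnostics, plus the run
#'   list as attribute `"runs"`.
#' @export
augmentation_experiment <- function(seeds = 1:3,
                                    config = experiment_config(),
                                    quiet = FALSE) {
  rows <- list(); runs <- list()
  for (seed in seeds) {
    cfg <- config
    cfg$master_seed <- seed
    cfg$augment <- TRUE
    cohort <- generate_cohort(as_cohort_spec(cfg))
    for (aug in c(TRUE, FALSE)) {
      cfg$transversal_prob <- if (aug) config$transversal_prob else 0
      if (!quiet) message("seed ", seed, ", transversal scaling ", aug)
      r <- run_demo(cfg, cohort = cohort, quiet = TRUE)
      gr <- r$report$groups
      hist <- r$model$history
      rec <- which(!is.na(hist$impostor_mean))
      mid <- rec[which.min(abs(hist$epoch[rec] - cfg$epochs / 3))]
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed, augment = aug,
        acc1_overall = unname(r$report$overall["acc1"]),
        acc1_same = unname(gr["same vendor", "acc1"]),
        acc1_diff = unname(gr["different vendors", "acc1"]),
        n_same = unname(gr["same vendor", "n"]),
        n_diff = unname(gr["different vendors", "n"]),
        impostor_mid = hist$impostor_mean[mid],
        impostor_late = hist$impostor_mean[rec[length(rec)]])
      runs[[paste0("s", seed, "_", if (aug) "aug" else "noaug")]] <- r
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "runs") <- runs
  out
}
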