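#' Run a full pairwise comparison
#'
#' Orchestrates one two-sample analysis end to end: preprocessing (background
#' correction, mean +/- 3 SD outlier rejection, Savitzky-Golay smoothing),
#' restriction to the low- and high-wavenumber windows, ten-fold
#' cross-validated ROC-AUC for all five classifiers, permutation importance
#' for the pooled logistic model, vanilla-gradient saliency for the network,
#' and unsupervised spectral clustering, per region.
#'
#' All randomness derives from one master `seed`: the generator uses the
#' config's own seed, each method's CV partition uses `seed` plus a fixed
#' per-method offset, and the interpretability split and clustering use
#' further fixed offsets.
#'
#' @param data A [spectral_dataset()] or a [synthetic_config()] (generated on
#'   the fly).
#' @param regions Named list of [spectral_region()]s (default LW and HW).
#' @param seed Master seed.
#' @param background_order,sd_multiplier,sg_window,sg_polyorder Preprocessing
#'   controls, see [preprocess()]; set `background_order = NA` for data
#'   already background-corrected.
#' @param folds CV folds (default 10).
#' @param cnn_epochs,cnn_validation_split CNN training controls.
#' @param pooling Named list of [pooling_scheme()]s per region; defaults to
#'   [pooling_lw()]/[pooling_hw()] for regions named LW/HW.
#' @param max_cluster_n Spectra cap for the N x N clustering stage (seeded
#'   stratified subsample above it).
#' @param case Label for the comparison (reports).
#' @param verbose Log stage progress.
#' @return A `comparison_report`: list with `case`, `auc` (data.frame method x
#'   region with mean and SEM), `mcc` (per region), `importance`, `saliency`
#'   summaries, and `metadata`.
#' @export
run_comparison <- function(data, regions = list(LW = region_lw(), HW = region_hw()),
                           seed = 1L,
                           background_order = 3, sd_multiplier = 3,
                           sg_window = 91, sg_polyorder = 3,
                           folds = 10, cnn_epochs = 50,
                           cnn_validation_split = 0.1,
                           pooling = NULL,
                           max_cluster_n = 1000,
                           case = "sample1 vs. sample0",
                           verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (inherits(data, "synthetic_config")) {
    say("generating synthetic dataset (N = %d)", 2L * data$n_per_class)
    data <- generate_dataset(data)
  }
  stopifnot(inherits(data, "spectral_dataset"))
  say("preprocessing %d spectra", nrow(data$intensities))
  prep <- preprocess(data, background_order = background_order,
                     sd_multiplier = sd_multiplier,
                     sg_window = sg_window, sg_polyorder = sg_polyorder)
  ds <- prep$dataset
  say("outlier filter removed %d spectra", length(prep$removed))

  method_seeds <- c(LRA = 101L, L2D = 211L, LRP = 307L, PCA = 401L, CNN = 503L)
  auc_rows <- list()
  fold_aucs <- list()
  mcc_list <- list()
  imp_list <- list()
  sal_list <- list()

  for (rg_name in names(regions)) {
    rg <- regions[[rg_name]]
    dsr <- select_region(ds, rg)
    say("region %s: %d points", rg_name, length(dsr$wavenumbers))
    scheme <- if (!is.null(pooling) && rg_name %in% names(pooling))
      pooling[[rg_name]]
    else if (identical(rg_name, "HW")) pooling_hw() else pooling_lw()
    methods <- list(
      LRA = method_lra(),
      L2D = method_l2d(),
      LRP = method_lrp(scheme),
      PCA = method_pca(),
      CNN = method_cnn(epochs = cnn_epochs,
                       validation_split = cnn_validation_split)
    )
    for (mn in names(methods)) {
      say("  %s: %d-fold CV", mn, folds)
      cv <- cross_validate(dsr, methods[[mn]], k = folds,
                           seed = seed + method_seeds[[mn]])
      auc_rows[[paste(rg_name, mn)]] <-
        data.frame(region = rg_name, method = mn,
                   mean_auc = cv$mean_auc, sem = cv$sem)
      fold_aucs[[rg_name]][[mn]] <- cv$fold_aucs
    }

    # interpretability on a held-out quarter
    set.seed(seed + 601L)
    n <- length(dsr$labels)
    test_idx <- sort(c(sample(which(dsr$labels == 1L),
                              round(sum(dsr$labels == 1L) / 4)),
                       sample(which(dsr$labels == 0L),
                              round(sum(dsr$labels == 0L) / 4))))
    train <- subset_rows(dsr, -test_idx)
    test <- subset_rows(dsr, test_idx)

    lrp_fit <- methods$LRP$fit(train)
    test_feats <- average_pooling(test$intensities, scheme, test$wavenumbers)
    imp <- permutation_importance(
      function(f) predict_logistic(lrp_fit$model, f),
      test_feats, test$labels, n_perm = 30, seed = seed + 701L)
    imp_list[[rg_name]] <- c(imp,
                             list(boundaries = scheme$boundaries))

    say("  CNN saliency (train %d / test %d)", nrow(train$intensities),
        nrow(test$intensities))
    cnn_fit <- methods$CNN$fit(train, seed = seed + 801L)
    sal <- vanilla_gradient_saliency(cnn_fit, test$intensities)
    sal_list[[rg_name]] <- cbind(wavenumber = test$wavenumbers, sal$summary)

    clus_ds <- dsr
    if (n > max_cluster_n) {
      set.seed(seed + 887L)
      keep <- sort(c(sample(which(dsr$labels == 1L), max_cluster_n %/% 2),
                     sample(which(dsr$labels == 0L), max_cluster_n %/% 2)))
      clus_ds <- subset_rows(dsr, keep)
    }
    say("  spectral clustering on %d spectra", length(clus_ds$labels))
    mcc_list[[rg_name]] <- cluster_comparison(clus_ds, seed = seed + 907L)
  }

  auc <- do.call(rbind, auc_rows)
  rownames(auc) <- NULL
  structure(list(case = case, auc = auc,
                 fold_aucs = fold_aucs,
                 mcc = lapply(mcc_list, function(x) x$mcc),
                 clustering = mcc_list,
                 importance = imp_list,
                 saliency = sal_list,
                 metadata = list(seed = seed,
                                 removed_rows = prep$removed,
                                 removed_outliers = length(prep$removed),
                                 stage_order = prep$stages,
                                 folds = folds,
                                 cnn_epochs = cnn_epochs,
                                 n_spectra = nrow(ds$intensities),
                                 timestamp = format(Sys.time()))),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>", x$case, "\n")
  print(make_roc_table(list(x)))
  for (rg in names(x$mcc))
    cat(sprintf("  clustering MCC (%s): %.2f\n", rg, x$mcc[[rg]]))
  invisible(x)
}

#' Tabulate AUC values across comparisons
#'
#' One row per case x region, one column per method, values rounded to two
#' decimals; the layout of a methods-by-regions results table.
#'
#' @param reports List of `comparison_report` objects.
#' @param path Optional path; writes the table as CSV alongside a JSON dump.
#' @return A data.frame.
#' @export
make_roc_table <- function(reports, path = NULL) {
  if (inherits(reports, "comparison_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1)
  rows <- list()
  for (rep in reports) {
    for (rg in unique(rep$auc$region)) {
      sub <- rep$auc[rep$auc$region == rg, ]
      row <- as.data.frame(as.list(round(
        stats::setNames(sub$mean_auc, sub$method), 2)))
      rows[[paste(rep$case, rg)]] <- cbind(
        data.frame(case = rep$case, region = rg), row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    jsonlite::write_json(lapply(reports, report_to_list),
                         sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

report_to_list <- function(rep) {
  list(case = rep$case,
       auc = rep$auc,
       fold_aucs = rep$fold_aucs,
       mcc = rep$mcc,
       metadata = rep$metadata)
}

#' Write a comparison report to disk
#'
#' Emits a human-readable text summary and a structured JSON file.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$auc, file.path(dir, "auc.csv"), row.names = FALSE)
  # sidecar with the row indices the outlier filter discarded
  writeLines(as.character(report$metadata$removed_rows),
             file.path(dir, "removed_outliers.txt"))
  for (rg in names(report$saliency))
    utils::write.csv(report$saliency[[rg]],
                     file.path(dir, paste0("saliency_", rg, ".csv")),
                     row.names = FALSE)
  txt <- c(paste("Comparison:", report$case),
           utils::capture.output(print(make_roc_table(list(report)))),
           sprintf("clustering MCC %s: %.3f", names(report$mcc),
                   unlist(report$mcc)),
           sprintf("outliers removed: %d", report$metadata$removed_outliers),
           sprintf("stage order: %s",
                   paste(report$metadata$stage_order, collapse = " -> ")))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
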