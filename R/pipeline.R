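#' Configuration for an end-to-end pipeline run
#'
#' Bundles the per-stage configurations with the cohort settings and a
#' single global seed that is propagated (via stage-tagged derivation) to
#' every stochastic stage.
#'
#' @param fixture a [fixture_config()] describing the synthetic cohort (or
#'   the grid/timing of user-supplied data).
#' @param n_subjects cohort size.
#' @param class_balance proportion of class-1 subjects.
#' @param functional_effect functional class signal passed to [make_cohort()].
#' @param n_affected_rois number of designated discriminative regions passed
#'   to [make_cohort()].
#' @param summary a [summary_config()].
#' @param radiomics a [radiomics_config()].
#' @param cnn_dense_units,cnn_blocks,cnn_first_filters,cnn_epochs,cnn_learning_rate
#'   CNN architecture/training settings (the input shape is derived from the
#'   data at run time).
#' @param gcn a [gcn_config()].
#' @param selection_k number of Fisher-selected features (default 2000,
#'   capped at the available feature count).
#' @param embedding_dim stacked-autoencoder embedding width (default 150).
#' @param sae_hidden_sizes optional explicit SAE layer widths (overrides the
#'   default halving interpolation ending at `embedding_dim`).
#' @param sae_epochs pretrain/fine-tune epochs for the SAE.
#' @param train_fraction stratified train split fraction (default 0.8).
#' @param seed global seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fixture = fixture_config(),
                       n_subjects = 40L,
                       class_balance = 0.5,
                       functional_effect = 1,
                       n_affected_rois = 10L,
                       summary = summary_config(),
                       radiomics = radiomics_config(),
                       cnn_dense_units = 1024L,
                       cnn_blocks = 4L,
                       cnn_first_filters = 16L,
                       cnn_epochs = 30L,
                       cnn_learning_rate = 1e-3,
                       gcn = gcn_config(),
                       selection_k = 2000L,
                       embedding_dim = 150L,
                       sae_hidden_sizes = NULL,
                       sae_epochs = 100L,
                       train_fraction = 0.8,
                       seed = 1L) {
  assert_that(train_fraction > 0 && train_fraction < 1, "train_fraction must be in (0,1)")
  structure(list(fixture = fixture, n_subjects = as.integer(n_subjects),
                 class_balance = class_balance,
                 functional_effect = functional_effect,
                 n_affected_rois = as.integer(n_affected_rois),
                 summary = summary, radiomics = radiomics,
                 cnn_dense_units = as.integer(cnn_dense_units),
                 cnn_blocks = as.integer(cnn_blocks),
                 cnn_first_filters = as.integer(cnn_first_filters),
                 cnn_epochs = as.integer(cnn_epochs),
                 cnn_learning_rate = cnn_learning_rate,
                 gcn = gcn, selection_k = as.integer(selection_k),
                 embedding_dim = as.integer(embedding_dim),
                 sae_hidden_sizes = sae_hidden_sizes,
                 sae_epochs = as.integer(sae_epochs),
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Interpolate SAE hidden sizes by halving from k down to dim.
default_sae_sizes <- function(k, dim, n_levels = 4L) {
  if (k <= dim) return(rep(dim, n_levels))
  sizes <- round(exp(seq(log(k), log(dim), length.out = n_levels + 1L)))[-1L]
  sizes[n_levels] <- dim
  as.integer(pmax(sizes, 1L))
}

# Stratified train/test split by label, seeded.
stratified_split <- function(labels, train_fraction, seed) {
  n <- length(labels)
  train <- logical(n)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      k <- max(1L, round(length(idx) * train_fraction))
      train[sample(idx, k)] <- TRUE
    }
  })
  list(train = train, test = !train)
}

#' Confusion counts from predicted and true labels
#'
#' Class 1 (ASD) is the positive class.
#'
#' @param predicted,actual integer vectors in \{0, 1\}.
#' @return A list of class `confusion_counts` with tp, fp, tn, fn.
#' @export
confusion_counts <- function(predicted, actual) {
  assert_that(length(predicted) == length(actual), "length mismatch")
  structure(list(tp = sum(predicted == 1 & actual == 1),
                 fp = sum(predicted == 1 & actual == 0),
                 tn = sum(predicted == 0 & actual == 0),
                 fn = sum(predicted == 0 & actual == 1)),
            class = "confusion_counts")
}

#' Classification metrics in percent
#'
#' Standard definitions: accuracy = (TP+TN)/total, sensitivity (recall) =
#' TP/(TP+FN), specificity = TN/(TN+FP), precision = TP/(TP+FP), each
#' multiplied by 100. A metric whose denominator is zero is reported as NA
#' (undefined), never as 0.
#'
#' @param counts a [confusion_counts()] (or list with tp, fp, tn, fn).
#' @return A one-row tibble with accuracy, sensitivity, specificity,
#'   precision (percent; NA where undefined).
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  assert_that(total > 0, "no evaluated nodes")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(accuracy = rate(tp + tn, total),
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 precision = rate(tp, tp + fp))
}

#' Run the full two-stream pipeline on a synthetic cohort
#'
#' Executes the complete workflow: cohort generation; per-subject radiomics
#' (atlas ROIs x wavelet sub-bands x first-order/GLCM features); Fisher
#' ranking and top-k selection (training subjects only); stacked-autoencoder
#' compression (fitted on training subjects, applied to all); sqrt-cosine
#' similarity and row-max-minimum thresholding into a population graph;
#' per-subject summary-derivative stacks; CNN training (training subjects)
#' and encoding of all subjects into node features; GCN fit on the training
#' mask and prediction on the test mask; evaluation metrics; and a
#' provenance manifest recording every intermediate shape and seed.
#'
#' @param config a [run_config()].
#' @param cohort optionally, a pre-built [make_cohort()] result (the fixture
#'   settings in `config` are then ignored for generation).
#' @param randomize_node_features replace the CNN node features with seeded
#'   standard-normal noise (a negative control: accuracy should collapse to
#'   chance).
#' @return An object of class `pipeline_result` with metrics, the graph,
#'   per-subject predictions, stage objects and the manifest.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL,
                         randomize_node_features = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_arg("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  fixture <- config$fixture
  fixture$seed <- derive_seed(config$seed, "fixture")
  cohort <- cohort %||% stage("cohort", make_cohort(
    fixture, n_subjects = config$n_subjects,
    class_balance = config$class_balance,
    n_affected_rois = config$n_affected_rois,
    functional_effect = config$functional_effect))
  labels <- cohort$labels
  ids <- vapply(cohort$subjects, `[[`, "", "id")
  split <- stratified_split(labels, config$train_fraction,
                            derive_seed(config$seed, "split"))

  # --- structural stream: radiomics -> Fisher -> SAE -> similarity graph ----
  rad <- stage("radiomics", radiomics_matrix(cohort, config$radiomics))
  k <- min(config$selection_k, ncol(rad$X))
  ranking <- stage("fisher", fisher_score(rad$X[split$train, , drop = FALSE],
                                          labels[split$train]))
  sel_train <- stage("select", select_top_k(ranking, rad$X[split$train, , drop = FALSE], k))
  X_sel_all <- rad$X[, sel_train$kept, drop = FALSE]
  sae_sizes <- config$sae_hidden_sizes %||% default_sae_sizes(k, config$embedding_dim)
  sae <- stage("sae", sae_fit(sel_train$X, hidden_sizes = sae_sizes,
                              seed = derive_seed(config$seed, "sae"),
                              epochs_pretrain = config$sae_epochs,
                              epochs_finetune = config$sae_epochs))
  emb <- stage("sae_encode", sae_encode(sae, X_sel_all))
  sim <- stage("similarity", similarity_matrix(emb))
  A <- stage("adjacency", threshold_adjacency(sim))

  # --- functional stream: summaries -> stack -> CNN node features ----------
  templates <- stage("templates", make_templates(fixture))
  stacks <- stage("summaries", lapply(cohort$subjects, function(s) {
    compute_all_summaries(s$fmri, templates, config$summary)
  }))
  input_shape <- dim(stacks[[1]]$data)
  cnn_cfg <- cnn_config(input_shape,
                        first_block_filters = config$cnn_first_filters,
                        repeated_blocks = config$cnn_blocks,
                        dense_units = config$cnn_dense_units,
                        seed = derive_seed(config$seed, "cnn"),
                        epochs = config$cnn_epochs,
                        learning_rate = config$cnn_learning_rate)
  cnn <- stage("cnn_build", cnn_build(cnn_cfg))
  cnn <- stage("cnn_train", cnn_train(cnn, stacks[split$train], labels[split$train]))
  feats <- stage("cnn_encode", cnn_encode(cnn, stacks, subject_ids = ids))
  # column-standardize node features before graph convolution (constant
  # columns are left at zero); GCN optimisation is scale-sensitive
  node_features <- unclass(feats)
  sds <- apply(node_features, 2, stats::sd)
  node_features <- sweep(node_features, 2, colMeans(node_features))
  node_features[, sds > 0] <- sweep(node_features[, sds > 0, drop = FALSE],
                                    2, sds[sds > 0], "/")
  if (randomize_node_features) {
    node_features <- with_seed(derive_seed(config$seed, "randomize"), {
      matrix(stats::rnorm(length(node_features)), nrow(node_features),
             ncol(node_features), dimnames = dimnames(node_features))
    })
  }

  # --- population graph + GCN ----------------------------------------------
  graph <- stage("graph", population_graph(node_features, A, labels,
                                           split$train, split$test))
  gcfg <- config$gcn
  gcfg$seed <- derive_seed(config$seed, "gcn_fit")
  fit <- stage("gcn_fit", gcn_fit(graph, gcfg))
  pred <- stage("gcn_predict", gcn_predict(fit, graph))
  test_idx <- which(split$test)
  counts <- confusion_counts(pred$labels[test_idx], labels[test_idx])
  metrics <- classification_metrics(counts)

  predictions <- tibble::tibble(
    subject_id = ids, label = labels,
    split = ifelse(split$train, "train", "test"),
    predicted = pred$labels,
    p_class0 = pred$probs[, 1], p_class1 = pred$probs[, 2])

  manifest <- list(
    seed = config$seed,
    stage_seeds = list(fixture = fixture$seed,
                       split = derive_seed(config$seed, "split"),
                       sae = derive_seed(config$seed, "sae"),
                       cnn = derive_seed(config$seed, "cnn"),
                       gcn = derive_seed(config$seed, "gcn_fit")),
    n_subjects = length(ids),
    grid_shape = fixture$grid_shape,
    n_timepoints = fixture$n_timepoints,
    n_atlas_regions = length(cohort$atlas$region_ids),
    radiomic_features_per_subject = ncol(rad$X),
    selection_k = k,
    sae_hidden_sizes = sae_sizes,
    embedding_dim = ncol(emb),
    similarity_threshold = sim$threshold,
    min_degree = min(rowSums(A)),
    summary_channels = input_shape[4],
    cnn_input_shape = input_shape,
    cnn_feature_width = ncol(node_features),
    n_train = sum(split$train),
    n_test = sum(split$test))

  structure(list(metrics = metrics, counts = counts, graph = graph,
                 predictions = predictions, similarity = sim,
                 fisher = ranking, sae = sae, cnn = cnn, gcn = fit,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects (%d train / %d test)\n",
              x$manifest$n_subjects, x$manifest$n_train, x$manifest$n_test))
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' Glance at a pipeline result
#'
#' @param x a `pipeline_result`.
#' @param ... unused.
#' @return One-row tibble of the test metrics and key widths.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  cbind(x$metrics,
        tibble::tibble(n_test = x$manifest$n_test,
                       selection_k = x$manifest$selection_k,
                       embedding_dim = x$manifest$embedding_dim,
                       cnn_feature_width = x$manifest$cnn_feature_width))
}

#' Tidy a pipeline result
#'
#' @param x a `pipeline_result`.
#' @param ... unused.
#' @return The per-subject prediction tibble.
#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) x$predictions

#' Plot the population graph's similarity structure
#'
#' @param object a `pipeline_result`.
#' @param ... unused.
#' @return A ggplot heat map of the similarity matrix with subjects ordered
#'   by class.
#' @method autoplot pipeline_result
#' @export
autoplot.pipeline_result <- function(object, ...) {
  S <- object$similarity$S
  ord <- order(object$predictions$label)
  S <- S[ord, ord]
  d <- expand.grid(i = seq_len(nrow(S)), j = seq_len(ncol(S)))
  d$similarity <- as.vector(S)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$similarity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "subject (ordered by class)", y = "subject")
}

#' Write a pipeline result bundle to a directory
#'
#' Writes predictions and metrics TSVs, the edge list, and a JSON manifest.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(result$predictions),
                     file.path(dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(result$metrics), file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_edge_list(result$similarity, file.path(dir, "edges.tsv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
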