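#' End-to-end node2vec + GCN pipeline on one chromosome
#'
#' Convenience wrapper chaining [build_graph()], [node2vec_embed()] and
#' [train_gcn()] with the standard hyperparameters. Pre-computed embeddings
#' can be supplied to avoid retraining node2vec when only the labels change
#' (the label-perturbation arms of the robustness suite).
#'
#' @param matrix a [contact_matrix()] or numeric matrix.
#' @param labels per-bin CNV labels.
#' @param seed seed driving the walk generation, skip-gram and GCN training.
#' @param d embedding dimension (default 64).
#' @param embedding optional pre-computed `list(embedding, graph)` as
#'   returned by [node2vec_embed()].
#' @param embed_args named list of extra arguments for [node2vec_embed()].
#' @param ... passed to [train_gcn()] (e.g. `epochs`, `hidden`, `head`).
#' @return the [train_gcn()] fit, with the embedding attached as
#'   `$embedding` and graph as `$graph`.
#' @export
gcn_pipeline <- function(matrix, labels, seed = 1, d = 64, embedding = NULL,
                         embed_args = list(), ...) {
  if (is.null(embedding)) {
    embedding <- do.call(node2vec_embed,
                         c(list(matrix, d = d, seed = seed), embed_args))
  }
  fit <- train_gcn(embedding$graph, embedding$embedding, labels, seed = seed,
                   ...)
  fit$embedding <- embedding$embedding
  fit$graph <- embedding$graph
  fit
}

#' Run the five-way perturbation robustness suite
#'
#' Trains the node2vec + GCN pipeline on an unperturbed baseline and under
#' each of the five perturbations of [apply_perturbation()], repeated over
#' `seeds`, and collects held-out accuracies and perturbation reports.
#' Embeddings are computed once per distinct matrix: the two
#' label-perturbation arms reuse the baseline embedding because the contact
#' matrix — hence the graph — is unchanged.
#'
#' @param matrix a [contact_matrix()].
#' @param labels true per-bin CNV labels.
#' @param seeds integer vector of replicate seeds.
#' @param kinds perturbations to run (default: all five plus the baseline).
#' @param d embedding dimension.
#' @param embed_args named list of extra arguments for [node2vec_embed()]
#'   (e.g. `list(epochs = 2)` for a lighter skip-gram schedule).
#' @param ... passed to [train_gcn()].
#' @return object of class `perturbation_suite`: data.frame `results`
#'   (kind, seed, accuracy, f1_macro, auc_macro, fraction_unchanged) and
#'   `summary` (mean accuracy per kind).
#' @export
run_perturbation_suite <- function(matrix, labels, seeds = 1:5,
                                   kinds = c("none", "label_reconstruction",
                                             "label_shuffle", "row_shuffle",
                                             "value_shuffle", "value_noise"),
                                   d = 64, embed_args = list(), ...) {
  labels <- cnv_labels(labels)
  rows <- list()
  for (seed in seeds) {
    base_emb <- do.call(node2vec_embed,
                        c(list(matrix, d = d, seed = seed), embed_args))
    for (kind in kinds) {
      pert <- apply_perturbation(matrix, labels, kind, seed = seed)
      emb <- if (kind %in% c("none", "label_reconstruction", "label_shuffle")) {
        base_emb
      } else {
        do.call(node2vec_embed,
                c(list(pert$matrix, d = d, seed = seed), embed_args))
      }
      fit <- gcn_pipeline(pert$matrix, pert$labels, seed = seed, d = d,
                          embedding = emb, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, seed = seed,
        accuracy = fit$metrics$accuracy,
        f1_macro = fit$metrics$f1_macro,
        auc_macro = fit$metrics$auc_macro,
        fraction_unchanged = if (is.null(pert$report)) NA_real_ else
          pert$report$fraction_unchanged)
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(accuracy ~ kind, results, mean)
  summary <- summary[match(kinds, summary$kind), ]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary),
            class = "perturbation_suite")
}

#' @export
print.perturbation_suite <- function(x, ...) {
  cat("<perturbation_suite> mean held-out accuracy by perturbation:\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-22s %.4f\n", x$summary$kind[i], x$summary$accuracy[i]))
  }
  invisible(x)
}

experiment_keys <- function() {
  c("task", "out_dir", "seed", "n_bins", "n_segments", "copy_pool",
    "min_len", "max_len", "noise", "base_depth", "decay_exponent",
    "diagonal_boost", "train_fraction", "dim", "hidden", "dropout",
    "gcn_epochs", "lr", "head", "embed_epochs", "linear_epochs", "linear_lr",
    "reduce_method", "perturb_seeds", "matrix_file", "labels_file")
}

#' Read and validate a flat key=value experiment config
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are
#' rejected before any computation.
#'
#' @param path config file path.
#' @return named list of strings (typed lazily by [run_experiment()]).
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop_bad_arg("no such config: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad)) stop_bad_arg("malformed config line: ", bad[1L])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  unknown <- setdiff(keys, experiment_keys())
  if (length(unknown)) {
    stop_bad_arg("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(keys)) stop_bad_arg("duplicate config key")
  if (!"task" %in% keys) stop_bad_arg("config must set `task`")
  stats::setNames(as.list(vals), keys)
}

cfg_num <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
}
cfg_chr <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

## FNV-1a hash of the canonicalised config, for stamping outputs
config_hash <- function(cfg) {
  s <- paste(sort(paste0(names(cfg), "=", unlist(cfg))), collapse = ";")
  ## doubles throughout: bitwXor() is limited to values below 2^31, and the
  ## 32-bit product is kept exact by splitting h into 16-bit halves
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- h %% 65536
    h <- h - lo + bitwXor(lo, b %% 65536)
    h <- ((h %/% 65536 * 16777619) %% 65536 * 65536 +
            h %% 65536 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Run a declarative experiment
#'
#' Executes the pipeline described by a config (see
#' [read_experiment_config()]): simulates a chromosome (or loads matrix and
#' label files), runs the requested task and writes all artifacts — metrics
#' JSON, perturbation reports, loss curves, the truth labels — into
#' `out_dir`, stamped with the package version and a hash of the config.
#' Fully deterministic given the config's seeds.
#'
#' Tasks: `simulate` (write the synthetic data only), `linear` (per-
#' chromosome linear model), `gcn` (node2vec + GCN) and
#' `perturbation_suite` (baseline + five perturbations).
#'
#' @param config path to a config file, or the list from
#'   [read_experiment_config()].
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return the output directory, invisibly; artifacts on disk.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_experiment_config(config) else config
  out <- out_dir %||% cfg_chr(cfg, "out_dir", "cnvhic-out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg_num(cfg, "seed", 1)
  log_path <- file.path(out, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  stamp <- list(package = "cnvhic",
                version = as.character(utils::packageVersion("cnvhic")),
                config_hash = config_hash(cfg), config = cfg)
  jsonlite::write_json(stamp, file.path(out, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  task <- cfg_chr(cfg, "task", NULL)
  logf("task=%s hash=%s", task, stamp$config_hash)

  ## inputs: either load from files or simulate
  if (!is.null(cfg$matrix_file)) {
    mat <- read_contact_matrix(cfg$matrix_file, format = "dense")
    labels <- read_cnv_labels(cfg$labels_file)$labels
  } else {
    sim <- simulate_chromosome(
      n_bins = cfg_num(cfg, "n_bins", 1000),
      n_segments = cfg_num(cfg, "n_segments", 10),
      copy_number_pool = as.numeric(strsplit(
        cfg_chr(cfg, "copy_pool", "1,2,3,4"), ",")[[1]]),
      min_len = cfg_num(cfg, "min_len", 20),
      max_len = cfg_num(cfg, "max_len", 50),
      seed = seed,
      noise_model = cfg_chr(cfg, "noise", "poisson"),
      base_depth = cfg_num(cfg, "base_depth", 100),
      decay_exponent = cfg_num(cfg, "decay_exponent", 1),
      diagonal_boost = cfg_num(cfg, "diagonal_boost", 5))
    mat <- sim$matrix
    labels <- sim$labels
    write_contact_matrix(mat, file.path(out, "matrix.tsv"))
    write_cnv_labels(labels, file.path(out, "labels.bed"),
                     copy_number = sim$copy_number)
    logf("simulated %d bins, %d segments", mat$n_bins,
         nrow(sim$segments$segments))
  }
  if (task == "simulate") return(invisible(out))

  if (task == "linear") {
    fit <- fit_linear_cnv(mat, labels,
                          train_fraction = cfg_num(cfg, "train_fraction", 0.6),
                          seed = seed,
                          epochs = cfg_num(cfg, "linear_epochs", 500),
                          lr = cfg_num(cfg, "linear_lr", 0.1))
    write_metrics_json(fit$metrics, file.path(out, "metrics.json"))
    write_linear_model(fit, file.path(out, "linear_model.json"))
    utils::write.table(data.frame(epoch = seq_along(fit$loss), loss = fit$loss),
                       file.path(out, "loss.tsv"), sep = "\t",
                       row.names = FALSE)
    logf("linear accuracy %.4f", fit$metrics$accuracy)
  } else if (task == "gcn") {
    fit <- gcn_pipeline(mat, labels, seed = seed,
                        d = cfg_num(cfg, "dim", 64),
                        embed_args = list(epochs = cfg_num(cfg, "embed_epochs", 5)),
                        train_fraction = cfg_num(cfg, "train_fraction", 0.6),
                        hidden = cfg_num(cfg, "hidden", 64),
                        dropout = cfg_num(cfg, "dropout", 0.5),
                        epochs = cfg_num(cfg, "gcn_epochs", 150),
                        lr = cfg_num(cfg, "lr", 0.01),
                        head = cfg_chr(cfg, "head", "sigmoid"))
    write_metrics_json(fit$metrics, file.path(out, "metrics.json"))
    write_embedding(fit$embedding, file.path(out, "embedding.tsv"))
    utils::write.table(data.frame(epoch = seq_along(fit$loss), loss = fit$loss),
                       file.path(out, "loss.tsv"), sep = "\t",
                       row.names = FALSE)
    logf("gcn accuracy %.4f", fit$metrics$accuracy)
  } else if (task == "perturbation_suite") {
    seeds <- as.numeric(strsplit(cfg_chr(cfg, "perturb_seeds",
                                         as.character(seed)), ",")[[1]])
    suite <- run_perturbation_suite(
      mat, labels, seeds = seeds, d = cfg_num(cfg, "dim", 64),
      embed_args = list(epochs = cfg_num(cfg, "embed_epochs", 5)),
      train_fraction = cfg_num(cfg, "train_fraction", 0.6),
      hidden = cfg_num(cfg, "hidden", 64),
      dropout = cfg_num(cfg, "dropout", 0.5),
      epochs = cfg_num(cfg, "gcn_epochs", 150),
      lr = cfg_num(cfg, "lr", 0.01))
    utils::write.table(suite$results, file.path(out, "perturbation_results.tsv"),
                       sep = "\t", row.names = FALSE)
    jsonlite::write_json(suite$summary, file.path(out, "perturbation_summary.json"),
                         digits = NA, dataframe = "rows")
    for (k in unique(suite$results$kind)) {
      sub <- suite$results[suite$results$kind == k, ]
      jsonlite::write_json(
        list(kind = k, mean_accuracy = mean(sub$accuracy),
             fraction_unchanged = sub$fraction_unchanged,
             seeds = sub$seed),
        file.path(out, paste0("report_", k, ".json")),
        digits = NA, auto_unbox = TRUE, na = "null")
    }
    logf("perturbation suite done: %d arms x %d seeds",
         length(unique(suite$results$kind)), length(seeds))
  } else {
    stop_bad_arg("unknown task: ", task)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
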