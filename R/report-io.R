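#' Write a plate run to the canonical CSV dialect
#'
#' One row per well per cycle with columns run_id, day, well_id, or_id,
#' odorant_id, phase, concentration, replicate, cycle, time_s, luminescence.
#' Numeric fields are serialized with 17 significant digits so that
#' write-read-write round-trips are byte-identical and values survive at
#' full double precision.
#'
#' @param run a `plate_run`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(run, path) {
  stopifnot(inherits(run, "plate_run"))
  tr <- run$traces
  df <- data.frame(run_id = tr$run_id, day = tr$day, well_id = tr$well_id,
                   or_id = tr$or_id, odorant_id = tr$odorant_id,
                   phase = tr$phase,
                   concentration = sprintf("%.17g", tr$concentration),
                   replicate = tr$replicate, cycle = tr$cycle,
                   time_s = sprintf("%.17g", tr$time_s),
                   luminescence = sprintf("%.17g", tr$luminescence),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate run from the canonical CSV dialect
#'
#' Validates structure on the way in: required columns, strictly positive
#' luminescence, unique (well_id, cycle) keys, and a complete 1..n cycle
#' sequence per well, reporting offending wells/rows by name.
#'
#' @param path CSV path.
#' @param control_id which or_id labels the vector control.
#' @return a `plate_run`.
#' @export
read_plate_csv <- function(path, control_id = "pCI") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "day", "well_id", "or_id", "odorant_id", "phase",
            "concentration", "replicate", "cycle", "time_s", "luminescence")
  if (nrow(df) == 0) stop("empty plate file: ", path)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate file missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$luminescence) | df$luminescence <= 0)
  if (length(bad))
    stop("non-positive luminescence at rows ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (well ", df$well_id[bad[1]], ")")
  key <- paste(df$well_id, df$cycle)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (well_id, cycle) key: ", d)
  }
  n_cyc <- max(df$cycle)
  for (w in unique(df$well_id)) {
    cyc <- sort(df$cycle[df$well_id == w])
    missing_cyc <- setdiff(seq_len(n_cyc), cyc)
    if (length(missing_cyc))
      stop("well ", sQuote(w), " is missing cycle ",
           paste(missing_cyc, collapse = ", "))
  }
  if (!control_id %in% df$or_id)
    stop("control label ", sQuote(control_id), " not present in plate file")
  conds <- unique(df[, c("odorant_id", "phase", "concentration")])
  names(conds) <- c("odorant", "phase", "concentration")
  wells_per <- table(paste(df$or_id, df$odorant_id, df$concentration))
  design <- panel_design(
    or_ids = setdiff(unique(df$or_id), control_id), control_id = control_id,
    odorant_ids = unique(df$odorant_id), conditions = conds,
    replicates = max(df$replicate), n_cycles = n_cyc,
    cycle_interval_s = if (n_cyc > 1) df$time_s[order(df$well_id, df$cycle)][2] -
      df$time_s[order(df$well_id, df$cycle)][1] else 90)
  structure(list(design = design,
                 traces = df[order(df$well_id, df$cycle), need],
                 params = list(imported_from = path,
                               run_id = df$run_id[1], day = df$day[1],
                               seed = NA_integer_)),
            class = "plate_run")
}

#' Write a response matrix as tidy + wide CSVs
#'
#' @param rm a `response_matrix`.
#' @param tidy_path path for the tidy per-replicate table.
#' @param wide_path optional path for the wide matrix of per-cell means.
#' @return paths, invisibly.
#' @export
write_response_matrix <- function(rm, tidy_path, wide_path = NULL) {
  stopifnot(inherits(rm, "response_matrix"))
  utils::write.csv(rm$tidy[, c("or_id", "condition", "replicate", "value",
                               "day", "run_id")],
                   tidy_path, row.names = FALSE, quote = FALSE)
  if (!is.null(wide_path)) {
    m <- response_means(rm)
    utils::write.csv(data.frame(or_id = rownames(m), m, check.names = FALSE),
                     wide_path, row.names = FALSE)
  }
  invisible(c(tidy_path, wide_path))
}

#' Run configuration: defaults, round-trip and hashing
#'
#' The run configuration is a flat named list serialized as YAML. The
#' config hash (MD5 of the canonical YAML text) stamps every pipeline
#' output so results can be traced to the exact settings that produced
#' them.
#'
#' @param odorants,dilution,replicates,n_cycles,cycle_interval_s design.
#' @param seed root seed; all pipeline randomness derives from it.
#' @param days two day labels for the cross-day design.
#' @param mode quantification mode.
#' @param alpha significance level used throughout.
#' @param classifier `"random_forest"` or `"lda"`.
#' @param ntree random-forest trees.
#' @param perplexity t-SNE perplexity.
#' @return named list of class `run_config`.
#' @export
run_config <- function(odorants = analog_odorants(), dilution = 1e-2,
                       replicates = 3L, n_cycles = 20L, cycle_interval_s = 90,
                       seed = 1L, days = c("day1", "day2"),
                       mode = "auc_baseline", alpha = 0.05,
                       classifier = "random_forest", ntree = 500L,
                       perplexity = 10) {
  structure(list(odorants = odorants, dilution = dilution,
                 replicates = as.integer(replicates),
                 n_cycles = as.integer(n_cycles),
                 cycle_interval_s = cycle_interval_s,
                 seed = as.integer(seed), days = days, mode = mode,
                 alpha = alpha, classifier = classifier,
                 ntree = as.integer(ntree), perplexity = perplexity),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Hierarchical clustering of receptor response profiles
#'
#' Average-linkage agglomeration on Euclidean distances between the
#' receptors' mean response profiles, the ordering used for panel heat
#' maps. Rows are pre-sorted by receptor label so that ties resolve
#' deterministically.
#'
#' @param rm a `response_matrix` (>= 2 receptor rows).
#' @param method linkage, default `"average"`.
#' @return list with `order` (receptor labels in dendrogram order),
#'   `heights`, and the `hclust` object.
#' @export
hierarchical_cluster <- function(rm, method = "average") {
  m <- response_means(rm)
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 rows to cluster")
  h <- stats::hclust(stats::dist(m), method = method)
  list(order = rownames(m)[h$order], heights = h$height, hclust = h,
       method = method)
}

#' Export a response heat map with its underlying matrix
#'
#' Writes a color-coded receptor x condition matrix (PDF via pheatmap) plus
#' a sidecar CSV of the ordered values; the color-scale bounds are returned
#' in the metadata. A constant (e.g. all-zero) matrix falls back to a
#' \[0, 1\] scale.
#'
#' @param rm a `response_matrix`.
#' @param row_order optional receptor label order (e.g. from
#'   [hierarchical_cluster()]).
#' @param path output figure path (`.pdf`).
#' @return invisibly, list with `path`, `csv`, `bounds`.
#' @export
heatmap_export <- function(rm, row_order = NULL, path) {
  m <- response_means(rm)
  if (!is.null(row_order)) {
    if (!setequal(row_order, rownames(m))) stop("row_order must permute the rows")
    m <- m[row_order, , drop = FALSE]
  }
  bounds <- range(m, finite = TRUE)
  if (bounds[1] == bounds[2]) bounds <- c(0, 1)
  csv <- paste0(tools::file_path_sans_ext(path), "_matrix.csv")
  utils::write.csv(data.frame(or_id = rownames(m), m, check.names = FALSE),
                   csv, row.names = FALSE)
  ok <- tryCatch({
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       breaks = seq(bounds[1], bounds[2], length.out = 101),
                       filename = path, silent = TRUE)
    TRUE
  }, error = function(e) {
    warning("heat-map figure could not be rendered: ", conditionMessage(e),
            " (ordered CSV written)")
    FALSE
  })
  invisible(list(path = if (ok) path else NA_character_, csv = csv,
                 bounds = bounds))
}

#' Run the full pipeline from a configuration
#'
#' simulate (two days) -> normalize + quantify -> differential-activation
#' statistics -> cluster + heat map -> t-SNE embedding -> cross-day
#' classification, writing every artifact under `out_dir` stamped with the
#' config hash. Deterministic: rerunning with an equal config reproduces
#' identical numeric outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, list with `config`, `hash`, `accuracy`, `counts`,
#'   `files`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (config$replicates < 2)
    stop("pipeline stage 'design': replicates must be >= 2 for the ",
         "statistical stages")
  if (length(config$days) != 2 || anyDuplicated(config$days))
    stop("pipeline stage 'design': need two distinct day labels")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage ", sQuote(name), ": ", conditionMessage(e),
           call. = FALSE))
  }
  message("[odorpanel] config ", hash, ": simulate")
  design <- default_panel_design(odorants = config$odorants,
                                 dilutions = config$dilution,
                                 replicates = config$replicates,
                                 n_cycles = config$n_cycles,
                                 cycle_interval_s = config$cycle_interval_s)
  affinity <- default_affinity(odorants = config$odorants)
  runs <- stage("simulate", lapply(seq_along(config$days), function(i) {
    simulate_plate_run(design, affinity,
                       partition_coeffs = default_partition(config$odorants),
                       seed = derive_seed(config$seed, 100 + i),
                       day = config$days[i],
                       run_id = paste0("run_", config$days[i]))
  }))
  files <- character()
  for (i in seq_along(runs)) {
    f <- file.path(out_dir, paste0("plate_", config$days[i], ".csv"))
    write_plate_csv(runs[[i]], f)
    files <- c(files, f)
  }
  message("[odorpanel] quantify (", config$mode, ")")
  rms <- stage("quantify", lapply(runs, build_response_matrix, mode = config$mode))
  rm_all <- stage("quantify", build_response_matrix(runs, mode = config$mode))
  f_tidy <- file.path(out_dir, "responses_tidy.csv")
  f_wide <- file.path(out_dir, "responses_means.csv")
  write_response_matrix(rm_all, f_tidy, f_wide)
  files <- c(files, f_tidy, f_wide)

  message("[odorpanel] differential activation statistics")
  dac <- stage("stats", differential_activation_counts(rms[[1]],
                                                       alpha = config$alpha))
  f_counts <- file.path(out_dir, "differential_activation_counts.csv")
  utils::write.csv(data.frame(odorant = rownames(dac$counts), dac$counts,
                              check.names = FALSE), f_counts, row.names = FALSE)
  files <- c(files, f_counts)

  message("[odorpanel] clustering + heat map")
  cl <- stage("report", hierarchical_cluster(rms[[1]]))
  hm <- stage("report", heatmap_export(rms[[1]], row_order = cl$order,
                                       path = file.path(out_dir, "heatmap.pdf")))
  files <- c(files, hm$csv, hm$path[!is.na(hm$path)])

  message("[odorpanel] discrimination")
  trials <- lapply(rms, trial_vectors)
  all_trials <- rbind(trials[[1]], trials[[2]])
  attr(all_trials, "panel") <- attr(trials[[1]], "panel")
  emb <- stage("discriminate",
               tsne_embed(all_trials, perplexity = config$perplexity,
                          seed = derive_seed(config$seed, 300)))
  f_emb <- file.path(out_dir, "tsne_embedding.csv")
  utils::write.csv(emb, f_emb, row.names = FALSE)
  model <- stage("discriminate",
                 train_classifier(trials[[1]], method = config$classifier,
                                  seed = derive_seed(config$seed, 400),
                                  ntree = config$ntree))
  report <- stage("discriminate", evaluate_classifier(model, trials[[2]]))
  f_conf <- file.path(out_dir, "confusion.csv")
  utils::write.csv(as.data.frame.matrix(report$confusion), f_conf)
  f_pred <- file.path(out_dir, "predictions.csv")
  utils::write.csv(report$predictions, f_pred, row.names = FALSE)
  files <- c(files, f_emb, f_conf, f_pred)

  summary <- list(config_hash = hash, accuracy_percent = report$accuracy,
                  n_anova_significant = dac$n_anova_significant,
                  seed = config$seed, files = basename(files))
  f_sum <- file.path(out_dir, "summary.yaml")
  yaml::write_yaml(summary, f_sum)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(list(config = config, hash = hash, accuracy = report$accuracy,
                 counts = dac$counts, files = c(files, f_sum)))
}
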