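#' Validated run configuration for the end-to-end pipeline
#'
#' One configuration object drives the whole analysis: data source
#' (synthetic cohort parameters or paths to the five real input tables),
#' preprocessing parameters, learner parameters, cross-validation design,
#' y-randomization budget, the domain combinations to run, the master
#' seed and the output directory.  Unknown keys are rejected so typos
#' cannot silently change a run.
#'
#' @param mode "synthetic" or "real".
#' @param synthetic a [synth_config()] (synthetic mode).
#' @param paths named list of input files for real mode: compounds,
#'   chem_descriptors, qhts, fingerprints, bioactivity, bio_fingerprints.
#' @param preprocess a [preprocess_config()].
#' @param rf an [rf_params()].
#' @param n_repeats,n_folds cross-validation design.
#' @param n_scrambles scrambled retrainings per assessed cell.
#' @param scramble_cells (repeat, fold) cells assessed per combination
#'   during \code{pipeline_run} (0 disables y-randomization).
#' @param combos list of domain subsets (default all 7).
#' @param min_records record threshold for the target scorer.
#' @param seed master seed.
#' @param output_dir where stage outputs are written.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       synthetic = synth_config(),
                       paths = NULL,
                       preprocess = preprocess_config(),
                       rf = rf_params(),
                       n_repeats = 20L,
                       n_folds = 5L,
                       n_scrambles = 10L,
                       scramble_cells = 5L,
                       combos = all_combos(),
                       min_records = 50L,
                       seed = 1L,
                       output_dir = "toxtriad_run") {
  mode <- match.arg(mode)
  cfg <- structure(list(mode = mode, synthetic = synthetic, paths = paths,
                        preprocess = preprocess, rf = rf,
                        n_repeats = as.integer(n_repeats),
                        n_folds = as.integer(n_folds),
                        n_scrambles = as.integer(n_scrambles),
                        scramble_cells = as.integer(scramble_cells),
                        combos = combos,
                        min_records = as.integer(min_records),
                        seed = as.integer(seed),
                        output_dir = output_dir),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

required_paths <- c("compounds", "chem_descriptors", "qhts", "fingerprints",
                    "bioactivity", "bio_fingerprints")

validate_run_config <- function(cfg) {
  known <- c("mode", "synthetic", "paths", "preprocess", "rf", "n_repeats",
             "n_folds", "n_scrambles", "scramble_cells", "combos",
             "min_records", "seed", "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("run_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (cfg$mode == "real") {
    if (is.null(cfg$paths))
      stop("run_config: real mode requires 'paths'", call. = FALSE)
    missing <- setdiff(required_paths, names(cfg$paths))
    if (length(missing))
      stop("run_config: missing path key(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  } else {
    if (!inherits(cfg$synthetic, "synth_config"))
      stop("run_config: 'synthetic' must be a synth_config", call. = FALSE)
  }
  for (nm in c("n_repeats", "n_folds", "n_scrambles", "seed"))
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]))
      stop("run_config: '", nm, "' must be a single integer", call. = FALSE)
  bad <- !vapply(cfg$combos, function(cb)
    length(cb) >= 1L && all(cb %in% c("chemical", "target", "cytotox")),
    TRUE)
  if (any(bad))
    stop("run_config: 'combos' must be non-empty subsets of ",
         "chemical/target/cytotox", call. = FALSE)
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; \code{synthetic},
#' \code{preprocess} and \code{rf} are nested maps of the corresponding
#' constructor arguments; \code{combos} is a list of domain-name lists.
#' Unknown keys at any level are rejected.
#'
#' @param path YAML file.
#' @param overrides named list of top-level values overriding the file
#'   (how command-line flags are merged).
#' @return A validated \code{run_config}.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path))
    stop("read_run_config: file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("read_run_config: malformed YAML", call. = FALSE)
  raw[names(overrides)] <- overrides
  args <- raw
  if (!is.null(raw$synthetic))
    args$synthetic <- do.call(synth_config, raw$synthetic)
  if (!is.null(raw$preprocess))
    args$preprocess <- do.call(preprocess_config, raw$preprocess)
  if (!is.null(raw$rf))
    args$rf <- do.call(rf_params, raw$rf)
  if (!is.null(raw$combos))
    args$combos <- lapply(raw$combos, unlist)
  do.call(run_config, args)
}

log_line <- function(stage, ..., repeat_ = NA, fold = NA, combo = NA) {
  message(sprintf("[%s] stage=%s repeat=%s fold=%s combo=%s %s",
                  format(Sys.time(), "%H:%M:%S"), stage, repeat_, fold,
                  combo, paste0(..., collapse = "")))
}

#' Pipeline stage: simulate a synthetic cohort
#'
#' Wraps [generate_cohort()] and [write_cohort()]; the cohort is written
#' under \code{<output_dir>/cohort/}.
#'
#' @param config a [run_config()] in synthetic mode.
#' @return Invisibly, the cohort directory.
#' @export
pipeline_simulate <- function(config) {
  validate_run_config(config)
  if (config$mode != "synthetic")
    stop("pipeline_simulate: config is not in synthetic mode", call. = FALSE)
  log_line("simulate", "generating cohort")
  cohort <- generate_cohort(config$synthetic)
  dir <- file.path(config$output_dir, "cohort")
  write_cohort(cohort, dir)
  log_line("simulate", "cohort written to ", dir)
  invisible(dir)
}

read_real_inputs <- function(config) {
  for (nm in required_paths)
    if (!file.exists(config$paths[[nm]]))
      stop("pipeline_featurize: input file for '", nm, "' not found: ",
           config$paths[[nm]], call. = FALSE)
  cmp <- utils::read.csv(config$paths$compounds, stringsAsFactors = FALSE)
  chem_df <- utils::read.csv(config$paths$chem_descriptors,
                             stringsAsFactors = FALSE, check.names = FALSE)
  chem <- as.matrix(chem_df[, -1, drop = FALSE])
  rownames(chem) <- as.character(chem_df[[1]])
  qhts <- utils::read.csv(config$paths$qhts, stringsAsFactors = FALSE)
  fps <- df_to_fingerprints(utils::read.csv(config$paths$fingerprints,
                                            stringsAsFactors = FALSE))
  bio <- utils::read.csv(config$paths$bioactivity, stringsAsFactors = FALSE)
  bio_fps <- df_to_fingerprints(
    utils::read.csv(config$paths$bio_fingerprints,
                    stringsAsFactors = FALSE))
  list(compounds = cmp, chem = chem, qhts = qhts, fingerprints = fps,
       bioactivity = bio, bio_fingerprints = bio_fps)
}

#' Pipeline stage: build descriptors and labels
#'
#' Trains the target scorer, scores all compounds, scales the qHTS block
#' and assembles the domain-tagged descriptor table; writes
#' \code{descriptors.csv} (with a leading domain-tag comment line) and
#' \code{labels.csv} under the output directory.
#'
#' @param config a [run_config()].
#' @return Invisibly, list(table, labels, scorer).
#' @export
pipeline_featurize <- function(config) {
  validate_run_config(config)
  log_line("featurize", "building descriptor table")
  if (config$mode == "synthetic") {
    dir <- file.path(config$output_dir, "cohort")
    cohort <- if (dir.exists(dir)) read_cohort(dir)
              else generate_cohort(config$synthetic)
    out <- featurize_cohort(cohort, min_records = config$min_records)
  } else {
    inp <- read_real_inputs(config)
    scorer <- lmnb(inp$bioactivity, inp$bio_fingerprints,
                   min_records = config$min_records)
    scores <- predict(scorer, inp$fingerprints)
    colnames(scores) <- paste0("tgt_", colnames(scores))
    cyto <- qhts_block(inp$qhts)
    out <- assemble_table(inp$chem, scores, cyto, inp$compounds)
    out$scorer <- scorer
  }
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  write_descriptor_table(out$table,
                         file.path(config$output_dir, "descriptors.csv"))
  write_num_csv(data.frame(compound_id = names(out$labels),
                           label = as.character(out$labels),
                           stringsAsFactors = FALSE),
                file.path(config$output_dir, "labels.csv"))
  log_line("featurize", sprintf("%d compounds x %d descriptors",
                                nrow(out$table), ncol(out$table)))
  invisible(out)
}

#' Write / read a domain-tagged descriptor table
#'
#' CSV with a leading \code{#domain} comment line tagging every column,
#' then a standard header row.
#'
#' @param table domain-tagged matrix.
#' @param path output file.
#' @return \code{write_descriptor_table}: invisibly, the path;
#'   \code{read_descriptor_table}: the matrix with domain tags.
#' @export
write_descriptor_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#domain,", paste(domains(table), collapse = ",")), con)
  df <- matrix_to_df(table)
  utils::write.csv(as.data.frame(lapply(df, format_full),
                                 check.names = FALSE, optional = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  if (!file.exists(path))
    stop("read_descriptor_table: file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#domain,"))
    stop("read_descriptor_table: missing #domain tag line in ", path,
         call. = FALSE)
  tags <- strsplit(sub("^#domain,", "", first), ",")[[1]]
  df <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE,
                        check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  attr(m, "domain") <- tags
  m
}

#' Pipeline stage: run the cross-validation study
#'
#' Builds the shared split plan, runs every configured combination with
#' [toxcv()], assesses a configurable number of cells per combination by
#' y-randomization, and writes per-compound external predictions
#' (\code{predictions.csv}), per-cell summaries (\code{cells.csv}) and
#' scramble p-values (\code{scrambles.csv}).
#'
#' @param config a [run_config()].
#' @return Invisibly, the \code{toxcv} fit (with \code{$scrambles}).
#' @export
pipeline_run <- function(config) {
  validate_run_config(config)
  table <- read_descriptor_table(file.path(config$output_dir,
                                           "descriptors.csv"))
  lab_df <- utils::read.csv(file.path(config$output_dir, "labels.csv"),
                            stringsAsFactors = FALSE)
  labels <- factor(lab_df$label, levels = c("nontoxic", "toxic"))
  names(labels) <- lab_df$compound_id
  log_line("run", sprintf("%d combinations, %d repeats x %d folds",
                          length(config$combos), config$n_repeats,
                          config$n_folds))
  fit <- toxcv(table, labels, combos = config$combos,
               n_repeats = config$n_repeats, n_folds = config$n_folds,
               rf = config$rf, control = config$preprocess,
               seed = config$seed)
  for (nm in names(fit$results))
    log_line("run", sprintf("done (%d cells)",
                            length(fit$results[[nm]]$cells)), combo = nm)

  scrambles <- NULL
  if (config$scramble_cells > 0L) {
    rows <- list()
    for (nm in names(fit$results)) {
      result <- fit$results[[nm]]
      n_cells <- length(result$cells)
      pick <- seq_len(min(config$scramble_cells, n_cells))
      for (i in pick) {
        cl <- result$cells[[i]]
        real_ccr <- confusion_metrics(cl$predictions$truth,
                                      cl$predictions$prediction)[["ccr"]]
        ys <- y_scramble_assess(table, labels, result$combo, fit$plan,
                                cl$repeat_, cl$fold, rf = config$rf,
                                cutoffs = result$cutoffs,
                                control = config$preprocess,
                                n_scrambles = config$n_scrambles,
                                master_seed = config$seed,
                                real_ccr = real_ccr)
        log_line("scramble", sprintf("p=%.3g", ys$p), repeat_ = cl$repeat_,
                 fold = cl$fold, combo = nm)
        rows[[length(rows) + 1L]] <-
          data.frame(combo = nm, repeat_ = cl$repeat_, fold = cl$fold,
                     real_ccr = ys$real_ccr, p = ys$p, pass = ys$pass)
      }
    }
    scrambles <- do.call(rbind, rows)
  }
  fit$scrambles <- scrambles

  preds <- do.call(rbind, lapply(names(fit$results), function(nm) {
    do.call(rbind, lapply(fit$results[[nm]]$cells, function(cl)
      cbind(data.frame(combo = nm, repeat_ = cl$repeat_, fold = cl$fold),
            cl$predictions)))
  }))
  write_num_csv(preds, file.path(config$output_dir, "predictions.csv"))
  cells <- do.call(rbind, lapply(fit$results, cell_metrics))
  write_num_csv(cells, file.path(config$output_dir, "cells.csv"))
  if (!is.null(scrambles))
    write_num_csv(scrambles, file.path(config$output_dir, "scrambles.csv"))
  invisible(fit)
}

report_header <- function(config) {
  sprintf("# seed=%d combos=%d repeats=%d folds=%d", config$seed,
          length(config$combos), config$n_repeats, config$n_folds)
}

write_report_csv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Pipeline stage: evaluation reports
#'
#' From a completed run (or a freshly recomputed one), writes the
#' performance-summary table, all pairwise nested-combination improvement
#' tests, the applicability-domain profile, Mantel tests between the
#' three domain distance matrices, and the aggregated tripartite variable
#' importances, each as a CSV with a seed/config comment header.
#'
#' @param config a [run_config()].
#' @param fit optionally, the \code{toxcv} object from [pipeline_run()];
#'   recomputed from the written stage outputs if missing.
#' @return Invisibly, a list of the report data.frames.
#' @export
pipeline_evaluate <- function(config, fit = NULL) {
  validate_run_config(config)
  if (is.null(fit)) fit <- pipeline_run(config)
  table <- read_descriptor_table(file.path(config$output_dir,
                                           "descriptors.csv"))
  out_dir <- config$output_dir
  log_line("evaluate", "writing reports")

  perf <- summary(fit)
  write_report_csv(perf, file.path(out_dir, "performance.csv"), config)

  nms <- names(fit$results)
  imp_rows <- list()
  for (a in nms) for (b in nms) {
    ca <- fit$results[[a]]$combo; cb <- fit$results[[b]]$combo
    if (length(cb) < length(ca) && all(cb %in% ca)) {
      rec <- paired_improvement(fit$results[[a]], fit$results[[b]])
      imp_rows[[length(imp_rows) + 1L]] <-
        data.frame(combo = a, comparison = b, mean_delta_ccr = rec$mean,
                   se = rec$se, p_value = rec$p_value)
    }
  }
  improvements <- if (length(imp_rows)) do.call(rbind, imp_rows) else NULL
  if (!is.null(improvements))
    write_report_csv(improvements, file.path(out_dir, "improvements.csv"),
                     config)

  spaces <- lapply(c("chemical", "target", "cytotox"), function(dd)
    if (dd %in% domains(table))
      descriptor_space(table, dd, fit$cutoffs, config$preprocess))
  names(spaces) <- c("chemical", "target", "cytotox")

  ad <- NULL
  if (!is.null(spaces$chemical)) {
    ad <- ad_profile(fit, spaces$chemical)
    write_report_csv(ad$profile, file.path(out_dir, "ad_profile.csv"),
                     config)
  }

  mant_rows <- list()
  have <- names(spaces)[!vapply(spaces, is.null, TRUE)]
  if (length(have) >= 2L) {
    for (i in seq_along(have)) for (j in seq_along(have)) {
      if (i < j) {
        mt <- mantel_test(as.matrix(stats::dist(spaces[[have[i]]])),
                          as.matrix(stats::dist(spaces[[have[j]]])),
                          n_perm = 999L, seed = config$seed)
        mant_rows[[length(mant_rows) + 1L]] <-
          data.frame(domain_a = have[i], domain_b = have[j], r = mt$r,
                     p = mt$p, n_perm = mt$n_perm)
      }
    }
    write_report_csv(do.call(rbind, mant_rows),
                     file.path(out_dir, "mantel.csv"), config)
  }

  imp <- NULL
  tri <- combo_name(c("chemical", "target", "cytotox"))
  if (tri %in% nms) {
    imp <- aggregate_importance(fit$results[[tri]], table)
    write_report_csv(as.data.frame(imp),
                     file.path(out_dir, "importance.csv"), config)
  }
  log_line("evaluate", "reports written to ", out_dir)
  invisible(list(performance = perf, improvements = improvements,
                 ad_profile = ad,
                 mantel = if (length(mant_rows)) do.call(rbind, mant_rows),
                 importance = imp))
}

#' Run every pipeline stage in order
#'
#' simulate (synthetic mode only), featurize, run, evaluate.  Idempotent:
#' identical config and seed reproduce byte-identical numeric outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, the [pipeline_evaluate()] report list.
#' @export
pipeline_all <- function(config) {
  validate_run_config(config)
  if (config$mode == "synthetic") pipeline_simulate(config)
  pipeline_featurize(config)
  fit <- pipeline_run(config)
  invisible(pipeline_evaluate(config, fit))
}
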