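# Config-driven orchestration: simulate/ingest -> normative model ->
# deviation networks -> density stacks -> metric curves/AUCs -> inference
# -> persisted artifacts. Every stochastic stage draws a seed derived from
# the master seed and stable labels, so runs are reproducible end to end.

#' Build a validated pipeline run configuration
#'
#' @param input_mode `"simulate"` (default), `"flat"` or `"freesurfer"`.
#' @param input_path path to the flat table (`input_mode = "flat"`) or to a
#'   directory of per-subject FreeSurfer stats subdirectories.
#' @param input_sep flat-table delimiter.
#' @param density_mode `"fixed"` (0.10-0.37 step `density_step`) or
#'   `"criteria"` (retention-criteria selection).
#' @param density_step grid step (default 0.01).
#' @param m_refs,restarts metric-engine settings (random references per
#'   density; modularity restarts).
#' @param small_world evaluate the reference-based small-world indices and
#'   modularity curves (the expensive part; `TRUE` for the full analysis).
#' @param n_perm permutations per test (>= 100).
#' @param alpha FDR level in (0, 1).
#' @param include_icv_morphometry also covary ICV in morphometry contrasts.
#' @param seed master seed.
#' @param out_dir artifact directory (created).
#' @param synthetic a `synthetic_config` used when `input_mode="simulate"`;
#'   its own seed is overridden by a seed derived from `seed`.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_mode = c("simulate", "flat", "freesurfer"),
                       input_path = NULL, input_sep = ",",
                       density_mode = c("fixed", "criteria"),
                       density_step = 0.01,
                       m_refs = 100L, restarts = 10L, small_world = TRUE,
                       n_perm = 10000L, alpha = 0.05,
                       include_icv_morphometry = FALSE,
                       seed = 1L, out_dir = tempfile("iscn_run_"),
                       synthetic = synthetic_config()) {
  input_mode <- match.arg(input_mode)
  density_mode <- match.arg(density_mode)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  grid <- density_grid_default(density_step)
  if (any(grid <= 0 | grid > 1) || is.unsorted(grid, strictly = TRUE))
    stop("density grid must be ascending within (0, 1]", call. = FALSE)
  if (input_mode != "simulate" && is.null(input_path))
    stop("input_path required for input_mode '", input_mode, "'",
         call. = FALSE)
  cfg <- list(input_mode = input_mode, input_path = input_path,
              input_sep = input_sep, density_mode = density_mode,
              density_step = density_step, grid = grid, m_refs = m_refs,
              restarts = restarts, small_world = small_world,
              n_perm = as.integer(n_perm), alpha = alpha,
              include_icv_morphometry = include_icv_morphometry,
              seed = as.integer(seed), out_dir = out_dir,
              synthetic = synthetic)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; a `synthetic:` block is
#' passed to [synthetic_config()].
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, if (is.null(y$synthetic)) list()
                 else y$synthetic)
  y$synthetic <- NULL
  do.call(run_config, c(y, list(synthetic = syn)))
}

acquire_table <- function(cfg) {
  if (cfg$input_mode == "simulate") {
    syn <- cfg$synthetic
    syn$seed <- derive_seed(cfg$seed, "simulate")
    generate_cohort(syn)
  } else if (cfg$input_mode == "flat") {
    read_flat_table(cfg$input_path, sep = cfg$input_sep)
  } else {
    stop("freesurfer input mode requires assembling per-subject rows with ",
         "read_freesurfer_stats() and clinical fields; supply a flat table",
         call. = FALSE)
  }
}

#' Run the full ISCN pipeline
#'
#' @param cfg a `run_config`.
#' @return (invisibly) list with `table`, `model`, `z`, `networks`, `grid`,
#'   `curvesets`, `inference`, `out_dir`; all artifacts are persisted under
#'   `cfg$out_dir` by [write_outputs()].
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[iscn %5.1fs] ",
    as.numeric(difftime(Sys.time(), t0, units = "secs"))), ...)

  registry <- build_dk_registry()
  log_stage("input: ", cfg$input_mode)
  table <- acquire_table(cfg)
  log_stage("cohort: ", nrow(table), " rows")

  hc <- cohort_rows(table, "HC")
  model <- fit_normative_model(hc, registry)
  z <- compute_deviation(table, model)
  networks <- build_all_networks(z)
  log_stage("networks: ", length(networks), " subjects x ", ncol(z), " nodes")

  grid <- if (cfg$density_mode == "fixed") {
    density_grid_default(cfg$density_step)
  } else {
    determine_density_range(networks, mode = "criteria",
                            m_refs = cfg$m_refs, restarts = cfg$restarts,
                            seed = derive_seed(cfg$seed, "density"))
  }
  log_stage("density grid: ", length(grid), " levels [", min(grid), ", ",
            max(grid), "]")

  curvesets <- lapply(names(networks), function(key) {
    stack <- build_graph_stack(networks[[key]], grid)
    metric_curves(stack, subject_id = key, m_refs = cfg$m_refs,
                  restarts = cfg$restarts,
                  seed = derive_seed(cfg$seed, "metrics"),
                  small_world = cfg$small_world)
  })
  names(curvesets) <- names(networks)
  log_stage("metric curves done")

  inference <- run_group_analysis(
    table, curvesets, registry, n_perm = cfg$n_perm, alpha = cfg$alpha,
    include_icv_morphometry = cfg$include_icv_morphometry,
    seed = derive_seed(cfg$seed, "inference"))
  log_stage("inference done")

  results <- list(table = table, model = model, z = z, networks = networks,
                  grid = grid, curvesets = curvesets, inference = inference,
                  config = cfg)
  write_outputs(results, cfg$out_dir)
  log_stage("artifacts written to ", cfg$out_dir)
  invisible(c(results, list(out_dir = cfg$out_dir)))
}

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(apply(m, 2, fmt_num))
  names(df) <- colnames(m)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read back a square matrix written by the pipeline
#' @param path TSV file.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  m
}

#' Persist pipeline results
#'
#' Writes, under `out_dir`: the cohort table, normative model coefficients,
#' z-score matrix, per-subject network matrices (TSV), long-format metric
#' curves and AUC tables, the inference result tables, a human-readable
#' summary, and run metadata (config, seed, package version) as YAML.
#' Column orders are fixed, so identical results produce byte-identical
#' files.
#'
#' @param results list as assembled by [run_pipeline()] (individual
#'   elements may be absent; whatever is present is written).
#' @param out_dir output directory (created).
#' @return (invisibly) character vector of written paths.
#' @export
write_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character(0)
  put <- function(p) { paths <<- c(paths, p); p }

  if (!is.null(results$table))
    write_flat_table(results$table, put(file.path(out_dir, "cohort.csv")))

  if (!is.null(results$model)) {
    m <- results$model
    df <- data.frame(roi = m$registry$name, t(m$coef), mu = m$mu,
                     sigma = m$sigma, check.names = FALSE)
    names(df)[2:5] <- c("intercept", "age", "sex", "icv")
    utils::write.table(df, put(file.path(out_dir, "normative_model.csv")),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }

  if (!is.null(results$z)) {
    df <- data.frame(subject = rownames(results$z), results$z,
                     check.names = FALSE)
    utils::write.table(df, put(file.path(out_dir, "zscores.csv")), sep = ",",
                       row.names = FALSE, quote = FALSE)
  }

  if (!is.null(results$networks) && length(results$networks)) {
    ndir <- file.path(out_dir, "networks")
    dir.create(ndir, showWarnings = FALSE)
    for (key in names(results$networks))
      write_matrix_tsv(results$networks[[key]],
                       put(file.path(ndir, paste0(gsub(":", "_", key),
                                                  ".tsv"))))
  }

  if (!is.null(results$curvesets) && length(results$curvesets)) {
    long <- do.call(rbind, lapply(results$curvesets, function(cs) {
      nodal <- do.call(rbind, lapply(names(cs$nodal_auc), function(m)
        data.frame(subject = cs$subject_id, metric = m,
                   node = names(cs$nodal_auc[[m]]),
                   auc = cs$nodal_auc[[m]], stringsAsFactors = FALSE)))
      glob <- data.frame(subject = cs$subject_id, metric = names(cs$global_auc),
                         node = "global", auc = unname(cs$global_auc),
                         stringsAsFactors = FALSE)
      rbind(nodal, glob)
    }))
    rownames(long) <- NULL
    long$auc <- fmt_num(long$auc)
    utils::write.table(long, put(file.path(out_dir, "auc.csv")), sep = ",",
                       row.names = FALSE, quote = FALSE)
  }

  inf <- results$inference
  if (!is.null(inf)) {
    for (nm in c("morphometry", "nodal_auc", "global_auc", "paired",
                 "correlation")) {
      df <- inf[[nm]]
      for (col in intersect(c("statistic", "p", "q", "r", "mean_change"),
                            names(df)))
        df[[col]] <- fmt_num(df[[col]])
      utils::write.table(df, put(file.path(out_dir,
                                           paste0("inference_", nm, ".csv"))),
                         sep = ",", row.names = FALSE, quote = FALSE)
    }
    summ <- c(
      "ISCN pipeline summary",
      sprintf("permutations: %d, FDR alpha: %g", inf$settings$n_perm,
              inf$settings$alpha),
      sprintf("significant morphometry features (q <= alpha): %s",
              paste(unique(inf$morphometry$feature[inf$morphometry$significant]),
                    collapse = ", ")),
      sprintf("significant nodal AUC features: %s",
              paste(unique(paste0(inf$nodal_auc$family, "/",
                                  inf$nodal_auc$feature)[inf$nodal_auc$significant]),
                    collapse = ", ")),
      sprintf("significant global AUC features: %s",
              paste(unique(inf$global_auc$feature[inf$global_auc$significant]),
                    collapse = ", ")))
    writeLines(summ, put(file.path(out_dir, "summary.txt")))
  }

  cfg <- results$config
  meta <- list(
    package = "iscn",
    version = as.character(utils::packageVersion("iscn")),
    seed = if (!is.null(cfg)) cfg$seed else NA,
    config = if (!is.null(cfg)) {
      cfg$synthetic <- unclass(cfg$synthetic)
      cfg$grid <- NULL
      unclass(cfg)
    } else NULL)
  yaml::write_yaml(meta, put(file.path(out_dir, "run_metadata.yaml")))
  invisible(paths)
}
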