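# End-to-end orchestration: preparation, preliminary adjusted models,
# stratified discovery, stratified inference with cross-stratum validation,
# and balance diagnostics, with reproducible seed management and a JSON run
# log.

#' Pipeline configuration
#'
#' @param table A [feature_table()] (counts or relative abundances) or a path
#'   to a TSV readable by [read_feature_table()].
#' @param metadata Metadata data.frame or CSV path; must contain
#'   `food_insecure`, `minicog`, and the adjustment covariates. The `rci`
#'   outcome is derived with [transform_outcome()] if absent.
#' @param output_dir Optional directory for CSV outputs and the JSON run log;
#'   `NULL` keeps everything in memory.
#' @param prevalence_threshold Prevalence filter threshold (default 0.05).
#' @param discovery A [discovery_config()]; its seed is overridden by
#'   stage-specific seeds derived from `seed`.
#' @param n_permutations Permutations for stage-2 p-values (default 1e5).
#' @param covariates Adjustment covariate names.
#' @param seed Master seed for the whole run.
#' @return A `run_config` list.
#' @export
run_config <- function(table, metadata, output_dir = NULL,
                       prevalence_threshold = 0.05,
                       discovery = fast_discovery_config(),
                       n_permutations = 1e5,
                       covariates = default_covariates, seed = 1L) {
  structure(list(table = table, metadata = metadata,
                 output_dir = output_dir,
                 prevalence_threshold = prevalence_threshold,
                 discovery = discovery, n_permutations = n_permutations,
                 covariates = covariates, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s': %s", name, conditionMessage(e))
  })
}

#' Run the full MiCA pipeline
#'
#' Executes, in order: input loading and validation; sample filtering
#' (samples lacking food-insecurity status or a cognitive score are dropped;
#' covariate missingness is imputed with [pmm_impute()]); feature-table
#' preparation (relative abundance + prevalence filter); preliminary adjusted
#' models (pooled food-insecurity on RCI, per-stratum Shannon diversity on
#' RCI, per-stratum per-taxon quartile scans with FDR); stage-1 clique
#' discovery per stratum; stage-2 stratified permutation inference with
#' cross-stratum validation for every discovered clique; and subclass balance
#' diagnostics. All stochastic stages run under seeds derived from the master
#' seed, so a rerun with the same config reproduces the report exactly.
#'
#' @param config A [run_config()].
#' @return A `mica_report` list with elements `descriptives`, `fi_fit`,
#'   `diversity_fits`, `scans`, `volcano`, `candidates`, `cliques`,
#'   `effects`, `validation`, `balance`, and `log`; written to
#'   `config$output_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- child_seeds(config$seed, 6L)
  log <- list(seed = config$seed,
              prevalence_threshold = config$prevalence_threshold,
              started = format(Sys.time(), tz = "UTC"))

  table <- stage("load", {
    t <- config$table
    if (is.character(t)) t <- read_feature_table(t)
    stopifnot(inherits(t, "feature_table"))
    t
  })
  meta <- stage("load", {
    m <- config$metadata
    if (is.character(m)) m <- read_metadata(m)
    required <- c("food_insecure", "minicog", config$covariates)
    missing <- setdiff(required, names(m))
    if (length(missing) > 0L)
      stopf("metadata is missing column(s): %s",
            paste(missing, collapse = ", "))
    m
  })

  prepped <- stage("prep", {
    keep <- !is.na(meta$food_insecure) & !is.na(meta$minicog)
    meta <- meta[keep, , drop = FALSE]
    table <- ft_subset(table, samples = keep)
    meta[config$covariates] <- pmm_impute(meta[config$covariates],
                                          seed = seeds[1L])
    if (is.null(meta$rci)) meta$rci <- transform_outcome(meta$minicog)
    rel <- if (max(abs(rowSums(table$values) - 1)) > 1e-6)
      to_relative_abundance(table) else table
    filtered <- prevalence_filter(rel, config$prevalence_threshold)
    meta$shannon <- as.numeric(shannon_diversity(rel))
    list(table = filtered, meta = meta)
  })
  table <- prepped$table
  meta <- prepped$meta
  log$n_samples <- nrow(meta)
  log$n_taxa_retained <- ncol(table$values)

  descriptives <- stage("descriptives", descriptive_table(meta))

  fi_fit <- stage("adjusted_scan", {
    fit_adjusted_lm(meta$rci, meta$food_insecure,
                    meta[config$covariates],
                    exposure_name = "food_insecure")
  })
  diversity_fits <- stage("adjusted_scan", {
    do.call(rbind, lapply(c("secure", "insecure"), function(s) {
      sel <- meta$food_insecure == (s == "insecure")
      fit_adjusted_lm(meta$rci[sel], meta$shannon[sel],
                      meta[sel, config$covariates], "shannon", s)
    }))
  })
  scans <- stage("adjusted_scan", {
    lapply(c(secure = "secure", insecure = "insecure"), function(s)
      asv_scan(table, meta, s, config$covariates))
  })
  volcano <- lapply(scans, volcano_data)

  candidates <- stage("clique_discovery", {
    dseeds <- child_seeds(seeds[2L], 2L)
    out <- list()
    for (i in 1:2) {
      s <- c("secure", "insecure")[i]
      sel <- meta$food_insecure == (s == "insecure")
      cfg <- config$discovery
      cfg$seed <- dseeds[i]
      out[[s]] <- repeated_holdout_discovery(
        ft_subset(table, samples = sel), meta$rci[sel], cfg)
    }
    out
  })
  cliques <- stage("clique_discovery", {
    lapply(candidates, function(cand)
      withCallingHandlers(
        select_cliques(cand, config$discovery$min_stability),
        warning = function(w) invokeRestart("muffleWarning")))
  })

  inference <- stage("clique_inference", {
    iseeds <- child_seeds(seeds[3L], 100L)
    k <- 0L
    effects <- list()
    validation <- list()
    for (s in names(cliques)) {
      for (cl in cliques[[s]]) {
        k <- k + 1L
        id <- sprintf("%s_clique%d", s, length(effects) + 1L)
        effects[[id]] <- stratified_effects(
          table, meta, cl, config$covariates,
          n_permutations = config$n_permutations, seed = iseeds[k])
        k <- k + 1L
        validation[[id]] <- cross_stratum_validate(
          table, meta, cl, discovered_in = s,
          covariates = config$covariates,
          n_permutations = config$n_permutations, seed = iseeds[k])
      }
    }
    list(effects = effects, validation = validation)
  })

  balance <- stage("balance", {
    out <- list()
    for (s in names(cliques)) {
      for (cl in cliques[[s]]) {
        id <- sprintf("%s_clique%d", s, length(out) + 1L)
        ind <- build_indicator(table, cl)
        out[[id]] <- subclass_balance(as.integer(ind$harboring),
                                      meta[config$covariates])
      }
    }
    out
  })

  log$n_cliques <- sum(lengths(cliques))
  log$finished <- format(Sys.time(), tz = "UTC")
  report <- structure(list(descriptives = descriptives, fi_fit = fi_fit,
                           diversity_fits = diversity_fits, scans = scans,
                           volcano = volcano, candidates = candidates,
                           cliques = cliques,
                           effects = inference$effects,
                           validation = inference$validation,
                           balance = balance, log = log),
                      class = "mica_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$descriptives, file.path(dir, "descriptives.csv"),
            row.names = FALSE)
  write.csv(rbind(report$fi_fit, report$diversity_fits),
            file.path(dir, "preliminary_fits.csv"), row.names = FALSE)
  for (s in names(report$scans))
    write.csv(report$scans[[s]], file.path(dir, paste0("scan_", s, ".csv")),
              row.names = FALSE)
  for (s in names(report$candidates)) {
    cand <- report$candidates[[s]]
    flat <- data.frame(key = cand$key, size = cand$size,
                       stability = cand$stability,
                       mean_prevalence = cand$mean_prevalence)
    write.csv(flat, file.path(dir, paste0("candidates_", s, ".csv")),
              row.names = FALSE)
  }
  eff <- do.call(rbind, lapply(names(report$effects), function(id) {
    t <- report$effects[[id]]$table
    t$clique_id <- id
    t$clique <- paste(report$effects[[id]]$clique, collapse = ";")
    t
  }))
  if (!is.null(eff))
    write.csv(eff, file.path(dir, "clique_effects.csv"), row.names = FALSE)
  jsonlite::write_json(report$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
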