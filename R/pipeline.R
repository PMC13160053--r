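# Pipeline orchestration: simulate -> fit -> landscape summaries
# (-> compare, -> stability), driven by one YAML config, with a JSON
# manifest recording the seed and an md5 per output so re-runs can be
# verified byte-for-byte.

#' Run the analysis pipeline from a configuration
#'
#' Stages run in dependency order; every output file is listed in a
#' manifest with its md5 hash and the seed, and a re-run with the same
#' config reproduces stochastic stages bit-exactly. The config is a YAML
#' file (or an equivalent named list) with blocks:
#'
#' * `seed`, `out_dir`
#' * `simulate`: arguments to [sim_config()] plus `conditions` (label
#'   vector; each condition draws its own library with a seed offset), or
#' * `counts`: named list condition -> count TSV path (real data)
#' * `fit`: `generations` and/or `r` (per condition or scalar). For
#'   simulated conditions the realized fold recorded by the simulator is
#'   used unless `r` is given.
#' * `landscape`: optional `annotation` (YAML path), `class_filter`
#' * `compare`: optional list with `a`, `b` (condition labels)
#' * `stability`: optional list with `ddg` (TSV path)
#'
#' @param config YAML path or named list.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  outputs <- character(0)
  note <- function(path) outputs <<- c(outputs, path)

  # --- stage: counts (simulate or load) -------------------------------
  fold <- list()
  counts_by_cond <- list()
  if (!is.null(config$simulate)) {
    simcfg <- config$simulate
    conditions <- simcfg$conditions %||% "cond1"
    simcfg$conditions <- NULL
    for (i in seq_along(conditions)) {
      cond <- conditions[[i]]
      args <- simcfg
      if (!is.null(args$dfe)) args$dfe <- do.call(dfe_spec, args$dfe)
      args$seed <- seed + (i - 1L) * 101L
      cfg <- do.call(sim_config, args)
      sim <- simulate_experiment(cfg, condition = cond)
      counts_by_cond[[cond]] <- sim$counts
      fold[[cond]] <- sim$fold
      p <- file.path(out_dir, paste0("counts_", cond, ".tsv"))
      write_counts(sim$counts, p)
      note(p)
      p <- file.path(out_dir, paste0("truth_", cond, ".tsv"))
      write_truth(sim, p)
      note(p)
    }
  } else if (!is.null(config$counts)) {
    for (cond in names(config$counts)) {
      path <- config$counts[[cond]]
      counts_by_cond[[cond]] <- tryCatch(
        read_counts(path),
        error = function(e) stop("stage counts: failed reading ", path,
                                 " for condition ", cond, ": ",
                                 conditionMessage(e), call. = FALSE)
      )
    }
  } else {
    stop("stage counts: config needs a 'simulate' or 'counts' block")
  }

  # --- stage: fit -----------------------------------------------------
  fits <- list()
  fit_cfg <- config$fit %||% list()
  for (cond in names(counts_by_cond)) {
    r <- if (!is.null(fit_cfg$r)) {
      if (length(fit_cfg$r) > 1 || !is.null(names(fit_cfg$r)))
        fit_cfg$r[[cond]] else fit_cfg$r
    } else if (!is.null(fold[[cond]])) {
      fold[[cond]]
    } else if (!is.null(fit_cfg$generations)) {
      2^fit_cfg$generations
    } else {
      stop("stage fit: no fold increase r for condition ", cond)
    }
    fits[[cond]] <- fit_counts(counts_by_cond[[cond]], r = r)
    p <- file.path(out_dir, paste0("fitness_", cond, ".tsv"))
    write_fitness(fits[[cond]], p)
    note(p)
  }

  # --- stage: landscape -----------------------------------------------
  land_cfg <- config$landscape %||% list()
  annotation <- if (!is.null(land_cfg$annotation)) {
    read_annotation(land_cfg$annotation)
  }
  stats_rows <- lapply(names(fits), function(cond) {
    fit <- fits[[cond]]
    agg <- aggregate_substitutions(fit)
    calls <- dual_replica_calls(fit)
    dfe <- dfe_summary(agg$s, deleterious = calls$deleterious)
    tibble::tibble(
      condition = cond,
      pct_deleterious = percent_deleterious(
        fit, class_filter = land_cfg$class_filter %||% "missense"),
      mean_s = dfe$mean_s,
      median_deleterious_s = dfe$median_deleterious_s,
      median_variance = median_variance(fit),
      n_substitutions = nrow(agg)
    )
  })
  p <- file.path(out_dir, "landscape_stats.tsv")
  readr::write_tsv(dplyr::bind_rows(stats_rows), p)
  note(p)

  # --- stage: compare -------------------------------------------------
  if (!is.null(config$compare)) {
    a <- config$compare$a
    b <- config$compare$b
    if (is.null(fits[[a]]) || is.null(fits[[b]])) {
      stop("stage compare: unknown condition ", a, " or ", b)
    }
    p <- file.path(out_dir, paste0("wilcoxon_", a, "_vs_", b, ".tsv"))
    readr::write_tsv(wilcoxon_positions(fits[[a]], fits[[b]]), p)
    note(p)
    p <- file.path(out_dir, paste0("ttest_", a, "_vs_", b, ".tsv"))
    readr::write_tsv(ttest_substitutions(fits[[a]], fits[[b]]), p)
    note(p)
  }

  # --- stage: stability -----------------------------------------------
  if (!is.null(config$stability)) {
    ddg <- read_ddg(config$stability$ddg)
    rows <- lapply(names(fits), function(cond) {
      res <- spearman_fitness_stability(fits[[cond]], ddg)
      tibble::tibble(condition = cond, rho = res$rho, n = res$n,
                     n_dropped = res$n_dropped)
    })
    doms <- if (!is.null(annotation)) names(annotation) else character(0)
    for (dm in doms) {
      for (cond in names(fits)) {
        pos <- unlist(lapply(annotation[[dm]], function(iv) seq(iv[1], iv[2])))
        res <- tryCatch(
          spearman_fitness_stability(fits[[cond]], ddg, positions = pos),
          error = function(e) NULL)
        if (!is.null(res)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            condition = paste0(cond, ":", dm), rho = res$rho, n = res$n,
            n_dropped = res$n_dropped)
        }
      }
    }
    p <- file.path(out_dir, "stability_corr.tsv")
    readr::write_tsv(dplyr::bind_rows(rows), p)
    note(p)
  }

  manifest <- list(
    seed = seed,
    created = format(Sys.time(), tz = "UTC"),
    outputs = lapply(outputs, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
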