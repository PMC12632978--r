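#' Pipeline configuration
#'
#' Collects every setting of the end-to-end screen simulation and analysis.
#' All parameters have working defaults; `registry_path`/`panel_path` of
#' `NULL` use the packaged fixtures.
#'
#' @param registry_path registry TSV (default: packaged 33-binder registry).
#' @param binder_ids optional subset of binder ids (e.g. the 24 prior-work
#'   binders for a pilot-scale run).
#' @param linker_unit,linker_repeats flexible linker (default 2xGGS).
#' @param orientations `"ordered_all"` or `"unordered"`.
#' @param panel_path cell panel TSV (default packaged PBMC panel).
#' @param n_donors,noise_cv donor settings.
#' @param pathways measured pSTAT panel.
#' @param dose_nM screening dose.
#' @param k,min_donors,sem_floor hit-calling settings.
#' @param lambda pSTAT5 leak for flexible constructs.
#' @param dose_grid dose-response grid (nM, must include 0).
#' @param n_dose_constructs how many hit constructs get dose-response triage.
#' @param n_ko_constructs how many ternary hit constructs get knockout tests.
#' @param seed master seed; every stage derives its own stream from it.
#' @param outdir output directory (default `tempfile()`), created on run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(registry_path = NULL, binder_ids = NULL,
                            linker_unit = "GGS", linker_repeats = 2,
                            orientations = "ordered_all",
                            panel_path = NULL, n_donors = 3, noise_cv = 0.15,
                            pathways = c("pSTAT1", "pSTAT3", "pSTAT5", "pSTAT6"),
                            dose_nM = 250, k = 6, min_donors = 2,
                            sem_floor = 0.025, lambda = 0.15,
                            dose_grid = c(0, 0.4, 1.6, 6.4, 25, 100, 400, 1600, 6400),
                            n_dose_constructs = 20, n_ko_constructs = 4,
                            seed = 1, outdir = tempfile("novoscreen_")) {
  cfg <- list(registry_path = registry_path, binder_ids = binder_ids,
              linker_unit = linker_unit, linker_repeats = linker_repeats,
              orientations = orientations, panel_path = panel_path,
              n_donors = n_donors, noise_cv = noise_cv, pathways = pathways,
              dose_nM = dose_nM, k = k, min_donors = min_donors,
              sem_floor = sem_floor, lambda = lambda, dose_grid = dose_grid,
              n_dose_constructs = n_dose_constructs,
              n_ko_constructs = n_ko_constructs,
              seed = as.integer(seed), outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file; keys as in [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0)
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  flat <- cfg[setdiff(names(cfg), "outdir")]
  writeLines(paste(deparse(flat), collapse = ""), f)
  unname(tools::md5sum(f))
}

stage_msg <- function(name, t0) {
  message(sprintf("[novoscreen] %-16s %.2fs", name,
                  as.numeric(proc.time()[["elapsed"]]) - t0))
}

construct_class <- function(manifest_row, receptors) {
  info <- function(r) receptors[match(r, receptors$receptor), ]
  a <- info(manifest_row$receptor_a); b <- info(manifest_row$receptor_b)
  if (any(c(a$receptor, b$receptor) == "IFNAR1")) return("IFNAR1_based")
  fams <- c(a$family, b$family)
  if ("growth_factor" %in% fams &&
      any(fams %in% c("cytokine_common", "cytokine_private")))
    return("cytokine_growth_factor")
  if (all(c(a$chain_class, b$chain_class) == "common")) return("common_common")
  "other"
}

#' Run the full screening pipeline
#'
#' Executes build-library, simulate-screen, call-hits, dose-response and
#' ko-test in sequence, writes every intermediate table to `config$outdir`,
#' and returns (and writes) a summary report. Dose-response triage is run on
#' the top-scoring hit constructs; knockout tests on the top ternary hits
#' (knockouts presuppose a signaling wild type). The report embeds the seed
#' and a hash of the configuration so a stored config reproduces every table
#' byte-identically. Per-stage timing goes to `stderr`.
#'
#' @param config a `pipeline_config`.
#' @return the report, an object of class `novoscreen_report` (also written
#'   as `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(proc.time()[["elapsed"]])
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    res <- tryCatch(force(expr),
                    error = function(e) stopf("pipeline stage '%s' failed: %s",
                                              name, conditionMessage(e)))
    stage_msg(name, t0)
    res
  }

  registry <- run_stage("load-registry", {
    reg <- if (is.null(config$registry_path)) default_registry()
           else load_registry(config$registry_path)
    if (!is.null(config$binder_ids)) reg <- subset_registry(reg, config$binder_ids)
    reg
  })
  panel <- run_stage("load-panel", {
    if (is.null(config$panel_path)) default_cell_panel()
    else load_cell_panel(config$panel_path)
  })

  manifest <- run_stage("build-library", {
    lk <- linker_spec(config$linker_unit, config$linker_repeats)
    m <- enumerate_library(registry, lk, config$orientations)
    write_tsv(m, file.path(config$outdir, "manifest.tsv"))
    m
  })

  truth <- run_stage("plant-truth",
    make_ground_truth(manifest, registry, panel, pathways = config$pathways,
                      lambda = config$lambda,
                      seed = derive_seed(config$seed, "truth")))

  screen <- run_stage("simulate-screen", {
    donors <- donor_profiles(config$n_donors, colnames(panel$density),
                             noise_cv = config$noise_cv,
                             seed = derive_seed(config$seed, "donors"))
    plan <- screen_plan(dose_nM = config$dose_nM, pathways = config$pathways,
                        seed = derive_seed(config$seed, "screen"))
    tab <- generate_screen(manifest, truth, registry, panel, donors, plan)
    write_tsv(tab, file.path(config$outdir, "screen.tsv"))
    tab
  })

  hits <- run_stage("call-hits", {
    h <- call_hits(screen, k = config$k, min_donors = config$min_donors,
                   sem_floor = config$sem_floor)
    write_tsv(h, file.path(config$outdir, "hits.tsv"))
    h
  })

  real <- hits[hits$condition != "single_binder_control", ]
  hit_ids <- unique(real$construct_id[real$reproducible])
  best_score <- vapply(hit_ids, function(id)
    max(real$mean_score[real$construct_id == id & real$reproducible]),
    numeric(1))
  hit_ids <- hit_ids[order(-best_score)]

  # pooled control spread on the fluorescence scale -> dose-response noise floor
  ctrl <- screen[screen$condition == "unstimulated_control", ]
  ckey <- paste(ctrl$donor_id, ctrl$cell_type, ctrl$pathway)
  noise_floor <- 3 * mean(tapply(ctrl$mfi, ckey, stats::sd))

  dose_calls <- run_stage("dose-response", {
    ids <- utils::head(hit_ids, config$n_dose_constructs)
    if (length(ids) == 0) NULL else {
      series <- do.call(rbind, lapply(ids, function(id) {
        generate_dose_series(manifest[manifest$construct_id == id, ], truth,
                             config$dose_grid, registry,
                             noise_cv = config$noise_cv,
                             seed = derive_seed(config$seed, paste0("ds:", id)))
      }))
      calls <- classify_series_table(series, noise_floor = noise_floor)
      write_tsv(calls, file.path(config$outdir, "dose_calls.tsv"))
      calls
    }
  })

  ko <- run_stage("ko-test", {
    tern <- hit_ids[hit_ids %in% truth$construct_id[truth$mechanism == "ternary"]]
    ids <- utils::head(tern, config$n_ko_constructs)
    ko_panel <- default_cell_panel(include_u937 = TRUE,
                                   baseline_mfi = panel$baseline_mfi)
    v <- batch_ko(manifest[match(ids, manifest$construct_id), ],
                  truth = truth, registry = registry, panel = ko_panel,
                  k = config$k, min_donors = config$min_donors,
                  noise_cv = config$noise_cv,
                  seed = derive_seed(config$seed, "ko"))
    write_tsv(v, file.path(config$outdir, "ko_verdicts.tsv"))
    v
  })

  classes <- vapply(hit_ids, function(id)
    construct_class(manifest[match(id, manifest$construct_id), ],
                    registry$receptors), character(1))
  class_counts <- as.list(table(factor(classes,
    levels = c("IFNAR1_based", "cytokine_growth_factor", "common_common",
               "other"))))

  confusion <- NULL
  if (!is.null(dose_calls)) {
    truth_lab <- c(ternary = "saturable", clustering = "non_saturating",
                   inactive = "no_signal")[
      truth$mechanism[match(dose_calls$construct_id, truth$construct_id)]]
    confusion <- table(planted = truth_lab, called = dose_calls$label)
  }

  report <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    library_size = nrow(manifest),
    unique_pairings = count_unique_pairings(manifest),
    n_constructs_screened = nrow(manifest),
    n_reproducible_hit_constructs = length(hit_ids),
    hits_by_class = lapply(class_counts, as.integer),
    activation_rate_by_receptor = as.list(round(
      activation_rate_by_receptor(hits, manifest), 4)),
    dose_response = if (is.null(dose_calls)) NULL else list(
      n_tested = nrow(dose_calls),
      labels = as.list(table(dose_calls$label)),
      confusion = if (is.null(confusion)) NULL else
        as.data.frame(confusion, stringsAsFactors = FALSE)),
    knockout = list(n_tested = nrow(ko),
                    n_dual_dependent = attr(ko, "n_dual_dependent"))
  )
  class(report) <- "novoscreen_report"
  jsonlite::write_json(unclass(report),
                       file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  stage_msg("report", t0)
  report
}

#' @export
print.novoscreen_report <- function(x, ...) {
  cat("novoscreen pipeline report\n")
  cat(sprintf("  library: %d constructs, %d unique receptor pairings\n",
              x$library_size, x$unique_pairings))
  cat(sprintf("  reproducible hit constructs: %d\n",
              x$n_reproducible_hit_constructs))
  cat("  hits by mechanistic class:",
      paste(sprintf("%s=%d", names(x$hits_by_class),
                    unlist(x$hits_by_class)), collapse = ", "), "\n")
  if (!is.null(x$dose_response))
    cat("  dose-response labels:",
        paste(sprintf("%s=%s", names(x$dose_response$labels),
                      unlist(x$dose_response$labels)), collapse = ", "), "\n")
  cat(sprintf("  knockout: %d of %d tested constructs dual-dependent\n",
              x$knockout$n_dual_dependent, x$knockout$n_tested))
  cat(sprintf("  seed %d, config %s\n", x$seed, x$config_hash))
  invisible(x)
}
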