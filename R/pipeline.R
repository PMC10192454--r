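# End-to-end orchestration: configuration, the staged pipeline
# (ingest/simulate -> compatibility -> traits -> heterosis -> multivariate),
# result serialization and a plain-text report.

#' Pipeline configuration
#'
#' Builds (and validates) the configuration for [run_pipeline()]. Exactly one
#' input source must be given: \code{input} (paths to pollination/trait
#' tables, or a packaged fixture name) or \code{simulate} (simulator
#' parameters, see [sim_params()]).
#'
#' @param input \code{NULL}, or a list with any of \code{pollination} /
#'   \code{traits} (file paths) or \code{fixture}
#'   (\code{"gx1_self"}/\code{"mx2_self"}).
#' @param simulate \code{NULL}, or a list of [sim_params()] arguments plus
#'   optionally \code{n_singles}, \code{n_doubles}.
#' @param aggregate replicate aggregation for pod set percentages.
#' @param alpha significance level for group tests.
#' @param standard1,standard2 standard-variety labels for economic heterosis.
#' @param heterosis_traits traits scored for heterosis.
#' @param retain_pct,k,k_range clustering controls (see [hcpc_cluster()]).
#' @param out_dir output directory (\code{NULL}: nothing is written).
#' @param seed integer seed (simulation and any other randomness).
#' @return list of class \code{"kola_config"}.
#' @export
kola_config <- function(input = NULL, simulate = NULL,
                        aggregate = "pooled", alpha = 0.05,
                        standard1 = "GX1/46 × GX1/16",
                        standard2 = "JX1/5 × JX1/9",
                        heterosis_traits = c("pod_set", "outturn", "brix"),
                        retain_pct = 80, k = "auto", k_range = 3:6,
                        out_dir = NULL, seed = 1L) {
  if (is.null(input) == is.null(simulate)) {
    stop_kola("exactly one of `input` and `simulate` must be given",
              class = "kola_config_error")
  }
  if (!is.null(input)) {
    for (p in c(input$pollination, input$traits)) {
      if (!file.exists(p)) {
        stop_kola("input file not found: ", p, class = "kola_config_error")
      }
    }
  }
  structure(
    list(input = input, simulate = simulate, aggregate = aggregate,
         alpha = alpha, standard1 = standard1, standard2 = standard2,
         heterosis_traits = heterosis_traits, retain_pct = retain_pct,
         k = k, k_range = k_range, out_dir = out_dir, seed = as.integer(seed)),
    class = "kola_config"
  )
}

#' Read a pipeline configuration file
#'
#' YAML (JSON is a subset accepted by the YAML parser) with the same keys as
#' [kola_config()].
#'
#' @param path config file path.
#' @param ... overrides applied on top of the file's keys.
#' @return a \code{kola_config}.
#' @export
read_kola_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  do.call(kola_config, cfg)
}

ingest_stage <- function(config) {
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    n_singles <- sim_args$n_singles %||% 20
    n_doubles <- sim_args$n_doubles %||% 0
    sim_args$n_singles <- sim_args$n_doubles <- NULL
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    params <- do.call(sim_params, sim_args)
    pop <- make_population(params)
    design <- make_crossing_design(pop, n_singles = n_singles,
                                   n_doubles = n_doubles, seed = params$seed)
    sim <- simulate_crossing_trial(pop, design, params)
    list(dataset = sim$dataset, sim = sim)
  } else {
    inp <- config$input
    if (!is.null(inp$fixture)) {
      list(dataset = kola_dataset(traits = kola_fixture(inp$fixture),
                                  metadata = list(fixture = inp$fixture)),
           sim = NULL)
    } else {
      poll <- if (!is.null(inp$pollination))
        read_cross_table(inp$pollination, "pollination")
      traits <- if (!is.null(inp$traits))
        read_cross_table(inp$traits, "trait")
      list(dataset = kola_dataset(pollinations = poll, traits = traits),
           sim = NULL)
    }
  }
}

#' Run the full crossing-trial analysis pipeline
#'
#' Stages, in order: ingest (or simulate), compatibility summary and
#' cross-type contrasts, trait summaries and group tests, heterosis table,
#' multivariate characterisation (PCA, Ward clusters with v-test category
#' description, trait correlations), then serialization of all stage outputs
#' plus a machine-readable summary. Identical configuration and seed give
#' identical outputs.
#'
#' @param config a [kola_config()] (or path to a YAML config file).
#' @param quiet suppress progress messages.
#' @return list of class \code{"kola_run_report"}: stage results, per-stage
#'   record counts, accumulated warnings, output file manifest, config echo
#'   and package version.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  if (is.character(config)) config <- read_kola_config(config)
  stopifnot(inherits(config, "kola_config"))
  notes <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    notes <<- c(notes, msg)
    if (!quiet) message(msg)
  }

  ing <- ingest_stage(config)
  dataset <- ing$dataset
  results <- list(dataset = dataset, sim = ing$sim)

  # -- compatibility ---------------------------------------------------------
  compat <- tryCatch(
    compatibility_summary(dataset, aggregate = config$aggregate),
    error = function(e) {
      stop_kola("[compatibility] ", conditionMessage(e),
                class = "kola_stage_error")
    }
  )
  results$compatibility <- compat
  types_present <- table(compat$cross_type)
  contrast_pairs <- list(c("DCC", "DCS"), c("SCC", "SCS"))
  contrasts <- list()
  if (!is.null(dataset$pollinations)) {
    for (pair in contrast_pairs) {
      if (all(pair %in% names(types_present)) &&
          all(types_present[pair] >= 2)) {
        for (outc in c("pod", "pseudo")) {
          contrasts[[paste(pair[1], pair[2], outc, sep = "_")]] <-
            cross_type_podset_test(dataset$pollinations, groups = pair,
                                   outcome = outc)
        }
      }
    }
  }
  if (!length(contrasts)) note("no cross-type contrast possible (fewer than two eligible cross types with counts)")
  results$contrasts <- contrasts
  occupied <- length(unique(compat$compat_class[!is.na(compat$compat_class)]))
  results$class_distribution <- if (occupied >= 2)
    class_distribution_test(compat$compat_class) else NULL

  # -- traits ----------------------------------------------------------------
  if (!is.null(dataset$traits)) {
    results$trait_summary <- summarize_traits(dataset)
    results$trait_pooled <- trait_table_summary(dataset)
    tests <- list()
    if (length(unique(compat$cross_type)) >= 2) {
      for (tr in intersect(TRAIT_COLUMNS, names(dataset$traits))) {
        tests[[tr]] <- tryCatch(
          trait_group_test(dataset$traits, trait = tr, alpha = config$alpha),
          error = function(e) NULL
        )
      }
    } else {
      note("single cross type: trait group tests skipped")
    }
    results$trait_tests <- Filter(Negate(is.null), tests)
  }

  # -- heterosis -------------------------------------------------------------
  het <- compute_heterosis_table(
    dataset, traits = config$heterosis_traits,
    standard1 = config$standard1, standard2 = config$standard2,
    aggregate = config$aggregate
  )
  if (nrow(het) == 0) note("no hybrid crosses: heterosis table empty")
  undef <- unique(het$cross_label[is.na(het$mph_pct)])
  results$heterosis <- het

  # -- multivariate ----------------------------------------------------------
  if (!is.null(dataset$traits) && nrow(dataset$traits) >= 3) {
    pca <- pca_standardized(dataset$traits)
    clusters <- tryCatch(
      hcpc_cluster(pca, k = config$k, retain_pct = config$retain_pct,
                   k_range = config$k_range),
      error = function(e) {
        note("clustering skipped: ", conditionMessage(e)); NULL
      }
    )
    results$pca <- pca
    results$clusters <- clusters
    results$correlations <- correlation_matrix(dataset$traits)
  } else {
    note("fewer than 3 trait records: multivariate stage skipped")
  }

  report <- structure(
    list(results = results,
         counts = list(
           crosses = length(dataset_labels(dataset)),
           pollination_records = if (is.null(dataset$pollinations)) 0L else
             nrow(dataset$pollinations),
           trait_records = if (is.null(dataset$traits)) 0L else
             nrow(dataset$traits),
           heterosis_rows = nrow(het)
         ),
         warnings = notes,
         undefined_heterosis = undef,
         manifest = character(0),
         config = config,
         version = as.character(utils::packageVersion("kolacross"))),
    class = "kola_run_report"
  )

  if (!is.null(config$out_dir)) {
    report$manifest <- write_pipeline_outputs(report, config$out_dir)
  }
  report
}

write_pipeline_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- report$results
  manifest <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    manifest <<- c(manifest, p)
  }
  put_csv(as.data.frame(res$compatibility), "compatibility.csv")
  if (!is.null(res$trait_summary)) put_csv(res$trait_summary,
                                           "trait_summary.csv")
  if (nrow(res$heterosis)) put_csv(as.data.frame(res$heterosis),
                                   "heterosis.csv")
  if (!is.null(res$clusters)) {
    put_csv(data.frame(cross_label = names(res$clusters$assignments),
                       cluster = as.integer(res$clusters$assignments)),
            "clusters.csv")
    if (!is.null(res$clusters$category_stats)) {
      put_csv(res$clusters$category_stats, "category_stats.csv")
    }
  }
  if (!is.null(res$correlations)) {
    put_csv(as.data.frame(res$correlations$r), "correlations.csv")
  }
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(run_summary(report), summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  manifest <- c(manifest, summary_path)
  report_path <- file.path(dir, "report.txt")
  writeLines(render_report(report), report_path)
  c(manifest, report_path)
}

# Machine-readable run summary (deterministic for a fixed config + seed; no
# timestamps).
run_summary <- function(report) {
  res <- report$results
  list(
    package_version = report$version,
    seed = report$config$seed,
    counts = report$counts,
    warnings = report$warnings,
    contrasts = lapply(res$contrasts, function(ct) {
      list(groups = ct$groups, outcome = ct$outcome,
           statistic = ct$statistic, p_value = ct$p_value,
           group_pct = as.list(ct$group_pct), separation = ct$separation)
    }),
    class_counts = if (!is.null(res$class_distribution))
      as.list(stats::setNames(as.integer(res$class_distribution$counts),
                              paste0("class", 0:5))) else NULL,
    clusters = if (!is.null(res$clusters))
      list(k = res$clusters$k,
           sizes = as.integer(table(res$clusters$assignments))) else NULL,
    undefined_heterosis = report$undefined_heterosis
  )
}

top_n_by <- function(df, label_col, value_col, n = 5) {
  keep <- !is.na(df[[value_col]])
  d <- df[keep, ]
  # deterministic: value descending, then label lexicographic
  d <- d[order(-d[[value_col]], d[[label_col]], method = "radix"), ]
  utils::head(d[, c(label_col, value_col)], n)
}

#' Human-readable pipeline report
#'
#' Stable-ordered plain text: record counts, the top crosses by pod set and
#' by each heterosis statistic (ties broken by label), contrast and cluster
#' summaries.
#'
#' @param report a \code{kola_run_report}.
#' @param n how many top crosses to list per ranking.
#' @return character vector of lines.
#' @export
render_report <- function(report, n = 5) {
  res <- report$results
  lines <- c(
    "kola crossing-trial analysis",
    sprintf("crosses: %d | pollination records: %d | trait records: %d",
            report$counts$crosses, report$counts$pollination_records,
            report$counts$trait_records)
  )
  if (report$counts$crosses == 0) {
    return(c(lines, "warning: zero crosses in input"))
  }
  compat <- res$compatibility
  lines <- c(lines, "", sprintf("top %d crosses by pod set (%%):", n))
  top <- top_n_by(as.data.frame(compat), "cross_label", "pod_set_pct", n)
  lines <- c(lines, sprintf("  %-40s %6.1f", top$cross_label,
                            top$pod_set_pct))
  for (ct in res$contrasts) {
    lines <- c(lines, sprintf(
      "contrast %s vs %s (%s): %.1f%% vs %.1f%%, LR = %.3g, p = %.3g",
      ct$groups[1], ct$groups[2], ct$outcome,
      ct$group_pct[1], ct$group_pct[2], ct$statistic, ct$p_value))
  }
  het <- as.data.frame(res$heterosis)
  if (nrow(het)) {
    for (stat in c("mph_pct", "bph_pct", "ech1_pct", "ech2_pct")) {
      if (all(is.na(het[[stat]]))) next
      lines <- c(lines, "", sprintf("top %d crosses by %s:", n, stat))
      for (tr in unique(het$trait)) {
        sub <- het[het$trait == tr, ]
        top <- top_n_by(sub, "cross_label", stat, n)
        if (!nrow(top)) next
        lines <- c(lines, sprintf("  [%s]", tr),
                   sprintf("    %-40s %8.2f", top$cross_label, top[[stat]]))
      }
    }
  }
  if (!is.null(res$clusters)) {
    sizes <- table(res$clusters$assignments)
    lines <- c(lines, "",
               sprintf("clusters: k = %d (%s)", res$clusters$k,
                       paste(sprintf("c%s=%d", names(sizes),
                                     as.integer(sizes)), collapse = ", ")))
  }
  if (length(report$warnings)) {
    lines <- c(lines, "", paste0("note: ", report$warnings))
  }
  lines
}

#' @export
print.kola_run_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
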