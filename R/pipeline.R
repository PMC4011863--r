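# End-to-end orchestration: climate summarization -> evolutionary model
# selection -> PGLS battery -> signal battery -> report bundle.

#' Assemble and validate an analysis configuration
#'
#' @param tree Path to a Newick file or a `"phylo"` object.
#' @param traits Path to a CSV/TSV trait table or a data frame; must carry
#'   a `species` column. Any climate-summary columns it contains are
#'   recomputed from `localities` when those are supplied.
#' @param localities Optional path or data frame of locality records.
#' @param out_dir Output directory for the report bundle.
#' @param pairs PGLS pairings (`response`, `predictor`); default
#'   [default_pgls_pairs()].
#' @param signal_variables Variables for the signal battery; default
#'   [default_signal_variables()].
#' @param model_variables Variables for BM/OU/lambda model comparison;
#'   defaults to `signal_variables`.
#' @param method `"lambda"`, `"ou"` or `"both"` PGLS batteries.
#' @param temperature_units Unit declaration for locality temperatures
#'   (`"celsius"` or `"worldclim-raw"`); mandatory when `localities` is a
#'   file path.
#' @param elevation_bounds Optional length-2 vector of accepted elevations
#'   (m); when given, localities are vetted before summarization.
#' @param seed Integer seed (drives the OU restart starts).
#' @param alpha_level Significance threshold for report flags.
#' @return A validated `"analysis_config"` list.
#' @export
analysis_config <- function(tree, traits, out_dir, localities = NULL,
                            pairs = default_pgls_pairs(),
                            signal_variables = default_signal_variables(),
                            model_variables = NULL,
                            method = c("lambda", "ou", "both"),
                            temperature_units = c("celsius",
                                                  "worldclim-raw"),
                            elevation_bounds = NULL, seed = 20140506,
                            alpha_level = 0.05) {
  method <- match.arg(method)
  temperature_units <- match.arg(temperature_units)
  if (is.character(tree) && !file.exists(tree))
    stop("tree file not found: ", tree)
  if (is.character(traits) && !file.exists(traits))
    stop("trait table not found: ", traits)
  if (is.character(localities) && !file.exists(localities))
    stop("locality table not found: ", localities)
  if (!is.null(elevation_bounds) && length(elevation_bounds) != 2)
    stop("`elevation_bounds` must be c(min, max)")
  structure(list(tree = tree, traits = traits, localities = localities,
                 out_dir = out_dir, pairs = pairs,
                 signal_variables = signal_variables,
                 model_variables = model_variables %||% signal_variables,
                 method = method, temperature_units = temperature_units,
                 elevation_bounds = elevation_bounds, seed = seed,
                 alpha_level = alpha_level),
            class = "analysis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_table_auto <- function(x) {
  if (is.data.frame(x)) return(x)
  header <- readLines(x, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

round_numeric <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

write_report_table <- function(df, path) {
  utils::write.table(round_numeric(df), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Run the full comparative analysis and write a report bundle
#'
#' Stages, in order: (1) read and validate inputs; (2) vet localities (when
#' elevation bounds are configured) and reduce them to species climate
#' summaries with logQ/logQ2, merged into the trait table under the
#' analysis variable names; (3) BM/OU/lambda model comparison per
#' configured variable with the delta-AIC >= 4 rule; (4) the PGLS pair
#' battery under the ML-lambda model (and/or the OU transform); (5) the
#' Pagel's-lambda signal battery; (6) a run log with seed, stage record
#' counts and package version. Any stage failure aborts with the stage
#' name and removes partial outputs. Identical inputs and seed give
#' byte-identical output tables. No multiple-testing correction is applied
#' anywhere; significance flags are raw p < `alpha_level`.
#'
#' @param config An `"analysis_config"` from [analysis_config()].
#' @return Invisibly, a list with `climate_summaries`, `model_comparison`,
#'   `pgls` (named by method), `signal` and the output paths.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$out_dir,
                     c("climate_summaries.csv", "model_comparison.tsv",
                       "pgls_lambda.tsv", "pgls_ou.tsv", "signal.tsv",
                       "run_log.txt"))
  names(paths) <- c("climate", "models", "pgls_lambda", "pgls_ou",
                    "signal", "log")
  st <- new.env(parent = emptyenv())
  st$written <- character()
  st$log <- c(sprintf("spadefoot run_analysis | package %s | seed %d",
                      as.character(utils::packageVersion("spadefoot")),
                      as.integer(config$seed)))
  append_log <- function(msg) st$log <- c(st$log, msg)
  mark_written <- function(p) st$written <- c(st$written, p)
  fail <- function(stage, e) {
    unlink(st$written)
    stop("stage `", stage, "` failed: ", conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  tree <- stage("read_tree", {
    if (inherits(config$tree, "phylo")) config$tree else
      read_newick(file = config$tree)
  })
  traits <- stage("read_traits", {
    tt <- read_table_auto(config$traits)
    if (!"species" %in% names(tt)) stop("trait table lacks `species`")
    missing_sp <- setdiff(tt$species, tree$tip.label)
    if (length(missing_sp) > 0)
      stop("species absent from tree: ", paste(missing_sp, collapse = ", "))
    tt
  })

  summaries <- NULL
  if (!is.null(config$localities)) {
    summaries <- stage("climate_summaries", {
      loc <- if (is.data.frame(config$localities))
        validate_localities(config$localities)
      else read_locality_table(config$localities,
                               temperature_units = config$temperature_units)
      n_raw <- nrow(loc)
      if (!is.null(config$elevation_bounds)) {
        vet <- vet_localities(loc, config$elevation_bounds[1],
                              config$elevation_bounds[2])
        loc <- vet$kept
        append_log(sprintf(
          "vet_localities: %d records in, %d kept, %d log entries",
          n_raw, nrow(loc), nrow(vet$log)))
      }
      s <- summarize_species(loc)
      append_log(sprintf("climate_summaries: %d species, %d localities",
                         nrow(s), nrow(loc)))
      s
    })
    traits <- stage("merge_climate", {
      clim <- climate_summary_variables(summaries)
      keep <- setdiff(names(traits), setdiff(names(clim), "species"))
      merge(traits[keep], clim, by = "species", sort = FALSE)
    })
  }

  stage("validate_config", {
    need <- unique(c(config$pairs$response, config$pairs$predictor,
                     config$signal_variables, config$model_variables))
    unknown <- setdiff(need, names(traits))
    if (length(unknown) > 0)
      stop("configured variable(s) not in trait table: ",
           paste(unknown, collapse = ", "), "; available: ",
           paste(setdiff(names(traits), "species"), collapse = ", "))
  })

  model_cmp <- stage("model_comparison", {
    rows <- lapply(config$model_variables, function(v) {
      yv <- stats::setNames(traits[[v]], traits$species)
      keep <- names(yv)[!is.na(yv)]
      tr <- if (length(keep) < length(tree$tip.label))
        ape::keep.tip(tree, keep) else tree
      cmp <- model_table(yv[tr$tip.label], tr, seed = config$seed)
      data.frame(variable = v, n = length(keep),
                 model = names(cmp$aic),
                 loglik = vapply(cmp$fits, `[[`, numeric(1), "loglik"),
                 aic = cmp$aic, delta_aic = cmp$delta_aic,
                 preferred = names(cmp$aic) %in% cmp$preferred,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    append_log(sprintf("model_comparison: %d variables x 3 models",
                       length(config$model_variables)))
    out
  })

  methods <- if (config$method == "both") c("lambda", "ou") else config$method
  pgls_tables <- stage("pgls_battery", {
    out <- lapply(methods, function(m) {
      tab <- run_pair_battery(traits, tree, pairs = config$pairs,
                              method = m,
                              alpha_level = config$alpha_level,
                              seed = config$seed)
      append_log(sprintf("pgls_battery[%s]: %d pairs", m, nrow(tab)))
      tab
    })
    names(out) <- methods
    out
  })

  signal_tab <- stage("signal_battery", {
    tab <- signal_battery(traits, tree,
                          variables = config$signal_variables)
    append_log(sprintf("signal_battery: %d variables", nrow(tab)))
    tab
  })

  stage("write_outputs", {
    if (!is.null(summaries)) {
      utils::write.csv(round_numeric(summaries), paths["climate"],
                       row.names = FALSE)
      mark_written(paths["climate"])
    }
    write_report_table(model_cmp, paths["models"])
    mark_written(paths["models"])
    for (m in methods) {
      p <- paths[paste0("pgls_", m)]
      write_report_table(pgls_tables[[m]], p)
      mark_written(p)
    }
    write_report_table(signal_tab, paths["signal"])
    mark_written(paths["signal"])
    append_log("note: raw p-values; no multiple-testing correction applied")
    writeLines(st$log, paths["log"])
    mark_written(paths["log"])
  })

  invisible(list(climate_summaries = summaries,
                 model_comparison = model_cmp, pgls = pgls_tables,
                 signal = signal_tab,
                 paths = paths[file.exists(paths)]))
}
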