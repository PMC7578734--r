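#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the defaults of
#' the published CSAP run: minimum antecedent support 15\%, minimum
#' confidence 80\%, rules of at most 3 items, antecedent-support reporting,
#' all co-occurring pairs kept as network edges.
#'
#' @param input path to a transaction file, or a \code{transactions} object.
#' @param input_format \code{"long"} or \code{"wide"} (ignored when
#'   \code{input} is already a \code{transactions} object).
#' @param registry an \code{acu_registry}, a registry file path, or
#'   \code{NULL} for none.
#' @param min_support_pct,min_confidence_pct thresholds in (0, 100].
#' @param max_rule_size cap on rule size (antecedent plus consequent).
#' @param support_convention \code{"antecedent"} or \code{"joint"}.
#' @param min_weight minimum co-occurrence count for a network edge.
#' @param layout_seed,layout_iterations Fruchterman-Reingold layout seed and
#'   iteration count.
#' @param out_dir output directory (created if absent).
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input, input_format = c("long", "wide"),
                            registry = NULL,
                            min_support_pct = 15, min_confidence_pct = 80,
                            max_rule_size = 3L,
                            support_convention = c("antecedent", "joint"),
                            min_weight = 1L,
                            layout_seed = 42L, layout_iterations = 150L,
                            out_dir = ".") {
  input_format <- match.arg(input_format)
  support_convention <- match.arg(support_convention)
  stopifnot(min_support_pct > 0, min_support_pct <= 100,
            min_confidence_pct > 0, min_confidence_pct <= 100,
            max_rule_size >= 2L, min_weight >= 1L)
  structure(list(input = input, input_format = input_format,
                 registry = registry,
                 min_support_pct = min_support_pct,
                 min_confidence_pct = min_confidence_pct,
                 max_rule_size = max_rule_size,
                 support_convention = support_convention,
                 min_weight = min_weight,
                 layout_seed = layout_seed,
                 layout_iterations = layout_iterations,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full prescription-mining pipeline
#'
#' Orchestrates the individual stages -- load, frequency tables, rule
#' mining, co-occurrence matrix, network construction, layout and export --
#' and writes every result plus a run manifest to the output directory.
#' The pipeline is a plain composition of the exported stage functions (no
#' hidden state), and identical input plus configuration yields
#' byte-identical outputs (the layout is seeded).
#'
#' Files written: \code{acupoint_frequency.csv},
#' \code{meridian_frequency.csv}, \code{rules.csv},
#' \code{cooccurrence_counts.csv}, \code{cooccurrence_normalized.csv},
#' \code{graph_stats.csv}, \code{nodes.csv}, \code{edges.csv},
#' \code{manifest.txt}.
#'
#' @param config a \code{pipeline_config}.
#' @param quiet suppress per-stage log lines.
#' @return Invisibly, a list with the in-memory results (\code{dataset},
#'   \code{acupoint_freq}, \code{meridian_freq}, \code{rules},
#'   \code{cooccurrence}, \code{network}, \code{stats}, \code{layout}) and
#'   \code{files}, the named vector of written paths.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(pipeline_config(build_csap_fixture(),
#'                                     out_dir = tempfile()))
#' out$stats
#' }
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
  }
  registry <- config$registry
  if (is.character(registry)) registry <- read_registry(registry)

  input_checksum <- NA_character_
  if (inherits(config$input, "transactions")) {
    dataset <- config$input
  } else {
    dataset <- load_transactions(config$input, config$input_format,
                                 registry = registry)
    input_checksum <- unname(tools::md5sum(config$input))
  }
  log("load", dataset$N, " prescriptions, ", length(dataset$universe),
      " acupoints, ", dataset$total_usages, " usages")

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  files <- c()

  af <- acupoint_frequency(dataset)
  write_frequency_table(af, path("acupoint_frequency.csv"))
  mf <- meridian_frequency(dataset, registry)
  write_frequency_table(mf, path("meridian_frequency.csv"))
  files <- c(files, acupoint_frequency = path("acupoint_frequency.csv"),
             meridian_frequency = path("meridian_frequency.csv"))
  log("freq", nrow(af), " acupoint rows, ", nrow(mf), " meridian rows")

  rules <- mine_rules(dataset, config$min_support_pct,
                      config$min_confidence_pct, config$max_rule_size,
                      config$support_convention)
  write_rules(rules, path("rules.csv"))
  files <- c(files, rules = path("rules.csv"))
  log("rules", nrow(rules), " rules at (", config$min_support_pct, "%, ",
      config$min_confidence_pct, "%)")

  cm <- cooccurrence_matrix(dataset)
  write_cooccurrence(cm, path("cooccurrence_counts.csv"),
                     path("cooccurrence_normalized.csv"))
  files <- c(files, cooccurrence_counts = path("cooccurrence_counts.csv"),
             cooccurrence_normalized = path("cooccurrence_normalized.csv"))
  log("cooc", length(cm$items), " x ", length(cm$items), " matrix")

  net <- build_network(dataset, config$min_weight)
  st <- graph_stats(net)
  stats_df <- data.frame(metric = c("node_count", "edge_count",
                                    "average_degree", "average_path_length",
                                    "diameter", "component_size"),
                         value = c(st$node_count, st$edge_count,
                                   st$average_degree, st$average_path_length,
                                   st$diameter, st$component_size))
  utils::write.table(stats_df, path("graph_stats.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  lay <- fr_layout(net, iterations = config$layout_iterations,
                   seed = config$layout_seed)
  export_graph(net, lay, path("nodes.csv"), path("edges.csv"))
  files <- c(files, graph_stats = path("graph_stats.csv"),
             nodes = path("nodes.csv"), edges = path("edges.csv"))
  log("network", st$node_count, " nodes, ", st$edge_count, " edges")

  manifest <- c(
    sprintf("package: acumine %s",
            as.character(utils::packageVersion("acumine"))),
    sprintf("input: %s", if (inherits(config$input, "transactions"))
      "<in-memory transactions>" else config$input),
    sprintf("input_md5: %s", input_checksum),
    sprintf("min_support_pct: %s", config$min_support_pct),
    sprintf("min_confidence_pct: %s", config$min_confidence_pct),
    sprintf("max_rule_size: %s", config$max_rule_size),
    sprintf("support_convention: %s", config$support_convention),
    sprintf("min_weight: %s", config$min_weight),
    sprintf("layout_seed: %s", config$layout_seed),
    sprintf("layout_iterations: %s", config$layout_iterations))
  writeLines(manifest, path("manifest.txt"))
  files <- c(files, manifest = path("manifest.txt"))

  invisible(list(dataset = dataset, acupoint_freq = af, meridian_freq = mf,
                 rules = rules, cooccurrence = cm, network = net,
                 stats = st, layout = lay, files = files))
}
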