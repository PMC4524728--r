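# End-to-end orchestration: config, staged analysis, report and artifacts.

#' Analysis configuration
#'
#' Materializes every tunable of the full topology analysis with its default.
#' Exactly one of `edges_path` (a scored edge-list TSV) or `network` (an
#' `igraph` object already in memory) must be supplied when the config is
#' run.
#'
#' @param edges_path Optional path to a scored edge list for
#'   [read_scored_edges()].
#' @param network Optional in-memory `igraph` network (takes precedence).
#' @param score_min Edge confidence threshold (default 0.4).
#' @param n_null Null-ensemble size (default 1000).
#' @param seed Integer seed governing every stochastic stage (default 42).
#' @param rho_min Rich-club regime threshold (default 1).
#' @param sd_mult Central-core z threshold (default 3).
#' @param degree_cutoff,node_score_cutoff,k_core,max_depth MCODE parameters.
#' @param min_module_size Strict module size filter (default 3).
#' @param n_random_triads Random triads in the perturbation stage.
#' @param swaps_per_edge Rewiring effort per null member.
#' @param gmt_path Optional GMT annotation collection for enrichment.
#' @param enrich_mode `"ease"` or `"fisher"`.
#' @param exhaustive_max Node limit for exhaustive knotty search fallbacks.
#' @param apl_scope Average-path-length convention (see
#'   [average_path_length()]).
#' @param out_dir Optional directory for artifacts (TSV/JSON/GraphML).
#' @return A `netarch_config` list with all defaults materialized.
#' @export
netarch_config <- function(edges_path = NULL, network = NULL,
                           score_min = 0.4, n_null = 1000L, seed = 42L,
                           rho_min = 1, sd_mult = 3, degree_cutoff = 2L,
                           node_score_cutoff = 0.2, k_core = 2L,
                           max_depth = 100L, min_module_size = 3L,
                           n_random_triads = 100L, swaps_per_edge = 10,
                           gmt_path = NULL, enrich_mode = "ease",
                           exhaustive_max = 12L,
                           apl_scope = "connected_pairs", out_dir = NULL) {
  structure(
    list(edges_path = edges_path, network = network, score_min = score_min,
         n_null = as.integer(n_null), seed = as.integer(seed),
         rho_min = rho_min, sd_mult = sd_mult,
         degree_cutoff = as.integer(degree_cutoff),
         node_score_cutoff = node_score_cutoff, k_core = as.integer(k_core),
         max_depth = as.integer(max_depth),
         min_module_size = as.integer(min_module_size),
         n_random_triads = as.integer(n_random_triads),
         swaps_per_edge = swaps_per_edge, gmt_path = gmt_path,
         enrich_mode = enrich_mode,
         exhaustive_max = as.integer(exhaustive_max),
         apl_scope = apl_scope, out_dir = out_dir),
    class = "netarch_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [netarch_config()]
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `netarch_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(netarch_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(netarch_config, vals)
}

pipeline_triad <- function(tab, core) {
  if (length(core) == 3L) return(core)
  z_sum <- tab$z_degree + tab$z_closeness + tab$z_betweenness
  ok <- !is.na(z_sum)
  tab$node[ok][order(-z_sum[ok], tab$node[ok])][seq_len(min(3L, sum(ok)))]
}

#' Run the full topology analysis
#'
#' Executes the staged pipeline: load -> global metrics -> null ensemble ->
#' rich-club profile/regime/significance/membership -> centrality table and
#' central core -> rich-club modules (MCODE on the club subgraph, size
#' filter, collapse of club nodes into module supernodes) -> knotty centres
#' of the full network, the club subgraph and the collapsed network, with
#' their overlaps and the module share of the collapsed centre -> triad
#' perturbation (the central core when it has exactly 3 nodes, otherwise the
#' top 3 nodes by summed centrality z-scores; comparison pool = other club
#' members) -> optional GMT enrichment of the club. Every stochastic stage
#' derives its seed from `config$seed`, so a config reproduces its report
#' exactly (modulo timings). A failed stage is recorded in `$errors` and
#' later stages that can still run do so.
#'
#' @param config A [netarch_config()].
#' @return A `netarch_report` list: `network` summary, `global_metrics`,
#'   `rich_club` (profile, regime, significance, members), `centrality`
#'   (table, core, top_brokers), `modules` (module_set, filtered, collapsed),
#'   `knotty` (full/club/collapsed centres, overlaps, module share),
#'   `perturbation`, `enrichment`, `errors`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "netarch_config"))
    stop("`config` must be a netarch_config", call. = FALSE)
  report <- list(errors = list())
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    st <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    out
  }

  net <- stage("load", {
    if (!is.null(config$network)) {
      assert_network(config$network, "config$network")
      config$network
    } else if (!is.null(config$edges_path)) {
      read_scored_edges(config$edges_path, config$score_min)
    } else {
      stop("config must supply `network` or `edges_path`")
    }
  })
  if (is.null(net)) {
    report$manifest <- list(config = config[setdiff(names(config), "network")],
                            timings = timings)
    class(report) <- "netarch_report"
    return(report)
  }
  report$network <- list(n_nodes = igraph::vcount(net),
                         n_edges = igraph::ecount(net))

  report$global_metrics <- stage("metrics",
    global_metrics(net, apl_scope = config$apl_scope))

  ensemble <- NULL
  if (igraph::ecount(net) >= 2L)
    ensemble <- stage("nulls",
      make_null_ensemble(net, n = config$n_null, seed = config$seed,
                         swaps_per_edge = config$swaps_per_edge))

  profile <- NULL; regime <- NULL; members <- character(0L)
  if (!is.null(ensemble)) {
    profile <- stage("richclub", rich_club_profile(net, ensemble))
    if (!is.null(profile)) {
      regime <- detect_regime(profile, config$rho_min)
      sig <- regime_significance(profile, regime)
      members <- club_members(net, regime)
      report$rich_club <- list(profile = profile, regime = regime,
                               significance = sig, members = members)
      report$small_world_index <-
        stage("smallworld", small_world_index(net, ensemble))
    }
  }

  tab <- stage("centrality", centrality_table(net))
  core <- character(0L)
  if (!is.null(tab)) {
    core <- suppressWarnings(central_core(tab, config$sd_mult))
    report$centrality <- list(
      table = tab, core = core,
      top_brokers = top_brokers(tab, n = 20L))
  }

  modules <- NULL; collapsed <- NULL
  club_graph <- if (length(members) >= 2L)
    igraph::induced_subgraph(net, members) else NULL
  if (!is.null(club_graph)) {
    modules <- stage("modules", {
      ms <- mcode_find(club_graph, degree_cutoff = config$degree_cutoff,
                       node_score_cutoff = config$node_score_cutoff,
                       k_core = config$k_core, max_depth = config$max_depth)
      filtered <- filter_modules(ms, config$min_module_size)
      list(all = ms, filtered = filtered)
    })
    if (!is.null(modules)) {
      collapsed <- stage("collapse",
        collapse_modules(net, modules$filtered, restrict_to = members))
      report$modules <- list(all = modules$all, filtered = modules$filtered,
                             collapsed = collapsed)
    }
  }

  report$knotty <- stage("knotty", {
    centre_of <- function(g) {
      if (is.null(g) || igraph::vcount(g) < 3L || igraph::ecount(g) < 2L)
        return(NULL)
      find_knotty_centre(g, method = "heuristic", seed = config$seed)
    }
    full <- centre_of(net)
    club <- centre_of(club_graph)
    coll <- centre_of(collapsed)
    overlaps <- if (!is.null(full) && !is.null(club))
      overlap_fraction(full$members, club$members) else NULL
    module_share <- if (!is.null(coll)) {
      is_mod <- igraph::V(collapsed)$is_module[
        match(coll$members, igraph::V(collapsed)$name)]
      mean(is_mod)
    } else NULL
    list(full = full, club = club, collapsed = coll,
         overlap_full_club = overlaps,
         collapsed_module_share = module_share)
  })

  if (!is.null(tab) && length(members) >= 6L) {
    report$perturbation <- stage("perturbation", {
      triad <- pipeline_triad(tab, core)
      pool <- setdiff(members, triad)
      if (length(triad) == 3L && length(pool) >= 3L)
        triad_experiment(net, triad, pool,
                         n_random = config$n_random_triads,
                         seed = config$seed)
      else NULL
    })
  }

  if (!is.null(config$gmt_path) && length(members)) {
    report$enrichment <- stage("enrichment", {
      collection <- read_gmt(config$gmt_path)
      enrich(members, collection, background = igraph::V(net)$name,
             mode = config$enrich_mode)
    })
  }

  report$manifest <- list(
    config = config[setdiff(names(config), "network")],
    seed = config$seed,
    input_md5 = if (!is.null(config$edges_path))
      unname(tools::md5sum(config$edges_path)) else NA_character_,
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    timings = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(report) <- "netarch_report"

  if (!is.null(config$out_dir)) write_report(report, net, config$out_dir)
  report
}

write_report <- function(report, net, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$rich_club))
    write.table(as.data.frame(report$rich_club$profile),
                file.path(out_dir, "rich_club_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$centrality))
    write.table(report$centrality$table,
                file.path(out_dir, "centrality.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$modules) && length(report$modules$filtered$modules)) {
    mods <- report$modules$filtered$modules
    mem <- do.call(rbind, lapply(seq_along(mods), function(i)
      data.frame(node = mods[[i]]$nodes, module_id = sprintf("M%02d", i),
                 module_score = mods[[i]]$score, stringsAsFactors = FALSE)))
    write.table(mem, file.path(out_dir, "modules.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$modules$collapsed))
      export_graphml(report$modules$collapsed,
                     file.path(out_dir, "collapsed.graphml"))
  }
  summary <- list(
    network = report$network,
    global_metrics = report$global_metrics,
    small_world_index = report$small_world_index,
    regime = report$rich_club$regime,
    p_pooled = report$rich_club$significance$p_pooled,
    n_club = length(report$rich_club$members),
    central_core = report$centrality$core,
    knotty = list(
      full = report$knotty$full$members,
      club = report$knotty$club$members,
      overlap_full_club = report$knotty$overlap_full_club,
      collapsed_module_share = report$knotty$collapsed_module_share),
    perturbation = if (!is.null(report$perturbation)) list(
      ratio = as.list(report$perturbation$ratio),
      p_value = as.list(report$perturbation$p_value)),
    errors = report$errors,
    manifest = report$manifest)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.netarch_report <- function(x, ...) {
  cat("netarch analysis report\n")
  if (!is.null(x$network))
    cat(sprintf("  network: %d nodes, %d edges\n",
                x$network$n_nodes, x$network$n_edges))
  if (!is.null(x$rich_club)) {
    rg <- x$rich_club$regime
    cat(sprintf("  rich club: %s, %d members, pooled p = %.3g\n",
                if (is.null(rg)) "no regime"
                else sprintf("regime k = %d..%d", rg[1L], rg[2L]),
                length(x$rich_club$members),
                x$rich_club$significance$p_pooled))
  }
  if (!is.null(x$centrality))
    cat(sprintf("  central core (%d): %s\n", length(x$centrality$core),
                paste(x$centrality$core, collapse = ", ")))
  if (!is.null(x$modules))
    cat(sprintf("  modules: %d found, %d after size filter\n",
                length(x$modules$all$modules),
                length(x$modules$filtered$modules)))
  if (length(x$errors))
    cat(sprintf("  stage errors: %s\n",
                paste(names(x$errors), collapse = ", ")))
  invisible(x)
}
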