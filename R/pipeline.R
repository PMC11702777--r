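#' Default pipeline configuration
#'
#' @param ... overrides for any configuration field.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    mode = "visiumhd",          # or "generic"
    matrix = NULL, positions = NULL, scalefactors = NULL, nuclei = NULL,
    counts = NULL, coords = NULL,
    out = "ctsvg_out",
    area_ratio = 2,
    min_genes = 300, min_cell_frac = 0.01,
    scale_factor = 1e4,
    n_pcs = 10, resolution = 1.2, cluster_seed = 0,
    knots = 2, n_seeds = 1000, keep = 100, fdr = 0.05, rng_seed = 0,
    modules_kmax = 15, modules_seed = 0
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full analysis pipeline
#'
#' Chains the stages assign (Visium HD mode only) -> cluster -> test ->
#' modules, writing each stage's artifacts under the configured output
#' directory together with the serialized configuration, so a rerun from
#' the same configuration and seeds reproduces the outputs. Stages whose
#' outputs already exist are resumed (skipped) unless \code{overwrite}.
#'
#' @param config a configuration list (see \code{\link{default_config}})
#'   or the path of a JSON file holding one.
#' @param overwrite recompute stages whose outputs already exist.
#' @return Invisibly, a list with the per-stage results (\code{cells},
#'   \code{clusters}, \code{svg}, \code{modules}).
#' @export
run_pipeline <- function(config, overwrite = FALSE) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  cfg <- default_config()
  cfg[names(config)] <- config
  # validate before any compute
  if (cfg$mode == "visiumhd") {
    for (f in c("matrix", "positions", "scalefactors", "nuclei")) {
      if (is.null(cfg[[f]])) stop("[assign] config misses required input: ", f)
    }
  } else if (cfg$mode == "generic") {
    for (f in c("counts", "coords")) {
      if (is.null(cfg[[f]])) stop("[cluster] config misses required input: ", f)
    }
  } else stop("unknown mode: ", cfg$mode)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(cfg$out, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- assign ---------------------------------------------------------
  cells_dir <- file.path(cfg$out, "cells")
  if (cfg$mode == "visiumhd") {
    if (overwrite || !file.exists(file.path(cells_dir, "matrix.mtx"))) {
      message("[assign] reading inputs and assigning squares to cells")
      vh <- tryCatch(read_visiumhd(cfg$matrix, cfg$positions, cfg$scalefactors),
                     error = function(e) stop("[assign] ", conditionMessage(e)))
      nuclei <- read_nuclei_geojson(cfg$nuclei)
      asg <- assign_cells(vh$grid, vh$counts, nuclei,
                          area_ratio = cfg$area_ratio)
      cells <- asg$cells
      write_cell_matrix(cells, cells_dir)
      utils::write.table(asg$assignment,
                         file.path(cfg$out, "square_assignment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      message("[assign] resuming from ", cells_dir)
      cells <- read_generic(cells_dir, file.path(cells_dir, "cells.csv"))
    }
  } else {
    cells <- tryCatch(read_generic(cfg$counts, cfg$coords),
                      error = function(e) stop("[cluster] ", conditionMessage(e)))
  }

  # --- cluster --------------------------------------------------------
  message("[cluster] QC and graph clustering")
  cells <- tryCatch(qc_filter(cells, min_genes = cfg$min_genes,
                              min_cell_frac = cfg$min_cell_frac),
                    error = function(e) stop("[cluster] ", conditionMessage(e)))
  clusters <- cluster_cells(cells, n_pcs = cfg$n_pcs,
                            resolution = cfg$resolution,
                            seed = cfg$cluster_seed,
                            scale_factor = cfg$scale_factor)
  utils::write.table(
    data.frame(cell = names(clusters$labels), cluster = clusters$labels),
    file.path(cfg$out, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # --- test -----------------------------------------------------------
  message("[test] fitting spatial surfaces and permutation testing")
  norm <- lognormalize(cells, scale_factor = cfg$scale_factor)
  svg <- tryCatch(
    test_svgs(norm, cells$coords, clusters, K = cfg$knots,
              n_seeds = cfg$n_seeds, keep = cfg$keep, fdr = cfg$fdr,
              rng_seed = cfg$rng_seed),
    error = function(e) stop("[test] ", conditionMessage(e)))
  svg_dir <- file.path(cfg$out, "svg")
  dir.create(svg_dir, showWarnings = FALSE)
  for (cl in names(svg$results)) {
    utils::write.table(svg$results[[cl]],
                       file.path(svg_dir, sprintf("cluster_%s.tsv", cl)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- modules --------------------------------------------------------
  message("[modules] grouping significant genes into modules")
  modules <- list()
  mod_dir <- file.path(cfg$out, "modules")
  dir.create(mod_dir, showWarnings = FALSE)
  for (cl in names(svg$results)) {
    sig <- svg$results[[cl]]$gene[svg$results[[cl]]$significant]
    if (length(sig) < 1L) next
    std <- standardize_fits(svg$fits[[cl]])
    mods <- cluster_gene_modules(std[sig, , drop = FALSE],
                                 k_max = cfg$modules_kmax,
                                 seed = cfg$modules_seed)
    modules[[cl]] <- mods
    utils::write.table(
      data.frame(gene = unlist(lapply(mods, `[[`, "genes")),
                 module = rep(vapply(mods, `[[`, integer(1), "id"),
                              vapply(mods, function(m) length(m$genes),
                                     integer(1)))),
      file.path(mod_dir, sprintf("cluster_%s_modules.tsv", cl)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    mg <- do.call(rbind, lapply(mods, `[[`, "metagene"))
    rownames(mg) <- paste0("module", vapply(mods, `[[`, integer(1), "id"))
    utils::write.table(t(mg),
                       file.path(mod_dir, sprintf("cluster_%s_metagenes.tsv", cl)),
                       sep = "\t", quote = FALSE)
  }
  invisible(list(cells = cells, clusters = clusters, svg = svg,
                 modules = modules, config = cfg))
}
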