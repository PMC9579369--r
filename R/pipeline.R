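# End-to-end orchestration: recording -> band decomposition -> correlation
# -> reciprocal distance -> edge weights -> ISOMAP point cloud -> Rips
# filtration -> persistence diagram -> plots, and for two cohorts the
# band-by-band bottleneck/Wasserstein distance table. Every parameter and
# seed lands in a JSON run manifest, and all outputs are deterministic
# functions of config + input, so a run is bit-reproducible.

#' Pipeline configuration
#'
#' All parameters of the full-scale analysis with resolvable defaults, which
#' are the concluded operating settings of the method: maximum simplex
#' dimension 2, Fs = 20 filtering steps, eps_max taken from the data (the
#' maximum inter-node distance, per band per cohort), bottleneck accuracy
#' e = 0.01, Wasserstein order 1.
#'
#' @param bands character vector of band names from [standard_bands()]
#'   (default all six, full band included).
#' @param reciprocal_cap distance cap for near-zero correlations.
#' @param isomap_k ISOMAP neighbour count; the pipeline default 12 keeps the
#'   neighbour graph of modular networks with blocks of up to ~12 strongly
#'   coupled channels connected (a disconnected graph raises an error
#'   reporting the minimal connecting k).
#' @param isomap_dim `"auto"` or an explicit embedding dimension.
#' @param max_dim maximum simplex dimension of the filtration.
#' @param eps_max `NULL` for the data-driven maximum distance, or a fixed
#'   override for cross-run comparability.
#' @param fs number of filtering steps (`NULL` = exact values).
#' @param min_length feature/noise split length; `NULL` defers to
#'   `0.1 * eps_max` at run time.
#' @param e bottleneck accuracy for the approximate column.
#' @param wasserstein_p Wasserstein order(s).
#' @param dims homological dimensions for the group comparison.
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory.
#' @return A `phnet_config` (a validated list).
#' @export
pipeline_config <- function(bands = names(standard_bands()),
                            reciprocal_cap = 1000, isomap_k = 12,
                            isomap_dim = "auto", max_dim = 2,
                            eps_max = NULL, fs = 20, min_length = NULL,
                            e = 0.01, wasserstein_p = 1, dims = c(0, 1),
                            seed = 1, out_dir = tempfile("phnet_run")) {
  known <- names(standard_bands())
  bad <- setdiff(bands, known)
  if (length(bad))
    stop("unknown band(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(known, collapse = ", "))
  cfg <- list(bands = bands, reciprocal_cap = reciprocal_cap,
              isomap_k = isomap_k, isomap_dim = isomap_dim,
              max_dim = max_dim, eps_max = eps_max, fs = fs,
              min_length = min_length, e = e,
              wasserstein_p = wasserstein_p, dims = dims,
              seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "phnet_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param cfg a [pipeline_config()].
#' @param path JSON file path.
#' @return `path` invisibly (write); a `phnet_config` (read).
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "phnet_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Run the full-scale analysis pipeline
#'
#' For each cohort and each requested band: band-filter the recording,
#' compute the Pearson correlation and reciprocal-correlation distance
#' matrices, write the edge-weight list, embed the nodes with ISOMAP,
#' build the Vietoris-Rips filtration over the full distance scale, compute
#' the persistence diagram, and write barcode and diagram plots. With two
#' cohorts, a band-by-band bottleneck/Wasserstein distance table is added.
#' A JSON manifest records every parameter, seed and output file.
#'
#' @param recordings a named list of one or two [recording()]s (one per
#'   cohort), or file paths accepted by [read_recording()].
#' @param cfg a [pipeline_config()].
#' @param plots write SVG barcode/diagram plots (default TRUE).
#' @return Invisibly, a list with per-cohort per-band results (`diagram`,
#'   `filtration_counts`, `eps_max`, `embedding_report`, file paths), the
#'   comparison table (two cohorts), and the manifest path.
#' @export
run_pipeline <- function(recordings, cfg = pipeline_config(), plots = TRUE) {
  stopifnot(inherits(cfg, "phnet_config"))
  if (inherits(recordings, "phnet_recording"))
    recordings <- list(cohort = recordings)
  if (!length(recordings) || length(recordings) > 2)
    stop("`recordings` must hold one or two cohorts")
  if (is.null(names(recordings)) || any(!nzchar(names(recordings))))
    names(recordings) <- paste0("cohort", seq_along(recordings))
  recordings <- lapply(recordings, function(r)
    if (is.character(r)) read_recording(r) else r)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  bands <- standard_bands()[cfg$bands]
  results <- list()
  diagrams <- list()

  for (cname in names(recordings)) {
    rec <- recordings[[cname]]
    cohort_res <- list()
    for (bname in names(bands)) {
      stage <- sprintf("%s/%s", cname, bname)
      res <- tryCatch(
        run_band(rec, bands[[bname]], cname, cfg, plots),
        error = function(err)
          stop("pipeline stage '", stage, "' failed: ",
               conditionMessage(err), call. = FALSE))
      cohort_res[[bname]] <- res
      diagrams[[cname]][[bname]] <- res$diagram
    }
    results[[cname]] <- cohort_res
  }

  comparison <- NULL
  comparison_path <- NULL
  if (length(recordings) == 2) {
    comparison <- compare_groups(diagrams[[1]], diagrams[[2]],
                                 dims = cfg$dims, p_orders = cfg$wasserstein_p,
                                 e = cfg$e)
    comparison_path <- file.path(cfg$out_dir, "distance_table.tsv")
    write_distance_table(comparison, comparison_path)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phnet")),
    config = unclass(cfg),
    cohorts = lapply(results, function(cr) lapply(cr, function(r)
      list(eps_max = r$eps_max, n_intervals = nrow(r$diagram),
           filtration_counts = as.list(r$filtration_counts),
           embedding_dim = r$embedding_report$chosen_dim,
           files = r$files))),
    comparison_table = comparison_path)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  invisible(list(results = results, comparison = comparison,
                 manifest = manifest_path, out_dir = cfg$out_dir))
}

run_band <- function(rec, band, cname, cfg, plots) {
  filtered <- band_filter(rec, band)
  corr <- pearson_matrix(filtered)
  dmat <- reciprocal_distance(corr, cap = cfg$reciprocal_cap)
  emb <- isomap_embed(dmat, k = cfg$isomap_k, target_dim = cfg$isomap_dim)
  cloud_d <- stats::dist(emb$points$coordinates)
  eps_max <- if (is.null(cfg$eps_max)) max(cloud_d) else cfg$eps_max
  filt <- rips_filtration(cloud_d, max_dim = cfg$max_dim,
                          eps_max = eps_max, fs = cfg$fs)
  diag <- persistent_homology(filt)
  min_length <- cfg$min_length %||% (0.1 * eps_max)
  feats <- classify_intervals(diag, min_length)

  tag <- sprintf("%s_%s", cname, band$name)
  paths <- list(
    correlation = file.path(cfg$out_dir, paste0(tag, "_correlation.tsv")),
    distance = file.path(cfg$out_dir, paste0(tag, "_distance.tsv")),
    edges = file.path(cfg$out_dir, paste0(tag, "_edges.txt")),
    cloud = file.path(cfg$out_dir, paste0(tag, "_pointcloud.txt")),
    filtration = file.path(cfg$out_dir, paste0(tag, "_filtration_counts.tsv")),
    diagram = file.path(cfg$out_dir, paste0(tag, "_diagram.csv")))
  write_matrix_tsv(corr, paths$correlation)
  write_matrix_tsv(dmat, paths$distance)
  write_edge_weights(dmat, paths$edges)
  write_point_cloud(emb$points, paths$cloud)
  counts <- count_by_dimension(filt)
  utils::write.table(data.frame(dimension = names(counts),
                                count = as.integer(counts)),
                     paths$filtration, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_diagram(diag, paths$diagram)
  if (plots) {
    paths$barcode <- file.path(cfg$out_dir, paste0(tag, "_barcode.svg"))
    paths$pdiagram <- file.path(cfg$out_dir, paste0(tag, "_diagram.svg"))
    save_plot(paths$barcode, plot_barcode(diag, main = tag))
    save_plot(paths$pdiagram, plot_diagram(diag, main = tag))
  }
  list(diagram = diag, filtration_counts = counts, eps_max = eps_max,
       embedding_report = emb$report, persistent_features = feats$persistent,
       files = paths)
}
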