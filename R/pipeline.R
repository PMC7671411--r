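#' Run the full clustering pipeline
#'
#' read -> filter -> normalize/log -> train embedding -> embed ->
#' (estimate k) -> RPH-kmeans -> markers -> cell-type assignment ->
#' trajectory. Every intermediate artifact is written under `outdir`
#' together with a JSON manifest of seeds, parameters and timings;
#' rerunning with the same inputs and seed reproduces the labels exactly.
#'
#' @param input path to a count matrix (mtx or delimited) or an
#'   `ExpressionMatrix` (raw layer).
#' @param outdir output directory (created if missing).
#' @param format input format passed to [read_expression()].
#' @param min_count filtering threshold (see [filter_min_count()]).
#' @param scale normalization target total (see [normalize_and_log()]).
#' @param dpae a [dpae_config()]; its `seed` is overridden by `seed`.
#' @param rph an [rph_config()].
#' @param k number of clusters; give exactly one of `k` / `k_range`.
#' @param k_range candidate range for weighted-BIC selection of k.
#' @param reference optional marker reference (path or named list) for
#'   cell-type assignment.
#' @param p_max,fc_min marker thresholds (see [rank_sum_markers()]).
#' @param annotate call markers/trajectory stages (needs >= 2 clusters).
#' @param seed master seed; stage seeds are derived from it.
#' @param verbose print stage progress to stderr.
#' @return invisibly, a list with the principal results (`labels`,
#'   `embedding`, `k`, `markers`, `assignments`, `trajectory`, `manifest`).
#' @export
run_pipeline <- function(input, outdir,
                         format = "auto", min_count = 1, scale = 1e4,
                         dpae = dpae_config(), rph = rph_config(),
                         k = NULL, k_range = NULL,
                         reference = NULL, p_max = 1e-6, fc_min = 1.5,
                         annotate = TRUE,
                         seed = 1L, verbose = TRUE) {
  if (is.null(k) == is.null(k_range))
    stop("supply exactly one of k / k_range")
  t0 <- Sys.time()
  say <- function(...) if (verbose) message("[cellsketch] ", sprintf(...))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  stage <- function(name, expr) {
    say("stage: %s", name)
    tic <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), tic, units = "secs"))
    out
  }

  m <- stage("read", {
    if (inherits(input, "ExpressionMatrix")) input
    else read_expression(input, format)
  })
  m <- stage("filter", filter_min_count(m, min_count))
  ml <- stage("normalize", normalize_and_log(m, scale))

  dpae$seed <- seed
  model <- stage("train_embedding", train_dpae(ml, dpae))
  emb <- stage("embed", embed_cells(model, ml))

  set.seed(seed + 1L)
  bic <- NULL
  if (!is.null(k_range)) {
    bic <- stage("estimate_k", {
      sk <- build_skeleton(emb, rph,
                           skeleton_target = max(2000L, 20L * max(k_range)))
      estimate_k_weighted_bic(sk, k_range)
    })
    k <- bic$k
    say("weighted BIC selected k = %d", k)
  }

  set.seed(seed + 2L)
  fit <- stage("cluster", rph_kmeans(emb, k, rph))
  write_results(fit$labels, emb, file.path(outdir, "cells"),
                cell_ids = ml$cell_ids)
  utils::write.table(
    data.frame(cluster = seq_len(k), signif(fit$centers, 15)),
    file.path(outdir, "centers.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  markers <- assignments <- traj <- NULL
  if (annotate && k >= 2) {
    markers <- stage("markers",
                     rank_sum_markers(ml, fit$labels, p_max, fc_min))
    utils::write.table(markers, file.path(outdir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(reference)) {
      ref <- if (is.character(reference)) read_marker_reference(reference)
      else reference
      assignments <- stage("assign", {
        assign_cell_types(markers, ref, n_bg = ncol(ml$values))
      })
      utils::write.table(assignments$assignments,
                         file.path(outdir, "cell_types.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    traj <- stage("trajectory", cluster_trajectory(emb, fit$labels))
    write_trajectory_newick(traj, file.path(outdir, "trajectory.nwk"))
  }

  manifest <- list(
    package = "cellsketch",
    version = as.character(utils::packageVersion("cellsketch")),
    seed = seed,
    n_cells = nrow(ml$values), n_genes = ncol(ml$values),
    min_count = min_count, scale = scale,
    k = k, k_range = k_range,
    dpae = dpae[setdiff(names(dpae), "")],
    rph = rph[!vapply(rph, is.null, logical(1))],
    inertia = fit$inertia,
    bic_scores = if (!is.null(bic)) bic$scores else NULL,
    timings = timings,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  say("done in %.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(labels = fit$labels, embedding = emb, k = k, fit = fit,
                 model = model, markers = markers,
                 assignments = assignments, trajectory = traj,
                 manifest = manifest))
}
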