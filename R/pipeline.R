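# End-to-end orchestration: sequence -> coupling -> cluster -> structure,
# and trajectories -> metrics -> landscape, with JSON reports.

# polynomial rolling hash of the serialized config, for report provenance
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

default_sca_config <- function() {
  list(redundancy = 0.95, max_gap = 0.20, lambda = 0.03,
       weights_cutoff = 0.8, coupling_threshold = 0.25, min_size = 2,
       n_clusters = NULL, ref_id = NULL, ref_start = 1L, seed = 1L)
}

#' Run the sequence-to-cluster pipeline
#'
#' Reads (or accepts) an alignment, applies the redundancy filter then
#' the gap-column filter, computes sequence weights, regularized
#' frequencies and the SCA coupling matrix, reports the fraction of
#' pairs above the coupling threshold, extracts the top coevolving
#' cluster, and optionally maps it onto a structure with
#' ligand-proximity annotation.
#'
#' @param aln an [alignment()] or a path readable by [read_alignment()].
#' @param config named list overriding [names in] the defaults:
#'   `redundancy` (0.95), `max_gap` (0.20), `lambda` (0.03),
#'   `weights_cutoff` (0.8), `coupling_threshold` (0.25), `min_size`,
#'   `n_clusters`, `ref_id`, `ref_start`.
#' @param structure optional `structure3d` for cluster mapping.
#' @param structure_offset offset added to reference residue numbers to
#'   reach structure numbering.
#' @param ligand optional ligand residue name for 5 A proximity
#'   annotation of the mapped cluster.
#' @param ligand_cutoff proximity cutoff (angstrom); default 5.
#' @param out_prefix optional path prefix; when given, writes the
#'   filtered alignment FASTA, coupling matrix TSVs, cluster report JSON
#'   and pipeline report JSON.
#' @return the report, a named list (counts at every stage, fraction
#'   above threshold, top cluster and its score, config echo and hash).
#' @export
run_sca_pipeline <- function(aln, config = list(), structure = NULL,
                             structure_offset = 0L, ligand = NULL,
                             ligand_cutoff = 5.0, out_prefix = NULL) {
  cfg <- utils::modifyList(default_sca_config(), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  if (is.character(aln)) aln <- stage("read", read_alignment(aln))
  n0 <- length(aln$seqs); L0 <- n_columns(aln)
  red <- stage("redundancy_filter",
               filter_redundant(aln, cfg$redundancy))
  gapres <- stage("gap_filter", filter_gap_columns(red, cfg$max_gap))
  flt <- gapres$alignment
  sw <- stage("sequence_weights",
              sequence_weights(flt, cfg$weights_cutoff))
  fm <- stage("frequencies",
              weighted_frequencies(flt, sw$weights, cfg$lambda))
  cm <- stage("coupling", coupling_matrix(fm))
  frac <- stage("fraction_above",
                fraction_above(cm, cfg$coupling_threshold))
  pm <- NULL
  if (!is.null(cfg$ref_id)) {
    # map on the pre-gap-filter alignment so dropped columns holding
    # reference residues cannot shift the numbering, then restrict
    pm <- stage("position_map",
                subset_position_map(
                  map_to_reference(red, cfg$ref_id, cfg$ref_start), flt))
  }
  cl <- stage("clustering",
              cluster_coupling_matrix(cm, n_clusters = cfg$n_clusters,
                                      min_size = cfg$min_size,
                                      posmap = pm))
  report <- list(
    config = cfg, config_hash = config_hash(cfg),
    n_seq_input = n0, n_columns_input = L0,
    n_seq_after_redundancy = length(red$seqs),
    n_columns_dropped = length(gapres$dropped),
    n_columns_final = n_columns(flt),
    Meff = sw$Meff,
    fraction_above_threshold = frac,
    coupling_threshold = cfg$coupling_threshold,
    n_clusters = cl$k,
    top_cluster_columns = cl$top_cluster,
    top_cluster_labels = cl$top_cluster_labels,
    top_cluster_score = cl$top_cluster_score)
  if (!is.null(structure)) {
    mp <- stage("structure_map",
                map_positions_to_structure(cl$top_cluster_labels,
                                           structure, structure_offset))
    report$mapped_residues <- mp$selection$resno
    report$unmapped_positions <- mp$unmapped
    if (!is.null(ligand)) {
      prox <- stage("ligand_proximity",
                    ligand_proximal_residues(structure, ligand,
                                             ligand_cutoff))
      report$cluster_near_ligand <-
        intersect(mp$selection$resno, prox$resno)
    }
  }
  if (!is.null(out_prefix)) {
    write_alignment(flt, paste0(out_prefix, "_filtered.fasta"))
    write_coupling_matrix(cm, out_prefix)
    jsonlite::write_json(report, paste0(out_prefix, "_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

default_traj_config <- function() {
  list(metrics = c("rmsd", "rmsf", "rg", "dcc"), selection = "ca",
       rg_selection = "heavy", ligand = NULL, sasa_probe = 1.4,
       sasa_points = 960, hbond_dcut = 3.5, hbond_angle = 150,
       grid_step = 0.1, seed = 1L)
}

#' Run the trajectory-metrics pipeline
#'
#' Computes the requested per-replicate metrics, summarizes each as
#' mean +/- SD per replicate and pooled over all frames, and (when
#' element ranges are supplied) the pooled 2D distance landscape with
#' its modes.
#'
#' @param trajs a [trajectory()] or list of replicate trajectories.
#' @param config named list overriding the defaults: `metrics` (subset
#'   of rmsd, rmsf, rg, dist, sasa, hbonds, dcc, landscape), `selection`,
#'   `rg_selection`, `ligand`, `sasa_probe`, `sasa_points`,
#'   `hbond_dcut`, `hbond_angle`, `grid_step`.
#' @param elements an [element_def()]; required when `"landscape"` is in
#'   `metrics`.
#' @param dist_pair list of two [residue_selection()]s for the `"dist"`
#'   metric.
#' @param ref reference for RMSD (frame index, matrix or `structure3d`);
#'   default frame 1 of each replicate.
#' @param out_prefix optional path prefix for TSV/JSON outputs.
#' @return report list: per-metric per-replicate and pooled summaries,
#'   landscape modes, config echo and hash.
#' @export
run_traj_pipeline <- function(trajs, config = list(), elements = NULL,
                              dist_pair = NULL, ref = 1L,
                              out_prefix = NULL) {
  cfg <- utils::modifyList(default_traj_config(), config)
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  if ("landscape" %in% cfg$metrics && is.null(elements)) {
    stop("[landscape] config error: element ranges ('elements') are ",
         "required for the landscape metric", call. = FALSE)
  }
  if ("dist" %in% cfg$metrics && is.null(dist_pair)) {
    stop("[dist] config error: 'dist_pair' selections are required",
         call. = FALSE)
  }
  if (any(cfg$metrics %in% c("sasa", "hbonds")) && is.null(cfg$ligand)) {
    stop("[sasa] config error: 'ligand' is required for SASA/H-bond ",
         "metrics", call. = FALSE)
  }
  report <- list(config = cfg[setdiff(names(cfg), "metrics")],
                 metrics = cfg$metrics, config_hash = config_hash(cfg),
                 n_replicates = length(trajs),
                 n_frames = vapply(trajs, n_frames, integer(1)))
  series_metric <- function(name, fun) {
    per <- lapply(seq_along(trajs), function(r) fun(trajs[[r]], r))
    pooled <- series_summary(per)
    list(per_replicate = lapply(per, series_summary), pooled = pooled,
         series = per)
  }
  out <- list()
  for (m in cfg$metrics) {
    out[[m]] <- switch(m,
      rmsd = stage("rmsd", series_metric("rmsd", function(tr, r)
        rmsd_series(tr, ref = ref, selection = cfg$selection))),
      rg = stage("rg", series_metric("rg", function(tr, r)
        rg_series(tr, selection = cfg$rg_selection))),
      dist = stage("dist", series_metric("dist", function(tr, r)
        group_distance_series(tr, dist_pair[[1]], dist_pair[[2]]))),
      sasa = stage("sasa", series_metric("sasa", function(tr, r)
        ligand_sasa_series(tr, cfg$ligand, cfg$sasa_probe,
                           cfg$sasa_points))),
      hbonds = stage("hbonds", series_metric("hbonds", function(tr, r)
        hbond_count_series(tr, cfg$ligand, cfg$hbond_dcut,
                           cfg$hbond_angle))),
      rmsf = stage("rmsf", {
        pooled <- pool_trajectories(trajs)
        list(profile = rmsf_profile(pooled, cfg$selection))
      }),
      dcc = stage("dcc", {
        res <- dcc_matrix(trajs, selection = cfg$selection)
        list(resno = res$resno, dcc = res$dcc)
      }),
      landscape = stage("landscape",
        distance_landscape(trajs, elements, grid_step = cfg$grid_step)),
      stop("unknown metric: ", m))
  }
  for (m in intersect(cfg$metrics, c("rmsd", "rg", "dist", "sasa",
                                     "hbonds"))) {
    report[[paste0(m, "_per_replicate")]] <- out[[m]]$per_replicate
    report[[paste0(m, "_pooled")]] <- out[[m]]$pooled
  }
  if ("rmsf" %in% cfg$metrics) {
    report$rmsf_mean <- mean(out$rmsf$profile$rmsf)
    report$rmsf_max <- max(out$rmsf$profile$rmsf)
  }
  if ("dcc" %in% cfg$metrics) {
    d <- out$dcc$dcc
    report$dcc_extreme_pairs <- sum(abs(d[upper.tri(d)]) >= 0.5)
  }
  if ("landscape" %in% cfg$metrics) {
    report$landscape_modes <- out$landscape$modes
  }
  if (!is.null(out_prefix)) {
    for (m in intersect(cfg$metrics, c("rmsd", "rg", "dist", "sasa",
                                       "hbonds"))) {
      for (r in seq_along(out[[m]]$series)) {
        write_time_series(out[[m]]$series[[r]],
                          sprintf("%s_%s_rep%d.tsv", out_prefix, m, r))
      }
    }
    if ("rmsf" %in% cfg$metrics) {
      utils::write.table(out$rmsf$profile,
                         paste0(out_prefix, "_rmsf.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if ("dcc" %in% cfg$metrics) {
      utils::write.table(out$dcc$dcc, paste0(out_prefix, "_dcc.tsv"),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    if ("landscape" %in% cfg$metrics) {
      write_landscape(out$landscape, out_prefix)
    }
    jsonlite::write_json(report, paste0(out_prefix, "_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", force = TRUE)
  }
  report$results <- out
  report
}
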