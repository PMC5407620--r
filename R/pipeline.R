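#' Pipeline configuration
#'
#' Bundles the tunable parameters of the staged pipeline with their default
#' values: 1000 permutations per enrichment null, 10000 random networks for
#' edge probabilities, 50000 random baseline paths, branch factor 2, 1000
#' resampling repetitions of sets of 1024 paths, a log2 fold-change
#' threshold of 1 (2-fold), an exclusive set-size cutoff of 15, the dummy
#' placeholder 0.001 and the secondary-fill band 0.8.
#'
#' @param n_perm Permutations per enrichment null.
#' @param n_random_networks Random networks for edge probabilities.
#' @param n_random_paths Random baseline paths.
#' @param branch Branching factor of the systematic search.
#' @param n_reps Resampling repetitions.
#' @param set_size Paths per resampled set.
#' @param fc_threshold Log2 fold-change perturbation threshold.
#' @param min_set_size Exclusive minimum gene-set size.
#' @param dummy Placeholder fold change.
#' @param band Secondary-fill averaging band.
#' @param n_decoys Synthetic decoy datasets for the precision stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_perm = 1000L, n_random_networks = 10000L,
                            n_random_paths = 50000L, branch = 2L,
                            n_reps = 1000L, set_size = 1024L,
                            fc_threshold = 1.0, min_set_size = 15L,
                            dummy = 0.001, band = 0.8, n_decoys = 5L) {
  cfg <- list(n_perm = n_perm, n_random_networks = n_random_networks,
              n_random_paths = n_random_paths, branch = branch,
              n_reps = n_reps, set_size = set_size,
              fc_threshold = fc_threshold, min_set_size = min_set_size,
              dummy = dummy, band = band, n_decoys = n_decoys)
  counts <- c("n_perm", "n_random_networks", "n_random_paths", "branch",
              "n_reps", "set_size", "n_decoys")
  for (f in counts) if (!is_count(cfg[[f]])) stopf("%s must be a positive integer", f)
  if (cfg$fc_threshold <= 0 || cfg$band <= 0) stopf("thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

.artifact <- function(dir, name) file.path(dir, name)

.require_artifact <- function(dir, name, stage) {
  p <- .artifact(dir, name)
  if (!file.exists(p)) {
    stopf("missing artifact %s; run the '%s' stage first", name, stage)
  }
  p
}

#' Write a probe table plus its column mapping
#'
#' @param probes A [probe_table()].
#' @param prefix Path prefix; writes `<prefix>.tsv` and
#'   `<prefix>_mapping.json`.
#' @return The two paths, invisibly.
#' @export
write_probe_table <- function(probes, prefix) {
  stopifnot(inherits(probes, "probe_table"))
  tsv <- paste0(prefix, ".tsv")
  mp <- paste0(prefix, "_mapping.json")
  df <- data.frame(probe_id = probes$probe_id, gene_symbol = probes$gene_symbol,
                   stringsAsFactors = FALSE)
  mapping <- list()
  for (t in seq_along(probes$timepoints)) {
    tp <- probes$timepoints[t]
    cols <- sprintf("%s_r%d", gsub("\\s+", "", tp), 1:3)
    pcol <- sprintf("%s_p", gsub("\\s+", "", tp))
    for (k in 1:3) df[[cols[k]]] <- probes$values[, t, k]
    df[[pcol]] <- probes$pvalues[, t]
    mapping[[tp]] <- list(replicates = cols, pvalue = pcol)
  }
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(mapping, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, mp))
}

# reconstruct a nes_matrix from the long-format TSV
read_nes_long <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  procs <- unique(df$process)
  tps <- unique(df$timepoint)
  shape <- function(col) {
    m <- matrix(NA_real_, length(procs), length(tps),
                dimnames = list(procs, tps))
    m[cbind(match(df$process, procs), match(df$timepoint, tps))] <- df[[col]]
    m
  }
  sizes <- df$size[match(procs, df$process)]
  names(sizes) <- procs
  structure(
    list(es = shape("es"), nes = shape("nes"), pvalue = shape("pvalue"),
         size = sizes, processes = procs, timepoints = tps,
         n_perm = NA_integer_, method = "max_plus_min",
         failures = data.frame(process = character(0),
                               timepoint = character(0),
                               reason = character(0))),
    class = "nes_matrix"
  )
}

.write_manifest <- function(dir, stage, config, seed, outputs) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("temponet")),
    seed = seed,
    config = unclass(config),
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest,
                       .artifact(dir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run one pipeline stage on a run directory
#'
#' Stages communicate through files so partial reruns are cheap. Each stage
#' writes its artifacts plus a machine-readable manifest (config, seed,
#' output checksums). Available stages: `simulate`, `preprocess`, `gsea`,
#' `network`, `paths`, `overlap`, `precision`, `all`.
#'
#' @param stage Stage name.
#' @param dir Run directory (created if needed).
#' @param spec A [synthetic_spec()] (used by `simulate` and `precision`).
#' @param config A [pipeline_config()].
#' @param seed Master seed.
#' @return Invisibly, a list of stage results.
#' @export
run_stage <- function(stage, dir, spec = synthetic_spec(),
                      config = pipeline_config(), seed = 1L) {
  stages <- c("simulate", "preprocess", "gsea", "network", "paths",
              "overlap", "precision", "all")
  if (!stage %in% stages) {
    stopf("unknown stage '%s'; choose one of: %s", stage,
          paste(stages, collapse = ", "))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    res <- list()
    for (s in setdiff(stages, "all")) {
      res[[s]] <- run_stage(s, dir, spec, config, seed)
    }
    return(invisible(res))
  }
  out <- switch(
    stage,
    simulate = {
      sl <- make_library(spec, seed = seed)
      fc <- make_fc_matrix(spec, sl, seed = seed)
      pt <- make_probe_table(spec, fc, seed = seed)
      write_gmt(sl$library, .artifact(dir, "library.gmt"))
      jsonlite::write_json(
        list(planted = sl$planted, connectors = sl$connectors,
             truth = fc$truth),
        .artifact(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      write_probe_table(pt, .artifact(dir, "probes"))
      files <- c("library.gmt", "truth.json", "probes.tsv",
                 "probes_mapping.json")
      .write_manifest(dir, stage, config, seed, .artifact(dir, files))
      list(planted = sl$planted)
    },
    preprocess = {
      tsv <- .require_artifact(dir, "probes.tsv", "simulate")
      mp <- .require_artifact(dir, "probes_mapping.json", "simulate")
      pt <- read_probe_table(tsv, mp)
      mat <- preprocess_probe_table(pt, threshold_log2 = config$fc_threshold,
                                    band = config$band, dummy = config$dummy)
      write_fc_matrix(mat, .artifact(dir, "fc_matrix.tsv"))
      .write_manifest(dir, stage, config, seed, .artifact(dir, "fc_matrix.tsv"))
      list(n_genes = nrow(mat), n_timepoints = ncol(mat))
    },
    gsea = {
      fcp <- .require_artifact(dir, "fc_matrix.tsv", "preprocess")
      lp <- .require_artifact(dir, "library.gmt", "simulate")
      mat <- read_fc_matrix(fcp)
      lib <- prepare_library(read_gmt(lp), min_exclusive = config$min_set_size)
      nm <- nes_matrix(mat, lib, n_perm = config$n_perm, seed = seed)
      write_nes_matrix(nm, .artifact(dir, "enrichment"))
      files <- c("enrichment_long.tsv", "enrichment_nes.tsv")
      .write_manifest(dir, stage, config, seed, .artifact(dir, files))
      nm
    },
    network = {
      lp <- .require_artifact(dir, "library.gmt", "simulate")
      fcp <- .require_artifact(dir, "fc_matrix.tsv", "preprocess")
      lib <- prepare_library(read_gmt(lp), min_exclusive = config$min_set_size)
      lib <- restrict_to_universe(lib, rownames(read_fc_matrix(fcp)))
      net <- build_network(lib)
      write_network(net, .artifact(dir, "network.tsv"),
                    graphml = .artifact(dir, "network.graphml"))
      dist <- network_distributions(net)
      utils::write.table(dist$size, .artifact(dir, "size_distribution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(dist$degree, .artifact(dir, "degree_distribution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c("network.tsv", "network.graphml", "size_distribution.tsv",
                 "degree_distribution.tsv")
      .write_manifest(dir, stage, config, seed, .artifact(dir, files))
      net
    },
    paths = {
      np <- .require_artifact(dir, "enrichment_long.tsv", "gsea")
      lp <- .require_artifact(dir, "library.gmt", "simulate")
      fcp <- .require_artifact(dir, "fc_matrix.tsv", "preprocess")
      nm <- read_nes_long(np)
      lib <- prepare_library(read_gmt(lp), min_exclusive = config$min_set_size)
      lib <- restrict_to_universe(lib, rownames(read_fc_matrix(fcp)))
      net <- build_network(lib)
      pmax_ <- systematic_paths(nm, net, branch = config$branch, direction = "max")
      pmin_ <- systematic_paths(nm, net, branch = config$branch, direction = "min")
      prand <- annotate_mean_nes(
        random_paths(net, length = length(nm$timepoints),
                     count = config$n_random_paths, seed = seed), nm)
      write_pathset(pmax_, .artifact(dir, "paths_systematic_max"))
      write_pathset(pmin_, .artifact(dir, "paths_systematic_min"))
      write_pathset(prand, .artifact(dir, "paths_random"))
      files <- c("paths_systematic_max.tsv", "paths_systematic_min.tsv",
                 "paths_random.tsv")
      .write_manifest(dir, stage, config, seed, .artifact(dir, files))
      list(max = pmax_, min = pmin_, random = prand)
    },
    overlap = {
      for (f in c("paths_systematic_max.tsv", "paths_systematic_min.tsv",
                  "paths_random.tsv")) .require_artifact(dir, f, "paths")
      read_ps <- function(name, prov) {
        df <- utils::read.delim(.artifact(dir, name), check.names = FALSE,
                                stringsAsFactors = FALSE)
        tcols <- grep("^t[0-9]+$", names(df), value = TRUE)
        path_set(as.matrix(df[, tcols]), provenance = prov,
                 mean_nes = df$mean_nes)
      }
      pmax_ <- read_ps("paths_systematic_max.tsv", "systematic-max")
      pmin_ <- read_ps("paths_systematic_min.tsv", "systematic-min")
      prand <- read_ps("paths_random.tsv", "random")
      smax <- overlap_summary(pmax_)
      smin <- overlap_summary(pmin_)
      cmp <- compare_overlap_distributions(pmax_, pmin_)
      bc1 <- best_covering(pmax_, k = 1L)
      bc2 <- best_covering(pmax_, k = 2L,
                           max_paths = max(5000L, length(pmax_)))
      null_df <- if (length(prand) >= config$set_size) {
        resampled_null(prand, set_size = config$set_size,
                       n_reps = config$n_reps, seed = seed)
      } else NULL
      bd <- path_bundle_data(pmax_)
      utils::write.table(bd$edges, .artifact(dir, "bundle_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(bd$nodes, .artifact(dir, "bundle_nodes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report <- list(
        perturbed = list(mean_overlap_factor = smax$mean_overlap_factor,
                         mean_nes = smax$mean_nes),
        unperturbed = list(mean_overlap_factor = smin$mean_overlap_factor,
                           mean_nes = smin$mean_nes),
        comparison = list(overlap_pvalue = cmp$overlap_pvalue,
                          nes_pvalue = cmp$nes_pvalue),
        best_single = list(covered = bc1$covered, fraction = bc1$fraction),
        best_pair = list(covered = bc2$covered, fraction = bc2$fraction,
                         n_optima = nrow(bc2$indices)),
        resampled_null = if (is.null(null_df)) NULL else
          list(mean_overlap_factor = mean(null_df$mean_overlap_factor),
               sd_overlap_factor = stats::sd(null_df$mean_overlap_factor),
               mean_nes = mean(null_df$mean_nes),
               sd_nes = stats::sd(null_df$mean_nes))
      )
      jsonlite::write_json(report, .artifact(dir, "overlap.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c("overlap.json", "bundle_edges.tsv", "bundle_nodes.tsv")
      .write_manifest(dir, stage, config, seed, .artifact(dir, files))
      report
    },
    precision = {
      np <- .require_artifact(dir, "enrichment_long.tsv", "gsea")
      pp <- .require_artifact(dir, "paths_systematic_max.tsv", "paths")
      lp <- .require_artifact(dir, "library.gmt", "simulate")
      nm <- read_nes_long(np)
      df <- utils::read.delim(pp, check.names = FALSE, stringsAsFactors = FALSE)
      tcols <- grep("^t[0-9]+$", names(df), value = TRUE)
      best <- unlist(df[which.max(df$mean_nes), tcols])
      lib <- read_gmt(lp)
      # synthetic decoy datasets: same library, no planted signal
      decoys <- lapply(seq_len(config$n_decoys), function(i) {
        fc <- make_fc_matrix(spec, lib, seed = derive_seed(seed, 77L, i),
                             planted = character(0))
        nes_matrix(fc$matrix, lib, n_perm = config$n_perm,
                   seed = derive_seed(seed, 78L, i))
      })
      pr <- path_precision(best, nm, decoys)
      jsonlite::write_json(
        list(path = unname(best), source_mean_nes = pr$source_value,
             n_exceed = pr$n_exceed, n_total = pr$n_total,
             precision_percent = pr$percent,
             exceedance_probability = pr$exceedance_probability,
             decoy_values = pr$values),
        .artifact(dir, "precision.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      .write_manifest(dir, stage, config, seed, .artifact(dir, "precision.json"))
      pr
    }
  )
  invisible(out)
}

#' Run the whole pipeline on synthetic data
#'
#' Convenience wrapper chaining all stages on one run directory.
#'
#' @inheritParams run_stage
#' @return Invisibly, the list of stage results.
#' @export
run_pipeline <- function(dir, spec = synthetic_spec(),
                         config = pipeline_config(), seed = 1L) {
  run_stage("all", dir, spec = spec, config = config, seed = seed)
}
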