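#' Pipeline configuration
#'
#' Collects paths, stage options and the root seed for [run_pipeline()].
#' Every stochastic stage derives its stream deterministically from `seed`,
#' so a config run twice produces byte-identical outputs.
#'
#' @param table_path,metadata_path,gcn_path input TSVs ([read_abundance_table()]
#'   / [read_gene_content()] formats); `gcn_path` may be NULL
#' @param outdir output directory (created if needed)
#' @param methods selector list for [run_selectors()]
#' @param timepoints time points analysed by the selectors
#' @param learner combination-search learner for [select_ensemble()]
#' @param r_threshold,p_threshold,min_prevalence network thresholds for
#'   [build_conet()]
#' @param abx_end_day day antibiotics ended (for `t_post`)
#' @param allow_partial skip the diversity stage with a warning when no
#'   gene-content matrix is supplied (error otherwise)
#' @param seed root seed
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(table_path, metadata_path, gcn_path = NULL,
                            outdir = "microrecov_out",
                            methods = c("wilcoxon", "gbdt_a", "gbdt_b",
                                        "netshift", "netmoss", "pccorr"),
                            timepoints = c("pre", "during", "post"),
                            learner = "logistic",
                            r_threshold = 0.4, p_threshold = 0.05,
                            min_prevalence = 0.1, abx_end_day = 7,
                            allow_partial = FALSE, seed = 1L) {
  structure(list(table_path = table_path, metadata_path = metadata_path,
                 gcn_path = gcn_path, outdir = outdir, methods = methods,
                 timepoints = timepoints, learner = learner,
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 min_prevalence = min_prevalence, abx_end_day = abx_end_day,
                 allow_partial = allow_partial, seed = as.integer(seed)),
            class = c("pipeline_config", "list"))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full recovery-prediction pipeline
#'
#' Stages: label (interquartile-range recoverer labeling), select (ensemble
#' p-RAB selection), diversity (TD/FD/FR profiles), predict (packaged
#' logistic model plus a refit), network (per group and time point
#' co-occurrence networks). Each stage writes its artifact before the next
#' starts, so a failing stage leaves partial outputs in place and aborts
#' with the stage name.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with the in-memory results of every stage
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (partial outputs kept in %s)",
                   name, conditionMessage(e), config$outdir), call. = FALSE))
  }

  table <- stage("load", read_abundance_table(config$table_path,
                                              config$metadata_path))

  labels <- stage("label", label_recoverers(table))
  write_tsv(as.data.frame(labels), out("labels.tsv"))

  ensemble <- stage("select", {
    selections <- run_selectors(table, labels, methods = config$methods,
                                timepoints = config$timepoints,
                                seed = config$seed)
    ens <- select_ensemble(selections, table, labels,
                           learner = config$learner, seed = config$seed)
    report <- list(
      per_method = lapply(selections, function(r)
        list(selected = r$selected, score = as.list(r$score))),
      combinations = ens$combinations,
      final_prabs = ens$final_prabs,
      best_methods = ens$best_methods,
      seed = config$seed)
    jsonlite::write_json(report, out("ensemble.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    ens
  })

  profiles <- NULL
  if (is.null(config$gcn_path)) {
    if (!config$allow_partial)
      stop("stage 'diversity' failed: no gene-content matrix configured ",
           "(set allow_partial = TRUE to skip)", call. = FALSE)
    warning("diversity stage skipped: no gene-content matrix configured")
  } else {
    profiles <- stage("diversity", {
      gcn <- read_gene_content(config$gcn_path)
      pr <- diversity_profiles(table, gcn, ensemble$final_prabs,
                               abx_end_day = config$abx_end_day)
      write_tsv(as.data.frame(pr), out("profiles.tsv"))
      pr
    })
  }

  prediction <- NULL
  if (!is.null(profiles)) {
    prediction <- stage("predict", {
      model <- recovery_model()
      lab <- labels$label[match(profiles$subject_id, labels$subject_id)]
      pre <- profiles$timepoint == "pre" & !is.na(lab)
      pred <- predict_recovery(model, profiles$FD[pre], profiles$TD[pre],
                               profiles$f_prabs_presence[pre])
      refit <- fit_recovery_model(profiles$FD[pre], profiles$TD[pre],
                                  profiles$f_prabs_presence[pre], lab[pre],
                                  seed = config$seed)
      jsonlite::write_json(
        list(packaged = unclass(model), refit = unclass(refit$model),
             refit_auc = refit$auc_mean, refit_accuracy = refit$accuracy_mean,
             ridged = refit$ridged, seed = config$seed),
        out("model.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
      list(packaged = pred, refit = refit)
    })
  }

  networks <- stage("network", {
    md <- table$metadata
    key <- paste(ifelse(is.na(md$group), "all", md$group), md$timepoint, sep = "_")
    nets <- list(); metrics <- list()
    for (k in sort(unique(key))) {
      ids <- md$sample_id[key == k]
      if (length(ids) < 5) next
      net <- build_conet(subset_table(table, sample_ids = ids),
                         r_threshold = config$r_threshold,
                         p_threshold = config$p_threshold,
                         min_prevalence = config$min_prevalence)
      write_graphml(net, out(sprintf("network_%s.graphml", k)))
      m <- network_metrics(net)
      metrics[[k]] <- data.frame(
        network = k, n_nodes = m$n_nodes, n_edges = m$n_edges,
        mean_degree = m$mean_degree, n_hubs = length(m$hub_nodes),
        E_a = m$E_a, mEDR = m$mEDR, stringsAsFactors = FALSE)
      nets[[k]] <- net
    }
    if (length(metrics) > 0)
      write_tsv(do.call(rbind, metrics), out("network_metrics.tsv"))
    nets
  })

  config_json <- out("config.json")
  # outdir is implied by the artifact location; omitting it keeps runs of the
  # same inputs/seed byte-identical regardless of where they are written
  cfg_rec <- unclass(config)
  cfg_rec$outdir <- NULL
  jsonlite::write_json(cfg_rec, config_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  manifest <- list(
    package = "microrecov",
    version = as.character(utils::packageVersion("microrecov")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(config_json)),
    artifacts = sort(setdiff(list.files(config$outdir), "manifest.json")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(table = table, labels = labels, ensemble = ensemble,
                 profiles = profiles, prediction = prediction,
                 networks = networks, manifest = manifest))
}
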