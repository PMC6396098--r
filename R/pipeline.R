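#' Run the full pipeline from a single configuration
#'
#' Config-driven orchestration: build (or generate) the network, learn
#' embeddings, cross-validate the classifier, optionally rank unknown
#' candidates, and write every stage output plus a manifest to a run
#' directory. One top-level seed fans out to per-stage seeds via
#' [derive_seed()], so a rerun with an identical config reproduces
#' byte-identical outputs.
#'
#' The configuration is a nested list (or a YAML file path) with
#' sections:
#' \describe{
#'   \item{synth}{arguments for [synth_config()] — generate a
#'     planted-signal network; or}
#'   \item{edge_files, positives_file}{paths to TSV edge lists and a
#'     herb-protein TSV of known interactions.}
#'   \item{embedding}{`d`, `num_walks`, `walk_length`, `p`, `q`,
#'     `window`, `negatives`, `epochs`.}
#'   \item{model}{`family` (default `"knn"`), `k`.}
#'   \item{evaluation}{`folds` (default 10).}
#'   \item{ranking}{`enabled` (default FALSE), `top_n`.}
#'   \item{seed}{top-level integer seed.}
#' }
#'
#' @param config nested list or YAML file path.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the `report` (an `htinet_cv`), the run
#'   `paths`, and the resolved `config`.
#' @export
htinet_run <- function(config, out_dir) {
  cfg <- resolve_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cfg$synth)) {
    scfg <- do.call(synth_config,
                    c(cfg$synth, list(seed = derive_seed(cfg$seed, "synth"))))
    gen <- generate_network(scfg)
    network <- gen$network
    positives <- gen$positives
  } else {
    network <- read_edge_lists(cfg$edge_files)
    tab <- read.delim(cfg$positives_file, header = FALSE,
                      stringsAsFactors = FALSE)
    positives <- data.frame(herb = namespace_id(tab[[1]], "herb"),
                            protein = namespace_id(tab[[2]], "protein"),
                            stringsAsFactors = FALSE)
  }
  net_sum <- summary(network)

  emb <- cfg$embedding
  wcfg <- walk_config(p = emb$p, q = emb$q, num_walks = emb$num_walks,
                      walk_length = emb$walk_length,
                      seed = derive_seed(cfg$seed, "walks"))
  embedding <- node2vec(network, d = emb$d, config = wcfg,
                        window = emb$window, negatives = emb$negatives,
                        epochs = emb$epochs, seed = cfg$seed)
  emb_path <- file.path(out_dir, "embeddings.txt")
  write_embeddings(embedding, emb_path)

  spec <- model_spec(cfg$model$family, k = cfg$model$k,
                     seed = derive_seed(cfg$seed, "model"))
  universe <- list(herbs = nodes_of_type(network, "herb"),
                   proteins = nodes_of_type(network, "protein"))
  report <- cross_validate(htinet_pipeline(embedding, spec), positives,
                           universe, n_folds = cfg$evaluation$folds,
                           seed = derive_seed(cfg$seed, "cv"))
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(model = report$name, n_folds = report$n_folds,
         per_fold = report$per_fold, mean_auroc = report$mean_auroc,
         mean_aupr = report$mean_aupr),
    report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  rank_path <- NULL
  if (isTRUE(cfg$ranking$enabled)) {
    neg <- sample_negatives(positives, universe$herbs, universe$proteins,
                            n = nrow(positives),
                            seed = derive_seed(cfg$seed, "fit_negatives"))
    x <- featurize_pairs(embedding,
                         rbind(positives[, c("herb", "protein")], neg))
    scorer <- train_model(spec, x,
                          c(rep(1, nrow(positives)), rep(0, nrow(neg))))
    cand <- enumerate_candidates(universe$herbs, universe$proteins,
                                 exclude = positives)
    ranking <- rank_unknown_pairs(scorer, embedding, cand)
    if (!is.null(cfg$ranking$top_n)) {
      ranking <- head(ranking, cfg$ranking$top_n)
    }
    rank_path <- file.path(out_dir, "ranking.tsv")
    write.table(ranking, rank_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(config = cfg,
         seeds = list(top = cfg$seed,
                      walks = derive_seed(cfg$seed, "walks"),
                      model = derive_seed(cfg$seed, "model"),
                      cv = derive_seed(cfg$seed, "cv")),
         network = list(n_nodes = net_sum$n_nodes,
                        n_edges = net_sum$n_edges,
                        nodes_per_type = as.list(net_sum$nodes),
                        edges_per_layer = as.list(net_sum$edges)),
         package_version = as.character(utils::packageVersion("htinet"))),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(report = report,
                 paths = list(embeddings = emb_path, report = report_path,
                              ranking = rank_path,
                              manifest = manifest_path),
                 config = cfg))
}

resolve_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$synth) &&
      (is.null(cfg$edge_files) || is.null(cfg$positives_file))) {
    stop("config needs either a 'synth' section or edge_files + ",
         "positives_file")
  }
  if (!is.null(cfg$edge_files)) {
    missing <- cfg$edge_files[!file.exists(cfg$edge_files)]
    if (length(missing) > 0) {
      stop("edge file(s) not found: ", paste(missing, collapse = ", "))
    }
  }
  emb_def <- list(d = 64L, num_walks = 10L, walk_length = 40L, p = 1,
                  q = 1, window = 10L, negatives = 5L, epochs = 5L)
  cfg$embedding <- utils::modifyList(emb_def, cfg$embedding %||% list())
  cfg$model <- utils::modifyList(list(family = "knn", k = 5L),
                                 cfg$model %||% list())
  cfg$evaluation <- utils::modifyList(list(folds = 10L),
                                      cfg$evaluation %||% list())
  cfg$ranking <- utils::modifyList(list(enabled = FALSE, top_n = NULL),
                                   cfg$ranking %||% list())
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg
}

#' Evaluate the pipeline over a parameter grid
#'
#' Runs [cross_validate()] at every point of a parameter grid (any of
#' the embedding or model parameters accepted by [htinet_run()]'s
#' config, e.g. `d`, `num_walks`, `k`) and tabulates mean AUROC/AUPR.
#' Embeddings are cached across grid points that share embedding
#' parameters, so a sweep over `k` retrains only the classifier.
#'
#' @param config base configuration (list or YAML path) as for
#'   [htinet_run()].
#' @param grid named list of parameter vectors; the grid is their cross
#'   product.
#' @return data.frame with one row per grid point: the parameter values,
#'   `mean_auroc` and `mean_aupr`. The best row (highest mean AUROC,
#'   AUPR tie-break) index is attached as attribute `best`.
#' @export
htinet_sweep <- function(config, grid) {
  if (length(grid) == 0) stop("empty parameter grid")
  cfg <- resolve_run_config(config)
  if (!is.null(cfg$synth)) {
    scfg <- do.call(synth_config,
                    c(cfg$synth, list(seed = derive_seed(cfg$seed, "synth"))))
    gen <- generate_network(scfg)
    network <- gen$network
    positives <- gen$positives
  } else {
    network <- read_edge_lists(cfg$edge_files)
    tab <- read.delim(cfg$positives_file, header = FALSE,
                      stringsAsFactors = FALSE)
    positives <- data.frame(herb = namespace_id(tab[[1]], "herb"),
                            protein = namespace_id(tab[[2]], "protein"),
                            stringsAsFactors = FALSE)
  }
  universe <- list(herbs = nodes_of_type(network, "herb"),
                   proteins = nodes_of_type(network, "protein"))
  pts <- expand.grid(grid, stringsAsFactors = FALSE)
  emb_names <- c("d", "num_walks", "walk_length", "p", "q", "window",
                 "negatives", "epochs")
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    e <- cfg$embedding
    m <- cfg$model
    for (nm in names(pts)) {
      if (nm %in% emb_names) e[[nm]] <- pts[[nm]][i]
      else m[[nm]] <- pts[[nm]][i]
    }
    ekey <- paste(unlist(e[emb_names]), collapse = "|")
    embedding <- get0(ekey, envir = cache)
    if (is.null(embedding)) {
      wcfg <- walk_config(p = e$p, q = e$q, num_walks = e$num_walks,
                          walk_length = e$walk_length,
                          seed = derive_seed(cfg$seed, "walks"))
      embedding <- node2vec(network, d = e$d, config = wcfg,
                            window = e$window, negatives = e$negatives,
                            epochs = e$epochs, seed = cfg$seed)
      assign(ekey, embedding, envir = cache)
    }
    spec <- model_spec(m$family, k = m$k,
                       seed = derive_seed(cfg$seed, "model"))
    rep <- cross_validate(htinet_pipeline(embedding, spec), positives,
                          universe, n_folds = cfg$evaluation$folds,
                          seed = derive_seed(cfg$seed, "cv"))
    rows[[i]] <- cbind(pts[i, , drop = FALSE],
                       data.frame(mean_auroc = rep$mean_auroc,
                                  mean_aupr = rep$mean_aupr))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  best <- order(-out$mean_auroc, -out$mean_aupr)[1]
  attr(out, "best") <- best
  out
}
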