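#' Default pipeline configuration
#'
#' Every tunable of the five-stage pipeline with its default. A resolved
#' config (the list returned by [run_pipeline()] in `$config`) is
#' sufficient to reproduce a run exactly.
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A named list.
#' @export
default_config <- function(...) {
  base <- list(
    inputs = list(sm = NULL, sm_fps = NULL, mirna = NULL,
                  edges_up = NULL, edges_down = NULL),
    synthetic = NULL,                  # synthetic_config() args, or NULL
    relations = c("up", "down"),
    mode = "full",                     # full | gatne_only | attrs_only | transductive
    kmer = 4,
    negative_threshold = 0.1,
    folds = 5,
    line = list(dim1 = 64, dim2 = 64, epochs = 50, negatives = 5, lr = 0.025),
    gatne = list(d = 128, s = 64, a = 20, K = 1, epochs = 10, batch = 512,
                 lr = 0.15, walk_length = 10, walks_per_vertex = 20,
                 window = 5, negatives = 5),
    classifier = "gbt",
    classifier_params = list(),
    seed = 7L,
    outdir = NULL,
    cache_dir = NULL)
  utils::modifyList(base, list(...))
}

#' Load a pipeline configuration from YAML
#'
#' Values found in the file override the defaults of [default_config()].
#'
#' @param path Path to a YAML file.
#' @return A config list.
#' @export
load_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

# Content-addressed stage cache: the key object is serialized and hashed
# (md5); results are stored as RDS under cache_dir. With cache_dir = NULL
# everything is recomputed.
stage_cache <- function(key, cache_dir, compute) {
  if (is.null(cache_dir)) return(compute())
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(serialize(key, NULL, version = 2), tmp)
  hash <- unname(tools::md5sum(tmp))
  path <- file.path(cache_dir, paste0(hash, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- compute()
  saveRDS(val, path)
  val
}

# Load study inputs from files or generate them synthetically.
resolve_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    cfg <- do.call(synthetic_config, config$synthetic)
    study <- generate_study(cfg)
    return(list(sm_fps = study$fingerprints$sm_fps,
                mirna = study$fingerprints$mirna,
                edges = study$edges))
  }
  inp <- config$inputs
  if (is.null(inp$mirna)) stopf("config needs either $synthetic or input paths")
  sm_fps <- if (!is.null(inp$sm_fps)) {
    read_fingerprint_sidecar(inp$sm_fps)
  } else {
    res <- maccs_fingerprints(read_sm_table(inp$sm))
    res$fingerprints
  }
  edges <- do.call(rbind, lapply(config$relations, function(r) {
    read_edge_list(inp[[paste0("edges_", r)]])
  }))
  class(edges) <- c("regulation_edge_set", "data.frame")
  list(sm_fps = sm_fps, mirna = read_mirna_fasta(inp$mirna), edges = edges)
}

#' Run the five-stage prediction pipeline
#'
#' Executes, in order: (1) multiplex network construction from the
#' regulation edges, (2) Tanimoto self-similarity networks of the small
#' molecules and the miRNAs, (3) LINE node attributes from each similarity
#' network, (4) GATNE embeddings of the attributed multiplex network, and
#' (5) balanced negative sampling plus cross-validated gradient-boosted
#' classification — and reports per-relation [cross_validate()] results.
#' When `config$outdir` is set, the report (JSON), final embeddings
#' (word2vec text), CV predictions (TSV), resolved config (YAML) and a run
#' log are written there; re-running an identical config reproduces the
#' artifacts byte for byte.
#'
#' @param config A config list (see [default_config()]).
#' @param shuffle_labels Negative-control switch passed to
#'   [cross_validate()].
#' @return List with `reports` (per relation), `negatives`, `attributes`,
#'   the final per-relation `embeddings`, and the resolved `config`.
#' @export
run_pipeline <- function(config = default_config(), shuffle_labels = FALSE) {
  stage <- "inputs"
  result <- tryCatch({
    inputs <- resolve_inputs(config)
    seed <- as.integer(config$seed)

    stage <- "similarity"
    mir_fps <- lapply(inputs$mirna$sequence, kmer_fingerprint, k = config$kmer)
    names(mir_fps) <- inputs$mirna$mirna_id
    sim_sm <- similarity_matrix(inputs$sm_fps)
    sim_mir <- similarity_matrix(mir_fps)

    stage <- "line_attributes"
    lp <- config$line
    attributes <- stage_cache(list("line", sim_sm, sim_mir, lp, seed),
                              config$cache_dir, function() {
      att_sm <- line_attributes(sim_sm, dim1 = lp$dim1, dim2 = lp$dim2,
                                epochs = lp$epochs, negatives = lp$negatives,
                                lr = lp$lr, seed = child_seed(seed, 41L))
      att_mir <- line_attributes(sim_mir, dim1 = lp$dim1, dim2 = lp$dim2,
                                 epochs = lp$epochs, negatives = lp$negatives,
                                 lr = lp$lr, seed = child_seed(seed, 42L))
      c(split_rows(att_sm), split_rows(att_mir))
    })

    stage <- "negative_sampling"
    negatives <- lapply(setNames(nm = config$relations), function(r) {
      sample_negatives(inputs$edges, sim_sm, r,
                       threshold = config$negative_threshold,
                       seed = child_seed(seed, 50L + match(r, config$relations)),
                       mirna_ids = inputs$mirna$mirna_id)
    })

    stage <- "cross_validation"
    reports <- lapply(setNames(nm = config$relations), function(r) {
      pos <- inputs$edges[inputs$edges$relation == r, , drop = FALSE]
      stage_cache(list("cv", pos, negatives[[r]], attributes, r, config$mode,
                       config$gatne, config$folds, config$classifier,
                       config$classifier_params, seed, shuffle_labels),
                  config$cache_dir, function() {
        cross_validate(pos, negatives[[r]], attributes, r,
                       k = config$folds, seed = child_seed(seed, 60L + match(r, config$relations)),
                       mode = config$mode, gatne = config$gatne,
                       classifier = config$classifier,
                       classifier_params = config$classifier_params,
                       shuffle_labels = shuffle_labels)
      })
    })

    stage <- "final_embeddings"
    embeddings <- if (config$mode %in% c("full", "gatne_only", "transductive")) {
      all_pairs <- rbind(as.data.frame(inputs$edges),
                         do.call(rbind, lapply(negatives, as.data.frame)))
      hp <- config$gatne
      lapply(setNames(nm = config$relations), function(r) {
        fold_embeddings(inputs$edges[inputs$edges$relation == r, , drop = FALSE],
                        all_pairs[all_pairs$relation == r, , drop = FALSE],
                        attributes, r, config$mode, hp, child_seed(seed, 70L))
      })
    } else NULL

    out <- list(reports = reports, negatives = negatives,
                attributes = attributes, embeddings = embeddings,
                config = config)
    if (!is.null(config$outdir)) write_run_artifacts(out)
    out
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  result
}

split_rows <- function(mat) {
  setNames(lapply(seq_len(nrow(mat)), function(i) mat[i, ]), rownames(mat))
}

write_run_artifacts <- function(result) {
  outdir <- result$config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- lapply(result$reports, function(rep) {
    list(folds = rep$folds, mean = as.list(rep$mean), sd = as.list(rep$sd),
         mode = rep$mode, k = rep$k)
  })
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  preds <- do.call(rbind, lapply(names(result$reports), function(r) {
    cbind(relation = r, result$reports[[r]]$scores)
  }))
  preds$score <- sprintf("%.6f", preds$score)
  write.table(preds, file.path(outdir, "predictions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(result$embeddings)) {
    for (r in names(result$embeddings)) {
      emb <- result$embeddings[[r]]
      rownames(emb) <- paste0(rownames(emb), "@", r)
      write_embeddings(emb, file.path(outdir, paste0("emb_", r, ".w2v")))
    }
  }
  att <- do.call(rbind, result$attributes)
  rownames(att) <- names(result$attributes)
  write_embeddings(att, file.path(outdir, "attrs.w2v"))
  portable <- result$config[setdiff(names(result$config), c("outdir", "cache_dir"))]
  yaml::write_yaml(drop_nulls(portable), file.path(outdir, "config.yaml"))
  log_lines <- c(sprintf("seed: %d", as.integer(result$config$seed)),
                 sprintf("mode: %s", result$config$mode),
                 sprintf("relations: %s", paste(names(result$reports), collapse = ",")),
                 vapply(names(result$reports), function(r) {
                   sprintf("mean AUC (%s): %.6f", r, result$reports[[r]]$mean[["AUC"]])
                 }, character(1)))
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(outdir)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}

#' Sensitivity sweep over embedding dimensions
#'
#' Evaluates the full cross-product of base dimensions `d` and edge
#' dimensions `s` with shared seeds and reports the mean AUC per cell
#' (averaged over the configured relations). A failing cell is recorded as
#' `NA` and the sweep continues.
#'
#' @param config Pipeline config (see [default_config()]).
#' @param base_dims Integer vector of base embedding dimensions.
#' @param edge_dims Integer vector of edge embedding dimensions.
#' @return Data.frame `(d, s, mean_auc)` with one row per grid cell.
#' @export
run_sensitivity <- function(config, base_dims, edge_dims) {
  if (!length(base_dims) || !length(edge_dims)) stopf("empty sweep grid")
  grid <- expand.grid(d = base_dims, s = edge_dims)
  grid$mean_auc <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$gatne$d <- grid$d[[i]]
    cfg$gatne$s <- grid$s[[i]]
    tryCatch({
      res <- run_pipeline(cfg)
      mean(vapply(res$reports, function(r) r$mean[["AUC"]], numeric(1)))
    }, error = function(e) {
      warning(sprintf("sweep cell d=%d s=%d failed: %s", grid$d[[i]],
                      grid$s[[i]], conditionMessage(e)), call. = FALSE)
      NA_real_
    })
  }, numeric(1))
  grid
}
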