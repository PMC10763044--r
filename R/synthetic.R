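#' Configuration of a synthetic regulation study
#'
#' Defines a fully synthetic study with planted block structure: small
#' molecules and miRNAs fall into latent blocks; fingerprints share a
#' per-block template (bit noise on top) so Tanimoto similarity clusters by
#' block, and regulation edges are drawn from a low-rank latent-factor
#' model aligned with the same blocks so that planted links are
#' recoverable by the pipeline.
#'
#' @param n_sm,n_mirna Entity counts (defaults 60 and 40).
#' @param latent_dim Latent factor dimension = number of blocks (default 4).
#' @param n_edges_per_relation Positive edges planted per relation
#'   (default 400).
#' @param fingerprint_block_count Number of fingerprint blocks (default:
#'   `latent_dim`).
#' @param noise_rate Per-bit flip / per-base mutation probability
#'   (default 0.05).
#' @param k k-mer size for miRNA fingerprints (default 4).
#' @param seed Integer master seed.
#' @param null_model If TRUE, generate a signal-free control: fingerprints
#'   are i.i.d. random (no blocks) and latent vectors are independent
#'   standard normals, so edges carry no recoverable structure.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_sm = 60, n_mirna = 40, latent_dim = 4,
                             n_edges_per_relation = 400,
                             fingerprint_block_count = latent_dim,
                             noise_rate = 0.05, k = 4, seed = 7L,
                             null_model = FALSE) {
  if (noise_rate < 0 || noise_rate > 1) stopf("noise_rate must lie in [0, 1]")
  if (latent_dim < 1) stopf("latent_dim must be >= 1")
  if (n_edges_per_relation > n_sm * n_mirna) {
    stopf("requested %d edges but only %d pairs exist", n_edges_per_relation,
          n_sm * n_mirna)
  }
  structure(list(n_sm = n_sm, n_mirna = n_mirna, latent_dim = latent_dim,
                 n_edges_per_relation = n_edges_per_relation,
                 fingerprint_block_count = fingerprint_block_count,
                 noise_rate = noise_rate, k = k, seed = as.integer(seed),
                 null_model = isTRUE(null_model)),
            class = "synthetic_config")
}

#' Generate synthetic fingerprints and miRNA sequences
#'
#' Small-molecule fingerprints are 166-bit keys sharing a non-overlapping
#' bit template per block, with every bit flipped independently at
#' `noise_rate`; miRNA sequences (length 22) repeat a block-specific motif
#' with per-base mutations at the same rate, so k-mer Tanimoto similarity
#' also clusters by block. Deterministic given the config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `sm_fps` (named list of [fingerprint()]s), `mirna`
#'   (data.frame `mirna_id`, `sequence`), and the planted block
#'   assignments `sm_blocks`, `mirna_blocks`.
#' @export
generate_fingerprints <- function(cfg) {
  B <- cfg$fingerprint_block_count
  sm_ids <- sprintf("SM%03d", seq_len(cfg$n_sm))
  mir_ids <- sprintf("mir%03d", seq_len(cfg$n_mirna))
  sm_blocks <- setNames(sort(rep_len(seq_len(B), cfg$n_sm)), sm_ids)
  mirna_blocks <- setNames(sort(rep_len(seq_len(B), cfg$n_mirna)), mir_ids)
  bases <- c("A", "C", "G", "U")

  with_seed(cfg$seed, {
    block_bits <- split(0:165, rep_len(seq_len(B), 166))
    motifs <- vapply(seq_len(B), function(b) {
      paste(sample(bases, 8, replace = TRUE), collapse = "")
    }, character(1))

    sm_fps <- lapply(sm_ids, function(id) {
      bits <- logical(166)
      if (!cfg$null_model) {
        bits[block_bits[[sm_blocks[[id]]]] + 1L] <- TRUE
        flip <- runif(166) < cfg$noise_rate
        bits <- xor(bits, flip)
      } else {
        bits <- runif(166) < 0.2
      }
      if (!any(bits)) bits[sample.int(166, 1L)] <- TRUE
      fingerprint(which(bits) - 1L, 166L)
    })
    names(sm_fps) <- sm_ids

    seqs <- vapply(mir_ids, function(id) {
      if (!cfg$null_model) {
        base_seq <- strsplit(strrep(motifs[[mirna_blocks[[id]]]], 3), "")[[1]][1:22]
        mut <- runif(22) < cfg$noise_rate
        base_seq[mut] <- sample(bases, sum(mut), replace = TRUE)
      } else {
        base_seq <- sample(bases, 22, replace = TRUE)
      }
      paste(base_seq, collapse = "")
    }, character(1))

    list(sm_fps = sm_fps,
         mirna = data.frame(mirna_id = mir_ids, sequence = unname(seqs),
                            stringsAsFactors = FALSE),
         sm_blocks = sm_blocks, mirna_blocks = mirna_blocks)
  })
}

# Latent factors: a centered block component (visible to the fingerprints,
# matching blocks attract, mismatching repel) plus free standard factors
# that only the realized topology can reveal — regulation depends on more
# than chemical/sequence similarity.
synthetic_latents <- function(cfg, blocks, seed_offset) {
  B <- cfg$latent_dim
  with_seed(child_seed(cfg$seed, seed_offset), {
    t(vapply(blocks, function(b) {
      if (cfg$null_model) {
        rnorm(B)
      } else {
        base <- numeric(B)
        base[(b - 1L) %% B + 1L] <- 1
        sqrt(8) * (base - 1 / B) + rnorm(B, sd = 0.8)
      }
    }, numeric(B)))
  })
}

#' Generate planted regulation edges
#'
#' Each entity receives a latent vector aligned with its fingerprint
#' block; for every relation, `n_edges_per_relation` positive pairs are
#' drawn without replacement with probability proportional to the sigmoid
#' of the latent inner product (weighted order sampling), independently
#' per relation. Deterministic given the config seed.
#'
#' @param cfg A [synthetic_config()].
#' @param fps Output of [generate_fingerprints()].
#' @return A `regulation_edge_set` with both `up` and `down` layers and
#'   attribute `latents` carrying the planted factors.
#' @export
generate_edges <- function(cfg, fps) {
  sm_lat <- synthetic_latents(cfg, fps$sm_blocks, 21L)
  mir_lat <- synthetic_latents(cfg, fps$mirna_blocks, 22L)
  aff <- sigmoid(sm_lat %*% t(mir_lat))
  # Degree-balance the propensities (Sinkhorn normalization) so the planted
  # signal lies in pair affinity rather than node popularity.
  for (it in seq_len(10L)) {
    aff <- aff / rowSums(aff)
    aff <- t(t(aff) / colSums(aff))
  }
  aff <- aff / max(aff)
  pairs <- expand.grid(sm = rownames(aff), mir = colnames(aff),
                       stringsAsFactors = FALSE)
  w <- aff[cbind(pairs$sm, pairs$mir)]

  pick_layer <- function(offset) {
    keys <- with_seed(child_seed(cfg$seed, offset), runif(nrow(pairs))^(1 / w))
    order(keys, decreasing = TRUE)[seq_len(cfg$n_edges_per_relation)]
  }
  up <- pick_layer(31L)
  down <- pick_layer(32L)
  out <- edge_set(c(pairs$sm[up], pairs$sm[down]),
                  c(pairs$mir[up], pairs$mir[down]),
                  c(rep("up", length(up)), rep("down", length(down))))
  attr(out, "latents") <- list(sm = sm_lat, mirna = mir_lat)
  out
}

#' Generate a complete synthetic study in memory
#'
#' @param cfg A [synthetic_config()].
#' @return List with `fingerprints` (the [generate_fingerprints()] output),
#'   `edges` (a `regulation_edge_set`), and `cfg`.
#' @export
generate_study <- function(cfg) {
  fps <- generate_fingerprints(cfg)
  edges <- generate_edges(cfg, fps)
  list(fingerprints = fps, edges = edges, cfg = cfg)
}

#' Write a synthetic study to disk
#'
#' Emits `sm.tsv` (with a placeholder SMILES column), `sm_fps.tsv`
#' (precomputed fingerprint sidecar so the cheminformatics backend stays
#' optional), `mirna.fasta`, `edges_up.tsv`, `edges_down.tsv` and
#' `truth.json`. Re-running with the same config produces byte-identical
#' files.
#'
#' @param cfg A [synthetic_config()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_study(cfg)
  fps <- study$fingerprints
  paths <- c(sm = file.path(outdir, "sm.tsv"),
             sm_fps = file.path(outdir, "sm_fps.tsv"),
             mirna = file.path(outdir, "mirna.fasta"),
             edges_up = file.path(outdir, "edges_up.tsv"),
             edges_down = file.path(outdir, "edges_down.tsv"),
             truth = file.path(outdir, "truth.json"))

  sm_tab <- data.frame(sm_id = names(fps$sm_fps), smiles = "*")
  write.table(sm_tab, paths[["sm"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_fingerprint_sidecar(fps$sm_fps, paths[["sm_fps"]])
  writeLines(paste0(">", fps$mirna$mirna_id, "\n", fps$mirna$sequence),
             paths[["mirna"]])
  for (r in c("up", "down")) {
    sub <- study$edges[study$edges$relation == r, c("sm_id", "mirna_id", "relation")]
    write.table(sub, paths[[paste0("edges_", r)]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  truth <- list(config = unclass(cfg),
                sm_blocks = as.list(fps$sm_blocks),
                mirna_blocks = as.list(fps$mirna_blocks),
                n_edges = nrow(study$edges))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Write / read a fingerprint sidecar table
#'
#' Plain-text fingerprint exchange format: one row per entity with the
#' fingerprint length and the comma-separated 0-based set-bit indices.
#'
#' @param fps Named list of [fingerprint()] objects.
#' @param path File path.
#' @return For the reader, a named list of [fingerprint()] objects.
#' @export
write_fingerprint_sidecar <- function(fps, path) {
  tab <- data.frame(id = names(fps),
                    length = vapply(fps, function(f) f$length, integer(1)),
                    bits = vapply(fps, function(f) paste(f$bits, collapse = ","),
                                  character(1)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_sidecar
#' @export
read_fingerprint_sidecar <- function(path) {
  tab <- read.delim(path, sep = "\t", colClasses = "character")
  fps <- lapply(seq_len(nrow(tab)), function(i) {
    fingerprint(as.integer(strsplit(tab$bits[[i]], ",")[[1]]),
                as.integer(tab$length[[i]]))
  })
  names(fps) <- tab$id
  fps
}
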