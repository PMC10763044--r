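# Internal helpers: id namespacing, seeded evaluation, logging.

# Vertex ids are namespaced internally so a small molecule and a miRNA can
# never collide; external files always carry the raw ids.
ns_sm <- function(ids) paste0("sm:", ids)
ns_mir <- function(ids) paste0("mir:", ids)

strip_ns <- function(ids) sub("^(sm|mir):", "", ids)

ns_type <- function(ids) {
  type <- rep(NA_character_, length(ids))
  type[startsWith(ids, "sm:")] <- "SM"
  type[startsWith(ids, "mir:")] <- "miRNA"
  if (anyNA(type)) {
    stop("un-namespaced vertex ids: ", paste(head(ids[is.na(type)], 5L), collapse = ", "))
  }
  type
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed (< 2^31) for a named pipeline stage.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

msg_log <- function(..., verbose = getOption("mhesmmr.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[mhesmmr] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))
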