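# Internal helpers: classed conditions, seed management, atomic writes.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed errors so callers/tests can discriminate failure modes:
#   fe_param_error      - invalid argument value
#   fe_data_error       - inputs structurally valid but insufficient/missing
#   fe_format_error     - unparseable file
#   fe_validation_error - object violates a container invariant
#   fe_degenerate_error - mathematically degenerate input (e.g. constant signal)
fe_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "fe_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

fe_warn <- function(class, msg) {
  warning(structure(
    class = c(class, "fe_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    fe_stop("fe_param_error",
            sprintf("`%s` must be a single integer >= %d", name, min))
  }
}

stopifnot_prob_open <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    fe_stop("fe_param_error", sprintf("`%s` must lie strictly in (0, 1)", name))
  }
}

# Run `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL runs in the ambient stream.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Reproducible seed splitting: the only entropy source is `master`; sub-seeds
# are a deterministic function of (master, n).  Kept below 2^31.
derive_seeds <- function(master, n) {
  with_seed_opt(as.integer(master), sample.int(.Machine$integer.max - 1L, n))
}

# Crash-safe write: materialize in a temp file in the target directory, then
# rename into place (atomic on POSIX filesystems).
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    fe_stop("fe_validation_error", sprintf("could not move output into '%s'", path))
  }
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  atomic_write(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

read_tsv_plain <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE, ...)
}
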