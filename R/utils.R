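# internal validators and small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_("'%s' must be a single finite number", name)
  if (integer && x != round(x))
    stop_("'%s' must be an integer", name)
  if (x < lower || x > upper)
    stop_("'%s' must be in [%s, %s] (got %s)", name, lower, upper, x)
  invisible(x)
}

check_prob <- function(x, name) check_number(x, name, 0, 1)

check_columns <- function(df, cols, name) {
  if (!is.data.frame(df)) stop_("'%s' must be a data.frame", name)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_("'%s' is missing required column(s): %s", name,
          paste(miss, collapse = ", "))
  invisible(df)
}

# normal-approximation 95% CI of a mean; NA bounds when n < 2
mean_ci95 <- function(x) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(mean = m, lo = NA_real_, hi = NA_real_))
  se <- stats::sd(x) / sqrt(n)
  c(mean = m, lo = m - 1.96 * se, hi = m + 1.96 * se)
}

# Deterministic per-client substream seed: adding clients never perturbs the
# draws of earlier clients. Kept below 2^31 for R's 32-bit integer seeds.
client_substream_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + index * 1000003) %%
               2147483647)
}

# md5 of an on-disk file (coefficient-file checksums for run logs)
file_md5 <- function(path) unname(tools::md5sum(path))

# md5 of an arbitrary R object via canonical JSON serialization
object_md5 <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  file_md5(tmp)
}
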