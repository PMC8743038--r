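# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never clobbers the
# user's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Locale-independent lexicographic sort (C collation) so matrix row/column
# order is bit-identical across machines.
sort_c <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Stable decimal formatting used by all writers: enough digits for an exact
# double round-trip, '.' decimal separator, no scientific-notation surprises
# between platforms.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    sprintf("%.17g", v)
  }, character(1))
  out
}

package_version_string <- function() {
  as.character(utils::packageVersion("dndscape"))
}

# Deterministic hash of a parameter list (paths excluded by the caller):
# serialize to canonical JSON, md5 the bytes.  Used to stamp outputs.
params_hash <- function(params) {
  json <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp, sep = "")
  unname(tools::md5sum(tmp))
}

is_count <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x == floor(x))
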