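# Internal helpers shared across modules.

# Locale-independent lexicographic ordering for identifiers. All tie rules in
# the package (facility labels, node snapping, candidate ranking) rely on this
# so that results do not depend on the session's collation locale.
lex_order <- function(x, ...) order(x, ..., method = "radix")

lex_min <- function(x) {
  stopifnot(length(x) > 0L)
  x[lex_order(x)][1L]
}

lex_sort <- function(x) x[lex_order(x)]

# Great-circle distance in meters between one query point and many points,
# lon/lat in degrees (WGS84). Used only for snapping, never for routing.
haversine_m <- function(lon, lat, lons, lats) {
  geosphere::distHaversine(c(lon, lat), cbind(lons, lats))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
# state afterwards so fixture generation never perturbs user simulations.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# JSON writer used by every artifact the package emits: fixed key order (the
# order of the list as constructed), floats rounded to 6 decimals, scalars
# unboxed. Rounding makes re-runs byte-identical across platforms.
round6 <- function(x) {
  if (is.double(x)) return(round(x, 6))
  if (is.list(x)) return(lapply(x, round6))
  x
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(round6(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

stop_phase <- function(phase, ...) {
  stop(sprintf("[%s] %s", phase, paste0(...)), call. = FALSE)
}
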