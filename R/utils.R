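# Small shared helpers.

# Run code under a temporary RNG state; restores the caller's stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# EXIF-style timestamp strings: "YYYY:MM:DD HH:MM:SS", timezone-naive.
# All timestamps in the package are handled as naive local times pinned to
# UTC so that arithmetic is DST-free.
.format_exif_time <- function(t) format(t, "%Y:%m:%d %H:%M:%S", tz = "UTC")

.parse_exif_time <- function(s) {
  as.POSIXct(s, format = "%Y:%m:%d %H:%M:%S", tz = "UTC")
}
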