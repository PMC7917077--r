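#' @keywords internal
"_PACKAGE"

# Round half away from zero, matching how the scores are printed in reports
# (base round() uses round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Stable hash of an R object (via its canonical JSON serialization) used to
# stamp outputs with the configuration that produced them.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           force = TRUE, null = "null")), tf)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
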