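# Internal helpers: seeded evaluation, argument checks, time/index conventions.
#
# Conventions used package-wide: times are seconds from recording start,
# sample indexing is 1-based in R but windows are half-open [t0, t1) in
# seconds, and all randomized operations take an explicit `seed`.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded operations do not
#' perturb the global random stream. A `NULL` seed evaluates the code under
#' the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministically fan a master seed out into n stage-local seeds.
seed_stream <- function(seed, n) {
  if (is.null(seed)) {
    return(rep(list(NULL), n))
  }
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

#' Sleep stage labels
#'
#' The five AASM stage labels used throughout the package, in wake-to-deep
#' order (REM last).
#' @return Character vector `c("Wake", "N1", "N2", "N3", "REM")`.
#' @export
sleep_stages <- function() c("Wake", "N1", "N2", "N3", "REM")

# Map common stage-label synonyms onto canonical labels.
canonical_stage <- function(x) {
  map <- c(
    "W" = "Wake", "WAKE" = "Wake", "Wake" = "Wake", "0" = "Wake",
    "N1" = "N1", "1" = "N1", "S1" = "N1",
    "N2" = "N2", "2" = "N2", "S2" = "N2",
    "N3" = "N3", "3" = "N3", "S3" = "N3", "SWS" = "N3",
    "R" = "REM", "REM" = "REM", "5" = "REM"
  )
  out <- map[as.character(x)]
  if (anyNA(out)) {
    bad <- unique(as.character(x)[is.na(out)])
    stopf("unknown sleep stage label(s): %s", paste(bad, collapse = ", "))
  }
  unname(out)
}
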