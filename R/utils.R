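# Internal helpers: classed error conditions, logging, number formatting.
#
# Error classes map onto the CLI exit codes (validation 2, parse 3,
# degenerate statistics 4); see inst/scripts/ewgo.

.ewgoStop <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "ewgo_error", "error", "condition")))
}

.parseError      <- function(msg) .ewgoStop("ewgo_parse_error", msg)
.validationError <- function(msg) .ewgoStop("ewgo_validation_error", msg)
.domainError     <- function(msg) .ewgoStop("ewgo_domain_error", msg)
.integrityError  <- function(msg) .ewgoStop("ewgo_integrity_error", msg)
.degenerateError <- function(msg) .ewgoStop("ewgo_degenerate_error", msg)

# Logging to stderr with a simple level filter; default INFO.
.logLevels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

.log <- function(level, ...) {
  threshold <- toupper(getOption("ewGO.logLevel", "INFO"))
  if (.logLevels[[level]] >= .logLevels[[threshold]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# Fixed-precision serialization (12 significant digits) keeps TSV reruns
# byte-identical.
.fmtNum <- function(x, digits = 12L) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

# Evaluate `code` under a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.isGOAccession <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9_]*:[0-9]+$", x)
}
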