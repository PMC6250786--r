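#' @keywords internal
"_PACKAGE"

## Founder population labels used throughout: the two wild isolates whose
## hybrids the simulator and statistics describe.
POPULATIONS <- c("AF16", "HK104")

## Genotype call tokens: A = AF16 allele, H = HK104 allele.
CALL_TOKENS <- c("AA", "HH", "AH")

## Metadata columns every genotype table carries before its marker columns.
TABLE_META_COLS <- c("line_id", "design", "male_pop", "herm_pop", "mitotype")

DESIGNS <- c("AI-RIL", "F2RIL")

pop_letter <- c(AF16 = "A", HK104 = "H")

hom_call <- function(pop) {
  l <- pop_letter[[pop]]
  paste0(l, l)
}

other_pop <- function(pop) POPULATIONS[POPULATIONS != pop]

assert_pop <- function(pop, what = "population") {
  if (length(pop) != 1L || !pop %in% POPULATIONS) {
    stop_validation(sprintf(
      "unknown %s label '%s' (expected one of: %s)",
      what, paste(pop, collapse = ","), paste(POPULATIONS, collapse = ", ")
    ))
  }
  pop
}

## Classed conditions so callers (and the CLI wrapper) can distinguish bad
## usage/config from runtime failures such as design extinction.
stop_usage <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("rilTRD_usage_error", "rilTRD_error")))
}

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("rilTRD_validation_error", "rilTRD_error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("rilTRD_format_error", "rilTRD_error")))
}

stop_runtime <- function(msg) {
  stop(errorCondition(msg, class = c("rilTRD_runtime_error", "rilTRD_error")))
}

#' Round half away from zero
#'
#' Fixed-precision rounding used for human-readable allele fractions, where
#' 0.445 must print as 0.45 (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places kept.
#' @return `x` rounded with halves going up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Deterministic Lehmer-style seed mixer.  Derives independent substream
## seeds from (master seed, replicate, attempt, ...) so every replicate and
## every restart after extinction is individually reproducible.  All
## arithmetic stays below 2^53 so the result is exact in doubles.
mix_seed <- function(seed, ...) {
  m <- 2147483647
  a <- 48271
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    s <- (s * a + as.numeric(k) + 1) %% m
  }
  s <- (s * a + 1) %% m
  as.integer(s)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "rilTRD")
  if (!nzchar(path)) {
    stop_runtime(sprintf("bundled data file '%s' not found", file))
  }
  path
}
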