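# Internal helpers: seeded RNG scoping, Laplace draws, significance stars.

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions never disturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministically forks one master seed into named substreams so that each
#' pipeline stage has its own reproducible stream. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param name substream label.
#' @return integer seed.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  as.integer((as.numeric(seed) %% m * 48271 + h) %% m)
}

#' Draw from a Laplace (double-exponential) distribution
#'
#' @param n number of draws.
#' @param location location parameter.
#' @param scale scale parameter b (> 0).
#' @return numeric vector.
#' @export
rlaplace <- function(n, location = 0, scale = 1) {
  stopifnot(scale > 0)
  u <- stats::runif(n, -0.5, 0.5)
  location - scale * sign(u) * log1p(-2 * abs(u))
}

#' Significance stars at the conventional 0.05 / 0.01 / 0.001 levels
#' @param p numeric vector of p-values.
#' @return character vector of "", "*", "**", "***".
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

# Parse numbers that may use the Unicode minus sign (U+2212), as the deposited
# supplementary tables do. Returns NA for unparseable entries without warning.
parse_signed_num <- function(x) {
  x <- gsub("−", "-", as.character(x), fixed = TRUE)
  suppressWarnings(as.numeric(x))
}
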