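#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_chr map_lgl imap list_rbind
#' @importFrom tidyr pivot_longer pivot_wider
NULL

# Derive a per-stage RNG seed from the root seed so each pipeline stage owns
# an independent, reproducible substream. Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  stages <- c(
    cohort = 1L, expression = 2L, aging = 3L, de = 4L,
    partition = 5L, enrichment = 6L, misc = 7L
  )
  idx <- stages[[stage]]
  as.integer((as.double(seed) %% 1e6) * 1009 + idx * 97) %% 2147483646L + 1L
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Split a ";"-delimited disease-code field into a character vector.
split_codes <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

assert_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    abort(paste0("`", name, "` must be finite."))
  }
  invisible(x)
}
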