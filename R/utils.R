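#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map2 imap pmap list_rbind
#' @importFrom stats median rnorm rpois runif rbinom t.test var sd setNames
#' @importFrom utils head tail
NULL

# Evaluate `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic 31-bit polynomial hash of a character string. Used to key
# per-image random draws to image identity so sampling is invariant to the
# order in which images are listed. Exact in double arithmetic (values < 2^36).
string_hash <- function(x, seed = 0L) {
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(as.character(x))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Hash a (nested) list deterministically, for config provenance stamps.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger", "niceNames", "showAttributes")),
               collapse = "\n")
  sprintf("%08x", string_hash(txt))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "gs_invalid_spec")
  }
  bad_low <- if (strict_lower) x <= lower else x < lower
  if (bad_low || x > upper) {
    abort(sprintf("`%s` = %s is outside its allowed range %s%s, %s].",
                  name, format(x), if (strict_lower) "(" else "[",
                  format(lower), format(upper)),
          class = "gs_invalid_spec")
  }
  invisible(x)
}
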