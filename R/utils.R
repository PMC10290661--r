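# Internal helpers: argument checks and seeded substreams.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stopf("`%s` must be numeric and non-missing", name)
  }
  ok <- if (strict_lower) x > lower else x >= lower
  if (!all(ok & x <= upper)) {
    stopf("`%s` must lie in %s%g, %g]", name,
          if (strict_lower) "(" else "[", lower, upper)
  }
  invisible(x)
}

#' Derive a reproducible substream seed from a master seed and a label
#'
#' Per-plot random substreams are derived by stable hashing of the plot id,
#' so results never depend on the order in which plots are generated.
#' Uses an FNV-1a style accumulation over the label's UTF-8 bytes, folded
#' into the 31-bit signed-integer range accepted by [set.seed()].
#'
#' @param master integer master seed.
#' @param label character scalar (e.g. a plot id).
#' @return An integer in `[0, 2^31 - 1)`.
#' @keywords internal
substream_seed <- function(master, label) {
  bytes <- utf8ToInt(enc2utf8(as.character(label)))
  h <- (as.double(master) %% 2147483647) + 2166136261
  for (b in bytes) {
    h <- (h + b) * 16777619
    h <- h %% 2147483647
  }
  as.integer(floor(h))
}

# Evaluate `expr` under a local RNG state seeded from (master, label).
with_substream <- function(master, label, expr) {
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
  set.seed(substream_seed(master, label))
  expr
}
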