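`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stream seed from a master seed
#'
#' Each synthetic table is generated from its own pseudo-random stream so that
#' enlarging one table does not perturb the others.  Stream seeds are a fixed
#' affine hash of the master seed, kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stream small integer identifying the stream.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483629) + 1L
}

# inclusive whole-day difference; both args Date
days_between <- function(from, to) as.integer(as.numeric(to) - as.numeric(from))

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# sample() without the length-1 surprise
sample_int <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
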