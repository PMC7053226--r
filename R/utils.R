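#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs code unmodified.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` independent stage seeds from one root seed (kept < 2^31).
derive_seeds <- function(seed, n, labels = NULL) {
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  if (!is.null(labels)) names(s) <- labels
  s
}

# Empirical p-value with the (r+1)/(n+1) convention (never exactly zero).
empirical_p <- function(n_ge, n_total) (n_ge + 1) / (n_total + 1)

#' Significance stars for p-values
#'
#' Returns `***`, `**`, `*` at the 0.001, 0.01 and 0.05 levels and `ns`
#' otherwise, the convention used in the package's correlation grids.
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "NA",
    ifelse(p < 0.001, "***",
      ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*", "ns"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ccp <- function(...) stop(..., call. = FALSE)

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_ccp(sprintf("%s: missing mandatory column(s): %s", what,
                     paste(missing, collapse = ", ")))
}
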