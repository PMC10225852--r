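#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream. With `seed = NULL` the code runs on the current
#' stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive deterministic child seeds from one root seed
#'
#' One root seed is fanned out into named child streams so that each
#' stochastic stage of a pipeline is independently reproducible.
#'
#' @param root integer root seed.
#' @param n number of child seeds.
#' @param salt integer stream offset separating independent uses.
#' @return integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @export
child_seeds <- function(root, n, salt = 0L) {
  stopifnot(is.numeric(root), length(root) == 1, n >= 1)
  with_seed(as.integer(root) + as.integer(salt),
            sample.int(.Machine$integer.max - 1L, n))
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
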