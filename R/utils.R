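# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards, so seeded helpers do
#' not perturb an enclosing simulation.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_input(...)
  invisible(TRUE)
}

# Shared writer: TSV body preceded by a single commented header line recording
# provenance (version + caller-supplied parameters).  Deterministic: no
# timestamps, so reruns are byte-identical.
write_result_tsv <- function(df, path, params = character()) {
  ver <- as.character(utils::packageVersion("coexsurv"))
  meta <- paste(c(paste0("coexsurv=", ver), params), collapse = " ")
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_result_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
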