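#' Run an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random-number stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize a stream to save
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Draw one Dirichlet vector via normalized gammas
#' @param alpha Positive concentration vector.
#' @return Numeric vector summing to 1.
#' @keywords internal
rdirichlet1 <- function(alpha) {
  stopifnot(all(alpha > 0))
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # guard against all-zero underflow
  g / sum(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as deterministic TSV
#' @keywords internal
write_tsv_det <- function(df, path, header_comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

stop_es <- function(...) stop(..., call. = FALSE)
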