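`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.log_levels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L)

#' Emit a log message to standard error
#'
#' Messages below the threshold set by `options(cisenrich.log_level = ...)`
#' (default `"INFO"`) are suppressed.
#'
#' @param level One of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @param ... Message fragments pasted together with no separator.
#' @return Invisibly, the message string (or `NULL` if suppressed).
#' @export
ce_log <- function(level = "INFO", ...) {
  level <- match.arg(level, names(.log_levels))
  threshold <- getOption("cisenrich.log_level", "INFO")
  if (.log_levels[[level]] < .log_levels[[threshold]]) return(invisible(NULL))
  msg <- paste0("[", level, "] ", paste0(..., collapse = ""))
  message(msg)
  invisible(msg)
}

# locale-independent sort so outputs are byte-identical everywhere
sort_c <- function(x) sort(x, method = "radix")

# run code under a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# open a (possibly gzip-compressed) text file and read all lines
read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
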