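# Shared helpers: identifier sanitization, atomic file writes, seeded RNG
# scopes, newline-delimited set files.

#' Make an identifier filesystem-safe
#'
#' Characters outside `[A-Za-z0-9.-]` are replaced by underscore so
#' identifiers can be used as path components on any filesystem.
#'
#' @param x character vector of identifiers.
#' @return sanitized character vector.
#' @export
sanitize_identifier <- function(x) {
  gsub("[^A-Za-z0-9.-]", "_", x)
}

# Write lines to a file via temp-file + atomic rename, creating parents.
atomic_write_lines <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- paste0(path, ".tmp.", Sys.getpid())
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

# Read a newline-delimited set file; missing file = empty set.
read_set_file <- function(path) {
  if (!file.exists(path)) return(character(0))
  x <- readLines(path, warn = FALSE)
  x[nzchar(x)]
}

# Evaluate expr with a locally fixed RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Minutes as difftime, for readable defaults.
minutes <- function(x) as.difftime(x, units = "mins")
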