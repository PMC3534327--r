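# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Parse "start-end" interval strings into a 2-column integer matrix.
# Empty / NA input yields a 0-row matrix. Coordinates are 1-based inclusive.
parse_intervals <- function(x, sep = ";") {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(x, sep, fixed = TRUE)[[1]], "-", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 2L, logical(1))
  if (any(bad)) {
    stop("malformed interval string: ", x, call. = FALSE)
  }
  m <- t(vapply(parts, function(p) as.integer(p), integer(2)))
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

format_intervals <- function(m, sep = ";") {
  if (is.null(m) || nrow(m) == 0) return("")
  paste(paste0(m[, "start"], "-", m[, "end"]), collapse = sep)
}

# 1-based inclusive overlap length of two intervals.
interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

check_interval <- function(start, end, length, what, where) {
  if (anyNA(c(start, end))) {
    stop(what, " interval has a missing bound (", where, ")", call. = FALSE)
  }
  if (start < 1L || end < start || end > length) {
    stop(what, " interval ", start, "-", end,
         " violates 1 <= start <= end <= length (", where, ")", call. = FALSE)
  }
  invisible(TRUE)
}

# Split a semicolon-separated cell into a character vector ("" -> empty).
split_cell <- function(x, sep = ";") {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, sep, fixed = TRUE)[[1]]
}

join_cell <- function(x, sep = ";") {
  if (length(x) == 0) "" else paste(x, collapse = sep)
}

# Named random streams: one global seed plus a stream label give an
# independent, reproducible seed, so adding a new generated field never
# perturbs existing streams. Horner hash modulo a Mersenne prime keeps the
# derived seed inside 32-bit integer range.
stream_seed <- function(seed, stream) {
  p <- 2147483629
  h <- as.double(seed %% p)
  for (k in utf8ToInt(stream)) {
    h <- (h * 131 + k) %% p
  }
  as.integer(h)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_path <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("'path' must be a single file path", call. = FALSE)
  }
  invisible(path)
}
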