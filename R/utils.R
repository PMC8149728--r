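# Shared internal helpers: condition classes, logging, quantile cuts, seeded RNG.

new_intercom_error <- function(msg, class) {
  structure(
    class = c(class, "intercom_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

abort_validation <- function(msg, ...) {
  stop(new_intercom_error(sprintf(msg, ...), "intercom_validation_error"))
}

abort_format <- function(msg, ...) {
  stop(new_intercom_error(sprintf(msg, ...), "intercom_format_error"))
}

abort_io <- function(msg, ...) {
  stop(new_intercom_error(sprintf(msg, ...), "intercom_io_error"))
}

abort_convergence <- function(msg, last_iterate = NULL) {
  cond <- new_intercom_error(msg, "intercom_convergence_error")
  cond$last_iterate <- last_iterate
  stop(cond)
}

log_msg <- function(...) {
  if (isTRUE(getOption("intercom.quiet", FALSE))) return(invisible(NULL))
  message("[intercom] ", ...)
}

#' Inclusive upper-quantile membership
#'
#' Returns a logical vector marking values greater than or equal to the
#' linear-interpolation (type 7) `q`-quantile of `x`. Ties at the cut are all
#' kept, so with constant input every element is marked.
#'
#' @param x numeric vector.
#' @param q quantile in `[0, 1]`.
#' @return logical vector, same length as `x`.
#' @keywords internal
quantile_keep <- function(x, q) {
  x >= stats::quantile(x, probs = q, type = 7, names = FALSE)
}

# Read a tab-delimited table with a mandatory header, skipping '#' comments.
read_tsv_checked <- function(path, required, what) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_io("%s file not found: %s", what, as.character(path)[1])
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_format("%s table %s lacks required column(s): %s",
                 what, path, paste(missing, collapse = ", "))
  }
  df
}

# Map sign vocabulary to +1/-1; unknown values give NA_integer_.
parse_sign <- function(x) {
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("1", "+1", "activation", "activate", "+")] <- 1L
  out[x %in% c("-1", "−1", "inhibition", "inhibit", "-")] <- -1L
  out
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
# Keeps all package randomness flowing from explicit integer seeds.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
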