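## Plain-text sample I/O and seeded fixture generation.

#' Read a positive-valued sample from a text file
#'
#' Accepts one value per line or a single comma-separated column;
#' `#` starts a comment (whole line or trailing).  Every parsed value
#' must be positive and finite; offending lines are named in the error.
#'
#' @param path file path.
#' @return Numeric vector of observations.
#' @export
read_sample <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  vals <- numeric(0)
  for (ln in seq_along(lines)) {
    s <- sub("#.*$", "", lines[ln])
    s <- trimws(s)
    if (!nzchar(s)) next
    parts <- trimws(strsplit(s, ",")[[1]])
    parts <- parts[nzchar(parts)]
    v <- suppressWarnings(as.numeric(parts))
    if (any(is.na(v)))
      stop(sprintf("non-numeric value on line %d of %s: '%s'",
                   ln, path, lines[ln]))
    if (any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("nonpositive value on line %d of %s: '%s'",
                   ln, path, lines[ln]))
    vals <- c(vals, v)
  }
  if (length(vals) == 0) stop("no data in ", path)
  vals
}

#' Write a result object to JSON or TSV
#'
#' JSON output keeps full double precision and parses back to the
#' written values; TSV output (for tabular objects) uses 6 significant
#' digits and orders columns as given.
#'
#' @param obj a list or `data.frame` result from this package.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @export
write_report <- function(obj, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    if (inherits(obj, "quadexp_fit")) obj <- unclass(obj)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    if (!is.data.frame(obj)) obj <- as.data.frame(obj)
    num <- vapply(obj, is.numeric, logical(1))
    obj[num] <- lapply(obj[num], signif, digits = 6)
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a seeded synthetic sample with a provenance sidecar
#'
#' Draws `n` values from quadexp(`alpha`, `beta`) under `seed`, writes
#' them one per line to `path`, and writes `<path>.json` recording the
#' parameters, seed, sample size and mixture weights so the fixture is
#' re-derivable.
#'
#' @inheritParams quadexp_mixture_weights
#' @param n sample size.
#' @param seed integer seed.
#' @param path output path for the sample.
#' @return `path`, invisibly.
#' @export
make_fixture <- function(alpha, beta, n, seed, path) {
  .check_ab(alpha, beta)
  set.seed(seed)
  x <- rquadexp(n, alpha, beta)
  writeLines(sprintf("%.17g", x), path)
  side <- list(alpha = alpha, beta = beta, n = n, seed = seed,
               mixture_weights = as.list(quadexp_mixture_weights(alpha, beta)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
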