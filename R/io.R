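## File formats: sample matrices as TSV/CSV of +-1 (or 0/1) entries, model
## configurations as JSON or YAML, partitions as TSV with a JSON diagnostics
## sidecar. All formats are plain text and round-trip losslessly.

#' Read a sample matrix from TSV/CSV
#'
#' One observation per row, one individual per column. A header row of the
#' form `ind_1 .. ind_N` is detected and skipped automatically. With
#' `encoding = "01"` entries in \eqn{\{0, 1\}} are mapped to
#' \eqn{\{-1, +1\}}; any value outside the declared encoding is an error.
#'
#' @param path File path; tab- or comma-separated (by extension, `.csv` means
#'   comma).
#' @param encoding `"pm1"` (entries \eqn{\pm 1}, default) or `"01"`.
#' @return A `"spin_sample"` matrix (method `"file"`).
#' @seealso [write_sample()]
#' @export
read_sample <- function(path, encoding = c("pm1", "01")) {
  encoding <- match.arg(encoding)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  has_header <- grepl("ind", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = sep, header = has_header,
                          colClasses = "numeric")
  X <- as.matrix(df)
  dimnames(X) <- NULL
  if (encoding == "01") {
    if (!all(X == 0 | X == 1)) {
      stop("file declares 0/1 encoding but contains other values")
    }
    X <- 2 * X - 1
  } else if (!all(X == 1 | X == -1)) {
    stop("sample entries must be -1 or +1 (or pass encoding = \"01\")")
  }
  attr(X, "seed") <- NULL
  attr(X, "method") <- "file"
  attr(X, "model_digest") <- NA_character_
  class(X) <- c("spin_sample", class(X))
  X
}

#' Write a sample matrix to TSV/CSV
#'
#' @param sample A `"spin_sample"` or \eqn{\pm 1} matrix.
#' @param path Output path (`.csv` writes comma-separated, else tabs).
#' @param header Write an `ind_1..ind_N` header row (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_sample <- function(sample, path, header = TRUE) {
  X <- unclass(as.matrix(sample))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(paste(paste0("ind_", seq_len(ncol(X))), collapse = sep), con)
  }
  utils::write.table(X, con, sep = sep, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a model configuration (JSON or YAML)
#'
#' Configuration keys: `sizes` (integer list), `J` (nested row-major list),
#' optional `labels`, optional `seed`. Unknown keys are rejected. The format
#' is chosen by extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path Configuration file path.
#' @return A list with `model` (a validated `"block_spin"`) and `seed`
#'   (`NULL` when absent).
#' @seealso [write_model_config()]
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("sizes", "J", "labels", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  }
  if (is.null(cfg$sizes) || is.null(cfg$J)) {
    stop("configuration must contain 'sizes' and 'J'")
  }
  J <- cfg$J
  if (is.list(J)) J <- do.call(rbind, lapply(J, as.numeric))
  J <- as.matrix(J)
  model <- block_spin(cfg$sizes, J, labels = cfg$labels)
  list(model = model, seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed))
}

#' Write a model configuration (JSON or YAML)
#'
#' @param model A `"block_spin"` model.
#' @param path Output path; extension selects the format.
#' @param seed Optional integer seed stored alongside the model.
#' @return `path`, invisibly. The file round-trips bit-exactly through
#'   [read_model_config()].
#' @export
write_model_config <- function(model, path, seed = NULL) {
  stopifnot(inherits(model, "block_spin"))
  cfg <- list(
    sizes = model$sizes,
    J = lapply(seq_len(model$M), function(r) model$J[r, ])
  )
  if (!identical(model$labels, rep.int(seq_len(model$M), model$sizes))) {
    cfg$labels <- model$labels
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = FALSE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path, precision = 17)
  }
  invisible(path)
}

#' Write a detected partition with its diagnostics sidecar
#'
#' Writes a TSV with columns `individual`, `class`, `label_hat` and a JSON
#' sidecar (`<path>.json`) holding the levels, windows, per-class counts and
#' status, so a detection run can be archived and re-read losslessly.
#'
#' @param result A `"grouping_result"`.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @seealso [read_partition()]
#' @export
write_partition <- function(result, path) {
  stopifnot(inherits(result, "grouping_result"))
  N <- length(result$membership)
  lab <- if (is.null(result$labels_hat)) rep(NA_integer_, N) else {
    out <- rep(NA_integer_, N)
    for (ci in seq_along(result$classes)) {
      out[result$classes[[ci]]] <- result$labels_hat[ci]
    }
    out
  }
  df <- data.frame(individual = seq_len(N),
                   class = result$membership,
                   label_hat = lab)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(
    status = result$status,
    levels = result$diagnostics$levels,
    halfwidth = result$diagnostics$halfwidth,
    class_level = result$class_level,
    class_sizes = vapply(result$classes, length, integer(1)),
    notes = result$diagnostics$notes,
    unassigned = result$diagnostics$unassigned
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA, pretty = TRUE, null = "list")
  invisible(path)
}

#' Read back a partition file and its sidecar
#'
#' @param path TSV path written by [write_partition()].
#' @return List with `table` (the data frame) and `diagnostics` (the parsed
#'   sidecar, when present).
#' @export
read_partition <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::fromJSON(side_path) else NULL
  list(table = tab, diagnostics = side)
}

#' The three-party worked-example model
#'
#' A high-temperature benchmark describing a population with one extremist
#' political movement (group 1, strong internal cohesion, antagonistic to
#' group 2), one mainstream party (group 2) and a politically disengaged
#' remainder (group 3), with coupling matrix
#' \deqn{J = \begin{pmatrix} 0.7 & -0.2 & 0.2 \\ -0.2 & 0.6 & 0.1 \\
#'   0.2 & 0.1 & 0.5 \end{pmatrix}.}
#' \eqn{I - J} is positive definite, the diagonal of \eqn{H^{-1}}
#' (\eqn{H = J^{-1} - I}) is strictly ordered, so the three groups occupy
#' three distinct correlation levels and the top level — the most strongly
#' correlated cluster of respondents — identifies the extremists. The same
#' configuration ships as `inst/extdata/three_party.json`.
#'
#' @param sizes Group sizes (default `c(40, 40, 40)`).
#' @return A `"block_spin"` model.
#' @examples
#' round(pair_limit_high(three_party_model())$Hinv, 4)
#' @export
three_party_model <- function(sizes = c(40, 40, 40)) {
  block_spin(sizes, three_party_J())
}

#' @rdname three_party_model
#' @export
three_party_J <- function() {
  matrix(c(0.7, -0.2, 0.2,
           -0.2, 0.6, 0.1,
           0.2, 0.1, 0.5), 3, 3, byrow = TRUE)
}
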