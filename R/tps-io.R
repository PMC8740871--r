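#' Read landmark configurations from a TPS file
#'
#' Parses the tpsDig record dialect: each record starts with `LM=<count>`,
#' followed by one `x y` coordinate line per landmark and key lines
#' `ID=`, `IMAGE=` and `SCALE=`.  Unknown keys are ignored with a warning.
#' Raw coordinates are multiplied by the record's SCALE (cm per raw unit)
#' and the y axis is converted from the image convention (down-positive)
#' to the mathematical convention (up-positive) by negation, so that
#' "higher on the face" means larger y throughout the package.
#'
#' @param path path to the TPS file.
#' @param scheme optional `landmark_scheme`; if given, each record's landmark
#'   count is checked against it.
#' @param default_scale fallback scale (cm per raw unit) for records without
#'   a SCALE key; if `NULL` (default) a missing SCALE is an error.
#' @return A `p x 2 x n` landmark array; subject ids in `dimnames`, per-record
#'   scales in `attr(, "scale_factors")`.
#' @export
read_tps <- function(path, scheme = NULL, default_scale = NULL) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines)
  if (!length(starts)) stop("no LM= records found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  known <- c("LM", "ID", "IMAGE", "SCALE")
  configs <- vector("list", length(starts))
  ids <- character(length(starts))
  scales <- numeric(length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    lm <- as.integer(sub("^LM\\s*=\\s*", "", block[1]))
    keyline <- grepl("^[A-Za-z]+\\s*=", block)
    keys <- toupper(sub("\\s*=.*$", "", block[keyline]))
    unknown <- setdiff(keys, known)
    if (length(unknown))
      warning("record ", r, ": ignoring unknown TPS key(s): ",
              paste(unknown, collapse = ", "))
    coord_lines <- block[!keyline]
    if (length(coord_lines) != lm)
      stop("record ", r, ": LM=", lm, " but ", length(coord_lines),
           " coordinate lines found")
    val <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), block, ignore.case = TRUE, value = TRUE)
      if (!length(hit)) NULL else sub("^[A-Za-z]+\\s*=\\s*", "", hit[1])
    }
    id <- val("ID")
    ids[r] <- if (is.null(id)) paste0("record", r) else id
    sc <- val("SCALE")
    if (is.null(sc)) {
      if (is.null(default_scale))
        stop("record ", r, " (", ids[r], "): missing SCALE and no default_scale given")
      scales[r] <- default_scale
    } else scales[r] <- as.numeric(sc)
    if (!is.finite(scales[r]) || scales[r] <= 0)
      stop("record ", r, ": invalid SCALE")
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), as.numeric))
    if (ncol(xy) != 2 || !all(is.finite(xy)))
      stop("record ", r, ": malformed coordinate lines")
    if (!is.null(scheme) && lm != length(scheme$names))
      stop("record ", r, " (", ids[r], "): LM=", lm,
           " does not match the ", length(scheme$names), "-point scheme")
    configs[[r]] <- cbind(x = xy[, 1] * scales[r], y = -xy[, 2] * scales[r])
  }
  if (length(unique(vapply(configs, nrow, 0L))) != 1)
    stop("records have differing landmark counts")
  A <- as_landmark_array(configs, ids = ids)
  attr(A, "scale_factors") <- scales
  A
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: coordinates are divided by `scale` and the y axis
#' flipped back to image convention, so a write/read round trip reproduces
#' the input.
#'
#' @param A `p x 2 x n` landmark array (cm, y-up) or list of configurations.
#' @param path output path.
#' @param scale cm per raw unit to record as SCALE (scalar or per subject).
#' @param ids subject identifiers (default from `dimnames`).
#' @return `path`, invisibly.
#' @export
write_tps <- function(A, path, scale = 1, ids = NULL) {
  A <- as_landmark_array(A)
  n <- dim(A)[3]
  if (is.null(ids)) ids <- dimnames(A)[[3]]
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  scale <- rep_len(scale, n)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    X <- A[, , i]
    raw <- cbind(X[, 1] / scale[i], -X[, 2] / scale[i])
    writeLines(sprintf("LM=%d", nrow(raw)), con)
    writeLines(sprintf("%.10g %.10g", raw[, 1], raw[, 2]), con)
    writeLines(sprintf("ID=%s", ids[i]), con)
    writeLines(sprintf("SCALE=%.10g", scale[i]), con)
  }
  invisible(path)
}
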