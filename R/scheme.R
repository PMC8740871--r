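#' Landmark scheme: names, roles, symmetry and slider structure
#'
#' A landmark scheme describes a fixed configuration template: the point
#' names, which points are fixed anatomical landmarks and which are
#' semilandmarks on curves, the bilateral left/right pairing, the midline
#' points, and for every semilandmark the (previous, self, next) neighbour
#' triple that defines its sliding tangent.
#'
#' @param names character vector of point labels (unique).
#' @param role character vector, one of `"fixed"` or `"semilandmark"` per point.
#' @param pairs integer matrix with two columns (left index, right index),
#'   one row per bilateral pair.
#' @param midline integer vector of midline point indices.
#' @param sliders integer matrix with columns `prev`, `self`, `next`; one row
#'   per semilandmark.
#' @return An object of class `landmark_scheme`.
#' @export
landmark_scheme <- function(names, role, pairs, midline, sliders) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("left", "right")))
  sliders <- matrix(as.integer(sliders), ncol = 3,
                    dimnames = list(NULL, c("prev", "self", "next")))
  scheme <- structure(
    list(names = as.character(names), role = as.character(role),
         pairs = pairs, midline = as.integer(midline), sliders = sliders),
    class = "landmark_scheme")
  validate_scheme(scheme)
  scheme
}

#' Validate a landmark scheme
#'
#' Checks that roles are known, that every point appears in exactly one of
#' the midline or a bilateral pair, and that slider triples reference
#' distinct valid indices whose `self` entries are exactly the
#' semilandmarks.
#'
#' @param scheme a `landmark_scheme`.
#' @return The scheme, invisibly; errors on violation.
#' @export
validate_scheme <- function(scheme) {
  p <- length(scheme$names)
  if (anyDuplicated(scheme$names))
    stop("duplicated landmark names in scheme")
  if (length(scheme$role) != p || !all(scheme$role %in% c("fixed", "semilandmark")))
    stop("role must be 'fixed' or 'semilandmark' for each of the ", p, " points")
  membership <- c(scheme$midline, as.vector(scheme$pairs))
  if (anyDuplicated(membership))
    stop("point(s) ", paste(unique(membership[duplicated(membership)]), collapse = ", "),
         " appear in more than one of {midline, a bilateral pair}")
  if (!setequal(membership, seq_len(p)))
    stop("every point must appear in exactly one of {midline, a bilateral pair}")
  sl <- scheme$sliders
  if (nrow(sl) > 0) {
    if (any(sl < 1L) || any(sl > p))
      stop("slider indices out of range")
    if (any(apply(sl, 1, anyDuplicated) > 0))
      stop("slider triples must reference distinct points")
    semis <- which(scheme$role == "semilandmark")
    if (!setequal(sl[, "self"], semis))
      stop("slider 'self' entries must be exactly the semilandmarks")
  } else if (any(scheme$role == "semilandmark")) {
    stop("semilandmarks declared but no slider triples given")
  }
  invisible(scheme)
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme:", length(x$names), "points (",
      sum(x$role == "fixed"), "fixed,", sum(x$role == "semilandmark"),
      "semilandmarks ),", nrow(x$pairs), "bilateral pairs,",
      length(x$midline), "midline points\n")
  invisible(x)
}

#' Read a landmark scheme from a YAML file
#'
#' The file holds the fields of [landmark_scheme()]: `names`, `role`,
#' `pairs` (list of two-element vectors), `midline`, and `sliders`
#' (list of three-element vectors).
#'
#' @param path path to the YAML scheme file.
#' @return A validated `landmark_scheme`.
#' @export
load_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("names", "role", "pairs", "midline", "sliders")
  if (!all(need %in% names(y)))
    stop("scheme file must define: ", paste(need, collapse = ", "))
  landmark_scheme(
    names = unlist(y$names), role = unlist(y$role),
    pairs = do.call(rbind, y$pairs),
    midline = unlist(y$midline),
    sliders = if (length(y$sliders)) do.call(rbind, y$sliders) else
      matrix(integer(0), ncol = 3))
}

#' Write a landmark scheme to a YAML file
#'
#' @param scheme a `landmark_scheme`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  y <- list(
    names = scheme$names, role = scheme$role,
    pairs = lapply(seq_len(nrow(scheme$pairs)), function(i) unname(scheme$pairs[i, ])),
    midline = scheme$midline,
    sliders = lapply(seq_len(nrow(scheme$sliders)), function(i) unname(scheme$sliders[i, ])))
  yaml::write_yaml(y, path)
  invisible(path)
}

# Point order of the bundled 71-point frontal-face scheme.
# 9 midline fixed, 14 fixed bilateral pairs, 17 semilandmark pairs
# (10 facial-outline, 3 eyebrow, 2 upper-lip, 2 lower-lip per side).
.frontal71_names <- function() {
  mid <- c("Tr", "Gl", "N", "Prn", "Sn", "Ls", "Sto", "Li", "Gn")
  fp  <- c("Zy", "Go", "Ch", "Al", "Ex", "En", "Ps", "Pi", "Pu",
           "EbM", "EbL", "Chk", "Tmp", "Nst")
  fixed_pairs <- as.vector(rbind(paste0(fp, "_l"), paste0(fp, "_r")))
  semis <- c(paste0("out", 1:10, "_l"), paste0("out", 1:10, "_r"),
             paste0("brow", 1:3, "_l"), paste0("brow", 1:3, "_r"),
             paste0("lipU", 1:2, "_l"), paste0("lipU", 1:2, "_r"),
             paste0("lipL", 1:2, "_l"), paste0("lipL", 1:2, "_r"))
  c(mid, fixed_pairs, semis)
}

#' The bundled 71-point frontal-face landmark scheme
#'
#' Thirty-seven fixed landmarks (9 midline: trichion, glabella, nasion,
#' pronasale, subnasale, labiale superius, stomion, labiale inferius,
#' gnathion; 14 bilateral pairs: zygion, gonion, cheilion, alare, exocanthion,
#' endocanthion, palpebrale superius/inferius, pupil, medial/lateral eyebrow,
#' malar point, temporal hairline, nostril base) plus 34 semilandmarks
#' covering the facial outline, the eyebrows and the lips.  The semilandmark
#' positions along their curves are arbitrary by construction and are
#' optimized by sliding during superimposition.  The scheme is a synthetic
#' stand-in encoding the named anatomical points with plausibly spaced curve
#' points; it is not a digitization template of any real dataset.
#'
#' @return A `landmark_scheme` with 71 points.
#' @export
default_scheme <- function() {
  nm <- .frontal71_names()
  role <- rep(c("fixed", "semilandmark"), c(37L, 34L))
  fixed_pair_idx <- cbind(seq(10L, 36L, by = 2L), seq(11L, 37L, by = 2L))
  semi_pair_idx <- cbind(c(38:47, 58:60, 64:65, 68:69),
                         c(48:57, 61:63, 66:67, 70:71))
  pairs <- rbind(fixed_pair_idx, semi_pair_idx)
  midline <- 1:9
  sl_chain <- function(idx, from, to) {
    full <- c(from, idx, to)
    t(vapply(seq_along(idx), function(k) full[k + 0:2], integer(3)))
  }
  sliders <- rbind(
    sl_chain(38:47, 1L, 9L),   # left outline: Tr .. Gn
    sl_chain(48:57, 1L, 9L),   # right outline
    sl_chain(58:60, 28L, 30L), # left brow: EbM_l .. EbL_l
    sl_chain(61:63, 29L, 31L), # right brow
    sl_chain(64:65, 14L, 6L),  # left upper lip: Ch_l .. Ls
    sl_chain(66:67, 15L, 6L),  # right upper lip
    sl_chain(68:69, 14L, 8L),  # left lower lip: Ch_l .. Li
    sl_chain(70:71, 15L, 8L))  # right lower lip
  landmark_scheme(nm, role, pairs, midline, sliders)
}
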