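#' Classical facial indices from landmark coordinates
#'
#' Computes the twelve classical facial indices from a superimposed (or
#' raw) configuration.  All are dimensionless ratios of Euclidean
#' inter-landmark distances and therefore invariant to rotation,
#' translation and uniform scaling:
#'
#' * `upper_fwhr_n_sto`  = |Zy-Zy| / |N-Sto|
#' * `upper_fwhr_gl_sto` = |Zy-Zy| / |Gl-Sto|
#' * `upper_fwhr_n_ls`   = |Zy-Zy| / |N-Ls|
#' * `upper_fwhr_gl_ls`  = |Zy-Zy| / |Gl-Ls|
#' * `total_fwhr`        = |Zy-Zy| / |N-Gn|
#' * `lower_fwhr`        = |Zy-Zy| / |Sn-Gn|
#' * `cheekbone_prominence` = |Zy-Zy| / |Go-Go|
#' * `mandibular_index`  = |Go-Go| / |Sto-Gn|
#' * `nasal_index`       = |Al-Al| / |N-Sn|
#' * `mouth_shape`       = |Ls-Li| / |Ch-Ch|
#' * `mouth_face_index`  = |Ch-Ch| / |Zy-Zy|
#' * `eye_hw_mean`       = mean of left and right |Ps-Pi| / |Ex-En|
#'
#' Glabella, nasion and stomion are taken from the digitized landmarks when
#' the scheme contains them; otherwise they are derived from their defining
#' points (Gl: midpoint of the eyebrow medial/central points; N: midpoint
#' between the highest eyelid points; Sto: midpoint of labiale superius and
#' inferius).  A zero denominator yields `NaN` for that index with a
#' warning, never silently.
#'
#' @param config `p x 2` configuration conforming to `scheme`.
#' @param scheme `landmark_scheme` with anatomical names.
#' @return Named numeric vector of the 12 indices (class `facial_indices`).
#' @export
compute_indices <- function(config, scheme) {
  X <- as.matrix(config)
  check_against_scheme(X, scheme)
  nm <- scheme$names
  pt <- function(label) {
    i <- match(label, nm)
    if (is.na(i)) NULL else X[i, ]
  }
  midpoint <- function(a, b) if (is.null(a) || is.null(b)) NULL else (a + b) / 2
  # derived-point fallbacks per the classical definitions
  Gl <- pt("Gl")
  if (is.null(Gl)) Gl <- midpoint(pt("brow2_l"), pt("brow2_r"))
  N <- pt("N")
  if (is.null(N)) N <- midpoint(pt("Ps_l"), pt("Ps_r"))
  Sto <- pt("Sto")
  if (is.null(Sto)) Sto <- midpoint(pt("Ls"), pt("Li"))
  need <- list(Gl = Gl, N = N, Sto = Sto, Sn = pt("Sn"), Ls = pt("Ls"),
               Li = pt("Li"), Gn = pt("Gn"),
               Zy_l = pt("Zy_l"), Zy_r = pt("Zy_r"),
               Go_l = pt("Go_l"), Go_r = pt("Go_r"),
               Ch_l = pt("Ch_l"), Ch_r = pt("Ch_r"),
               Al_l = pt("Al_l"), Al_r = pt("Al_r"),
               Ex_l = pt("Ex_l"), Ex_r = pt("Ex_r"),
               En_l = pt("En_l"), En_r = pt("En_r"),
               Ps_l = pt("Ps_l"), Ps_r = pt("Ps_r"),
               Pi_l = pt("Pi_l"), Pi_r = pt("Pi_r"))
  missing <- names(need)[vapply(need, is.null, TRUE)]
  if (length(missing))
    stop("scheme lacks landmarks required for the indices: ",
         paste(missing, collapse = ", "))
  d <- function(a, b) sqrt(sum((a - b)^2))
  ratio <- function(num, den, index) {
    if (den <= .Machine$double.eps) {
      warning("coincident defining points: ", index, " is NaN")
      return(NaN)
    }
    num / den
  }
  zyzy <- d(need$Zy_l, need$Zy_r)
  gogo <- d(need$Go_l, need$Go_r)
  chch <- d(need$Ch_l, need$Ch_r)
  alal <- d(need$Al_l, need$Al_r)
  eye_l <- ratio(d(need$Ps_l, need$Pi_l), d(need$Ex_l, need$En_l), "eye_hw_mean")
  eye_r <- ratio(d(need$Ps_r, need$Pi_r), d(need$Ex_r, need$En_r), "eye_hw_mean")
  out <- c(
    upper_fwhr_n_sto  = ratio(zyzy, d(need$N, need$Sto), "upper_fwhr_n_sto"),
    upper_fwhr_gl_sto = ratio(zyzy, d(need$Gl, need$Sto), "upper_fwhr_gl_sto"),
    upper_fwhr_n_ls   = ratio(zyzy, d(need$N, need$Ls), "upper_fwhr_n_ls"),
    upper_fwhr_gl_ls  = ratio(zyzy, d(need$Gl, need$Ls), "upper_fwhr_gl_ls"),
    total_fwhr        = ratio(zyzy, d(need$N, need$Gn), "total_fwhr"),
    lower_fwhr        = ratio(zyzy, d(need$Sn, need$Gn), "lower_fwhr"),
    cheekbone_prominence = ratio(zyzy, gogo, "cheekbone_prominence"),
    mandibular_index  = ratio(gogo, d(need$Sto, need$Gn), "mandibular_index"),
    nasal_index       = ratio(alal, d(need$N, need$Sn), "nasal_index"),
    mouth_shape       = ratio(d(need$Ls, need$Li), chch, "mouth_shape"),
    mouth_face_index  = ratio(chch, zyzy, "mouth_face_index"),
    eye_hw_mean       = mean(c(eye_l, eye_r)))
  class(out) <- c("facial_indices", class(out))
  out
}

#' Names of the twelve facial indices
#' @return Character vector of length 12.
#' @export
index_names <- function() {
  c("upper_fwhr_n_sto", "upper_fwhr_gl_sto", "upper_fwhr_n_ls",
    "upper_fwhr_gl_ls", "total_fwhr", "lower_fwhr", "cheekbone_prominence",
    "mandibular_index", "nasal_index", "mouth_shape", "mouth_face_index",
    "eye_hw_mean")
}

#' Per-subject table of facial indices
#'
#' Computes the 12 indices for every configuration and joins subject
#' covariates (sex, age, cohort, BMI) when a subjects table is supplied.
#' Subjects that cannot be matched by id are listed and excluded with a
#' warning.
#'
#' @param configs `p x 2 x n` array (ids in `dimnames`) or list.
#' @param scheme `landmark_scheme`.
#' @param subjects optional data.frame with a `subject_id` column plus
#'   covariates.
#' @return data.frame keyed by `subject_id` with 12 index columns (and the
#'   joined covariates).
#' @export
index_table <- function(configs, scheme, subjects = NULL) {
  A <- as_landmark_array(configs)
  ids <- dimnames(A)[[3]]
  if (is.null(ids)) ids <- paste0("s", seq_len(dim(A)[3]))
  idx <- t(apply(A, 3, compute_indices, scheme = scheme))
  out <- data.frame(subject_id = ids, idx, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (!is.null(subjects)) {
    keep <- intersect(c("subject_id", "sex", "age", "cohort", "bmi"),
                      names(subjects))
    unmatched <- setdiff(out$subject_id, subjects$subject_id)
    if (length(unmatched)) {
      warning("excluding unmatched subject id(s): ",
              paste(unmatched, collapse = ", "))
      out <- out[!out$subject_id %in% unmatched, , drop = FALSE]
    }
    out <- merge(subjects[, keep, drop = FALSE], out,
                 by = "subject_id", sort = FALSE)
  }
  out
}
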