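#' Default chromophore extinction matrix
#'
#' Molar extinction coefficients of oxy- and deoxy-hemoglobin at the two
#' laser wavelengths (780 and 850 nm), in (uM cm)^-1, taken from the
#' standard compiled tabulations used across continuous-wave NIRS software.
#' Rows are wavelengths, columns are chromophores (HbO, HbR). All
#' correctness guarantees in the package rest on forward/inverse
#' round-trip consistency, not on these particular numbers; supply your
#' own matrix to use a different tabulation.
#'
#' @return 2 x 2 numeric matrix with dimnames
#'   `list(c("780","850"), c("HbO","HbR"))`.
#' @export
default_extinction_matrix <- function() {
  m <- matrix(c(0.000710, 0.001075,    # 780 nm: HbO, HbR
                0.001058, 0.000691),   # 850 nm: HbO, HbR
              nrow = 2, byrow = TRUE,
              dimnames = list(c("780", "850"), c("HbO", "HbR")))
  m
}

#' Default differential pathlength factors
#'
#' Unitless wavelength-dependent scaling of the geometric source-detector
#' distance: 5.075 at 780 nm and 4.64 at 850 nm.
#'
#' @return named numeric vector of length 2.
#' @export
default_dpf <- function() c("780" = 5.075, "850" = 4.64)

check_extinction <- function(extinction) {
  if (!is.matrix(extinction) || any(dim(extinction) != 2) ||
      !all(is.finite(extinction)))
    stop("extinction matrix must be a finite 2 x 2 matrix")
  if (abs(det(extinction)) < 1e-12)
    stop("singular extinction matrix for wavelength pair (",
         paste(rownames(extinction), collapse = ", "),
         "): cannot separate HbO from HbR")
  invisible(TRUE)
}

#' Forward modified Beer-Lambert law
#'
#' Maps chromophore concentration changes to optical-density changes at
#' each wavelength: `dOD(lambda) = (eps_HbO(lambda) * dHbO +
#' eps_HbR(lambda) * dHbR) * d * DPF(lambda)`, where `d` is the
#' source-detector separation and DPF the differential pathlength factor.
#'
#' @param hbo,hbr concentration changes in uM; vectors, or time x channel
#'   matrices of equal dimension.
#' @param separation source-detector distance(s) in cm; scalar, or one
#'   value per channel when `hbo` is a matrix.
#' @param dpf named vector of DPFs per wavelength (default [default_dpf()]).
#' @param extinction 2 x 2 extinction matrix (wavelength x chromophore),
#'   (uM cm)^-1.
#' @return A time x channel x wavelength array (drops to a matrix
#'   `length(hbo) x 2` for vector input), with wavelength dimnames.
#' @seealso [mbll_invert()] for the inverse transform.
#' @examples
#' od <- forward_mbll(1.0, -0.25, separation = 3)
#' mbll_invert(od, separation = 3)
#' @export
forward_mbll <- function(hbo, hbr, separation, dpf = default_dpf(),
                         extinction = default_extinction_matrix()) {
  check_extinction(extinction)
  vec_in <- !is.matrix(hbo)
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!all(dim(hbo) == dim(hbr))) stop("hbo and hbr dimensions differ")
  if (!all(is.finite(separation)) || any(separation <= 0))
    stop("separation must be positive and finite")
  nc <- ncol(hbo)
  if (length(separation) == 1L) separation <- rep(separation, nc)
  if (length(separation) != nc)
    stop("need one separation per channel")
  if (length(dpf) != 2L) stop("dpf must give one value per wavelength")
  od <- array(0, dim = c(nrow(hbo), nc, 2),
              dimnames = list(NULL, colnames(hbo), rownames(extinction)))
  for (w in 1:2) {
    path <- separation * dpf[w]   # per-channel effective pathlength
    od[, , w] <- sweep(extinction[w, 1] * hbo + extinction[w, 2] * hbr,
                       2, path, `*`)
  }
  if (vec_in) matrix(od, ncol = 2, dimnames = list(NULL, rownames(extinction)))
  else od
}

#' Invert the modified Beer-Lambert law
#'
#' Recovers oxy- and deoxy-hemoglobin concentration changes from
#' two-wavelength optical-density changes by solving, per sample and
#' channel, the 2 x 2 linear system defined by the extinction matrix,
#' separation and DPFs.
#'
#' @param od optical-density changes: a `n x 2` matrix (columns =
#'   wavelengths) or a time x channel x 2 array as produced by
#'   [forward_mbll()].
#' @inheritParams forward_mbll
#' @return list with elements `hbo` and `hbr` (uM), shaped like the input
#'   without the wavelength dimension.
#' @export
mbll_invert <- function(od, separation, dpf = default_dpf(),
                        extinction = default_extinction_matrix()) {
  check_extinction(extinction)
  if (!all(is.finite(separation)) || any(separation <= 0))
    stop("separation must be positive and finite")
  if (length(dpf) != 2L) stop("dpf must give one value per wavelength")
  mat_in <- is.matrix(od)
  if (mat_in) od <- array(od, dim = c(nrow(od), 1, 2))
  if (length(dim(od)) != 3 || dim(od)[3] != 2)
    stop("od must be a n x 2 matrix or a time x channel x 2 array")
  nc <- dim(od)[2]
  if (length(separation) == 1L) separation <- rep(separation, nc)
  if (length(separation) != nc) stop("need one separation per channel")
  inv <- solve(extinction)  # chromophore x wavelength
  # undo the pathlength scaling, then apply the inverse extinction matrix;
  # vectorised over channels
  s1 <- sweep(matrix(od[, , 1], dim(od)[1], nc), 2, separation * dpf[1], `/`)
  s2 <- sweep(matrix(od[, , 2], dim(od)[1], nc), 2, separation * dpf[2], `/`)
  hbo <- inv[1, 1] * s1 + inv[1, 2] * s2
  hbr <- inv[2, 1] * s1 + inv[2, 2] * s2
  if (mat_in) list(hbo = hbo[, 1], hbr = hbr[, 1])
  else list(hbo = hbo, hbr = hbr)
}
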