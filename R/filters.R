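# Analysis filter banks for the supported wavelet families.
#
# Coefficients are the standard published decomposition (analysis) filter
# pairs, in the same orientation used by the common DWT toolboxes: dec_lo is
# the low-pass analysis filter, dec_hi the high-pass analysis filter. For the
# orthogonal families the low-pass coefficients have unit squared sum.

.wavelet_filter_table <- list(
  haar = list(
    orthogonal = TRUE,
    dec_lo = c(0.7071067811865476, 0.7071067811865476),
    dec_hi = c(-0.7071067811865476, 0.7071067811865476)
  ),
  db2 = list(
    orthogonal = TRUE,
    dec_lo = c(-0.12940952255126037, 0.22414386804201339,
               0.83651630373780790, 0.48296291314453416),
    dec_hi = c(-0.48296291314453416, 0.83651630373780790,
               -0.22414386804201339, -0.12940952255126037)
  ),
  db4 = list(
    orthogonal = TRUE,
    dec_lo = c(-0.010597401785069032, 0.032883011666885200,
               0.030841381835560764, -0.187034811719093090,
               -0.027983769416859854, 0.630880767929858900,
               0.714846570552915700, 0.230377813308896500),
    dec_hi = c(-0.230377813308896500, 0.714846570552915700,
               -0.630880767929858900, -0.027983769416859854,
               0.187034811719093090, 0.030841381835560764,
               -0.032883011666885200, -0.010597401785069032)
  ),
  sym4 = list(
    orthogonal = TRUE,
    dec_lo = c(-0.075765714789273330, -0.029635527645998510,
               0.497618667632015450, 0.803738751805916100,
               0.297857795605277360, -0.099219543576847220,
               -0.012603967262037833, 0.032223100604042700),
    dec_hi = c(-0.032223100604042700, -0.012603967262037833,
               0.099219543576847220, 0.297857795605277360,
               -0.803738751805916100, 0.497618667632015450,
               0.029635527645998510, -0.075765714789273330)
  ),
  coif2 = list(
    orthogonal = TRUE,
    dec_lo = c(-0.000720549445520347, -0.001823208870911032,
               0.005611434819368834, 0.023680171946847770,
               -0.059434418646431090, -0.076488599078280760,
               0.417005184423239100, 0.812723635449413500,
               0.386110066822762900, -0.067372554723725600,
               -0.041464936786871780, 0.016387336463203640),
    dec_hi = c(-0.016387336463203640, -0.041464936786871780,
               0.067372554723725600, 0.386110066822762900,
               -0.812723635449413500, 0.417005184423239100,
               0.076488599078280760, -0.059434418646431090,
               -0.023680171946847770, 0.005611434819368834,
               0.001823208870911032, -0.000720549445520347)
  ),
  coif3 = list(
    orthogonal = TRUE,
    dec_lo = c(-3.459977319727278e-05, -7.098330250637900e-05,
               4.662169598204029e-04, 1.117518770830630e-03,
               -2.574517688136797e-03, -9.007976136730624e-03,
               1.588054486366945e-02, 3.455502757329774e-02,
               -8.230192710629983e-02, -7.179982161915484e-02,
               4.284834763773700e-01, 7.937772226260872e-01,
               4.051769024091182e-01, -6.112339000297255e-02,
               -6.577191128146936e-02, 2.345269614207717e-02,
               7.782596425672746e-03, -3.793512864380802e-03),
    dec_hi = c(3.793512864380802e-03, 7.782596425672746e-03,
               -2.345269614207717e-02, -6.577191128146936e-02,
               6.112339000297255e-02, 4.051769024091182e-01,
               -7.937772226260872e-01, 4.284834763773700e-01,
               7.179982161915484e-02, -8.230192710629983e-02,
               -3.455502757329774e-02, 1.588054486366945e-02,
               9.007976136730624e-03, -2.574517688136797e-03,
               -1.117518770830630e-03, 4.662169598204029e-04,
               7.098330250637900e-05, -3.459977319727278e-05)
  ),
  `bior3.5` = list(
    orthogonal = FALSE,
    dec_lo = c(-0.013810679320049757, 0.041432037960149270,
               0.052480581416189075, -0.267927178808965270,
               -0.071815532464258730, 0.966747552403483000,
               0.966747552403483000, -0.071815532464258730,
               -0.267927178808965270, 0.052480581416189075,
               0.041432037960149270, -0.013810679320049757),
    dec_hi = c(0, 0, 0, 0,
               -0.176776695296636900, 0.530330085889910600,
               -0.530330085889910600, 0.176776695296636900,
               0, 0, 0, 0)
  )
)

#' Analysis filters of a wavelet family
#'
#' Returns the standard decomposition (analysis) low-pass/high-pass filter
#' pair of a named wavelet family.
#'
#' @param family One of `"haar"`, `"db2"`, `"db4"`, `"sym4"`, `"coif2"`,
#'   `"coif3"`, `"bior3.5"`.
#' @return A list with elements `dec_lo`, `dec_hi` (numeric coefficient
#'   vectors), `family` and `orthogonal`.
#' @examples
#' f <- wavelet_filters("haar")
#' sum(f$dec_lo^2)  # 1 for orthogonal families
#' @export
wavelet_filters <- function(family) {
  if (!is.character(family) || length(family) != 1L ||
      !family %in% names(.wavelet_filter_table)) {
    stop("unsupported wavelet family: ", deparse(substitute(family)), " (",
         if (is.character(family)) family else "non-string",
         "); supported: ", paste(names(.wavelet_filter_table), collapse = ", "),
         call. = FALSE)
  }
  f <- .wavelet_filter_table[[family]]
  list(family = family, orthogonal = f$orthogonal,
       dec_lo = f$dec_lo, dec_hi = f$dec_hi)
}

#' Wavelet decomposition specification
#'
#' Bundles the wavelet family, the number of recursive decomposition levels,
#' the boundary extension rule and the sub-band energy convention used by the
#' attention mechanism.
#'
#' @param family Wavelet family name (see [wavelet_filters()]).
#' @param levels Number of decomposition levels `L >= 1` (typically 1 or 2).
#' @param boundary Signal extension at image borders: `"periodic"` (circular,
#'   the default; preserves energy for orthogonal families on even sizes) or
#'   `"zero"` (zero padding).
#' @param energy One of `"raw-mean"` (the printed mean of coefficients,
#'   default), `"abs-mean"` or `"squared-mean"`.
#' @return An object of class `wavelet_spec`.
#' @examples
#' wavelet_spec("sym4", levels = 2)
#' @export
wavelet_spec <- function(family = "haar", levels = 1L,
                         boundary = c("periodic", "zero"),
                         energy = c("raw-mean", "abs-mean", "squared-mean")) {
  filt <- wavelet_filters(family)  # validates the family
  boundary <- match.arg(boundary)
  energy <- match.arg(energy)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 1L)
    stop("levels must be a positive integer", call. = FALSE)
  structure(list(family = family, levels = levels, boundary = boundary,
                 energy = energy, filters = filt),
            class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat("wavelet_spec:", x$family, "| levels:", x$levels,
      "| boundary:", x$boundary, "| energy:", x$energy, "\n")
  invisible(x)
}
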