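#' Stain matrix for optical-density colour deconvolution
#'
#' Builds a 3x3 stain matrix whose rows are unit-norm optical-density (OD)
#' direction vectors over (R, G, B) for hematoxylin, DAB and a residual
#' channel. In OD space stains mix additively (Beer-Lambert), so a pixel's
#' OD vector is `concentrations %*% M`; deconvolution inverts this map.
#'
#' @param hematoxylin numeric(3), OD direction of the hematoxylin stain.
#' @param dab numeric(3), OD direction of the DAB chromogen.
#' @param residual numeric(3) or `NULL`; when `NULL` the normalised cross
#'   product of the two stain vectors is used, giving an orthogonal
#'   complement channel that absorbs colour not explained by either stain.
#' @return A 3x3 numeric matrix of class `stain_matrix` with rows
#'   `hematoxylin`, `dab`, `residual`, each of unit Euclidean norm.
#' @examples
#' M <- stain_matrix()
#' rowSums(M^2)  # all 1
#' @export
stain_matrix <- function(hematoxylin = c(0.650, 0.704, 0.286),
                         dab = c(0.269, 0.568, 0.778),
                         residual = NULL) {
  stopifnot(length(hematoxylin) == 3, length(dab) == 3)
  if (any(hematoxylin < 0) || any(dab < 0)) {
    stop("stain OD vectors must have non-negative components")
  }
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  if (is.null(residual)) {
    residual <- c(
      h[2] * d[3] - h[3] * d[2],
      h[3] * d[1] - h[1] * d[3],
      h[1] * d[2] - h[2] * d[1]
    )
  }
  nr <- sqrt(sum(residual^2))
  if (nr < 1e-12) stop("residual vector is degenerate; stain vectors may be collinear")
  r <- residual / nr
  M <- rbind(hematoxylin = h, dab = d, residual = r)
  colnames(M) <- c("R", "G", "B")
  if (abs(det(M)) < 1e-8 || kappa(M) > 1e8) {
    stop("stain matrix is singular or ill-conditioned")
  }
  class(M) <- c("stain_matrix", class(M))
  M
}

#' Default H-DAB stain basis
#'
#' The widely used hematoxylin/DAB OD basis (hematoxylin approximately
#' (0.650, 0.704, 0.286), DAB (0.269, 0.568, 0.778)) with an orthogonal
#' residual channel.
#'
#' @return A `stain_matrix`.
#' @export
hdab_stain_matrix <- function() stain_matrix()
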