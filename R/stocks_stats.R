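# Areal pigment stocks and the summary statistics used with them.

#' Integrate discrete water-column concentrations to an areal stock
#'
#' Replicate values at the same depth are averaged first; the mean profile
#' is integrated by trapezoid between sampled depths, with constant
#' extension from the shallowest sample up to `z_surface` (e.g. the ice
#' bottom) and from the deepest sample down to `z_bottom`. ug/L integrated
#' over metres gives mg m-2, so a two-depth pigment design maps directly to
#' an areal phytoplankton stock.
#'
#' @param depth sampling depths, m (replicates allowed).
#' @param concentration ug/L at each depth.
#' @param z_surface,z_bottom integration bounds, m (`z_bottom > z_surface`).
#' @return areal stock in mg m-2.
#' @export
#' @examples
#' # two depths at 0.4 ug/L over a 1.5-9.0 m column -> 3.0 mg m-2
#' integrate_water_column(c(2.2, 7.5), c(0.4, 0.4), 1.5, 9.0)
integrate_water_column <- function(depth, concentration, z_surface,
                                   z_bottom) {
  stop_if_not(length(depth) == length(concentration) && length(depth) >= 1,
              "depth and concentration must be equal-length, non-empty")
  stop_if_not(all(is.finite(depth)) && all(is.finite(concentration)),
              "inputs must be finite")
  stop_if_not(z_bottom > z_surface, "z_bottom must exceed z_surface")
  mean_by_depth <- tapply(concentration, depth, mean)
  z <- as.numeric(names(mean_by_depth))
  c_ <- as.numeric(mean_by_depth)
  o <- order(z); z <- z[o]; c_ <- c_[o]
  z_ext <- c(z_surface, z, z_bottom)
  c_ext <- c(c_[1], c_, c_[length(c_)])
  keep <- !duplicated(z_ext)
  trapz_(z_ext[keep], c_ext[keep])
}

#' Ratio of benthic to planktonic areal pigment stock
#'
#' @param benthic benthic mat stock, mg m-2.
#' @param pelagic water-column (phytoplankton) stock, mg m-2, > 0.
#' @return dimensionless ratio.
#' @export
benthic_pelagic_ratio <- function(benthic, pelagic) {
  stop_if_not(all(pelagic > 0), "pelagic stock must be > 0")
  benthic / pelagic
}

#' Pearson correlation with degrees of freedom and two-sided p-value
#'
#' Standard product-moment correlation via [stats::cor.test()], reported
#' with df = n - 2. Degenerate inputs (zero variance in either variable)
#' return NA with `defined = FALSE` rather than an error.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return data.frame with `r`, `df`, `p`, `defined`.
#' @export
pearson_r <- function(x, y) {
  stop_if_not(length(x) == length(y) && length(x) >= 3,
              "need equal-length vectors with n >= 3")
  stop_if_not(all(is.finite(x)) && all(is.finite(y)),
              "inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: a variable has zero variance")
    return(data.frame(r = NA_real_, df = length(x) - 2L, p = NA_real_,
                      defined = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(r = unname(ct$estimate), df = unname(ct$parameter),
             p = ct$p.value, defined = TRUE)
}

#' Principal component analysis of standardized indicator tables
#'
#' Column-standardizes the feature table (PCA on the correlation matrix,
#' matching the convention for mixed-unit optical indicator sets) and
#' decomposes it by singular values. Compositional columns (e.g. PARAFAC
#' component percentages) can be alr-transformed first via `alr_spec`.
#'
#' @param features numeric matrix or data.frame, samples x features.
#' @param standardize scale columns to unit variance (default TRUE;
#'   centring is always applied).
#' @param alr_spec optional list with `columns` (names or indices of the
#'   compositional block) and `denominator` (component within that block);
#'   the block is replaced by its [alr_transform()] before the PCA.
#' @return list with `scores` (samples x PC), `loadings` (features x PC),
#'   `variance_explained` (fractions summing to 1), `sdev`.
#' @export
pca_summary <- function(features, standardize = TRUE, alr_spec = NULL) {
  X <- as.data.frame(features)
  if (!is.null(alr_spec)) {
    cols <- alr_spec$columns
    block <- as.matrix(X[, cols, drop = FALSE])
    tr <- alr_transform(block, alr_spec$denominator %||% 1)
    X <- X[, setdiff(seq_len(ncol(X)), .col_idx(X, cols)), drop = FALSE]
    X <- cbind(X, as.data.frame(tr))
  }
  X <- as.matrix(X)
  stop_if_not(is.numeric(X), "features must be numeric")
  stop_if_not(nrow(X) >= 2, "need at least 2 samples")
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    stop_if_not(all(sds > 0), "constant feature column cannot be standardized")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation,
       variance_explained = varfrac, sdev = pc$sdev)
}

.col_idx <- function(df, cols) {
  if (is.character(cols)) match(cols, colnames(df)) else cols
}
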