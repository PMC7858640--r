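# Trilinear (PARAFAC) decomposition of an EEM stack.
#
# The model is X[i, e, f] ~ sum_k A[i,k] * B[e,k] * C[f,k] with all factors
# constrained non-negative, fitted by alternating least squares in which
# each row subproblem is a small non-negative least-squares solve restricted
# to the observed (non-masked) cells. Scatter-excised cells are treated as
# missing, never imputed. After the fit, emission and excitation loadings
# are peak-normalized to 1 ("Fmax scaling") so score A[i,k] is the modelled
# maximum fluorescence [Ck] of component k in sample i, in Raman units.

# stack a list of eems into an array [sample, em, ex]
eem_stack <- function(eems) {
  stop_if_not(length(eems) >= 1 && all(vapply(eems, inherits, TRUE, "eem")),
              "eems must be a list of eem objects")
  ex <- eems[[1]]$ex; em <- eems[[1]]$em
  for (e in eems)
    stop_if_not(identical(e$ex, ex) && identical(e$em, em),
                "all EEMs must share the same grids")
  X <- array(NA_real_, c(length(eems), length(em), length(ex)))
  for (i in seq_along(eems)) X[i, , ] <- eems[[i]]$intensity
  list(X = X, em = em, ex = ex)
}

# khatri-rao product (columnwise kronecker), rows of `slow` vary slowest
.kr <- function(slow, fast) {
  K <- ncol(slow)
  out <- matrix(0, nrow(slow) * nrow(fast), K)
  for (k in seq_len(K)) out[, k] <- kronecker(slow[, k], fast[, k])
  out
}

# non-negative LS for one row restricted to observed entries; fast path is
# the unconstrained normal-equation solution (valid when it lands in the
# non-negative orthant), falling back to Lawson-Hanson NNLS otherwise
.nnls_row <- function(Z, y, prev) {
  obs <- is.finite(y)
  if (sum(obs) < ncol(Z)) return(prev)   # under-determined row: keep
  Zo <- Z[obs, , drop = FALSE]; yo <- y[obs]
  G <- crossprod(Zo)
  x <- tryCatch(solve(G, crossprod(Zo, yo)), error = function(e) NULL)
  if (!is.null(x) && all(x > -1e-12)) return(pmax(as.numeric(x), 0))
  as.numeric(pracma::lsqnonneg(Zo, yo)$x)
}

.parafac_sse <- function(X, A, B, C) {
  fitv <- array(0, dim(X))
  for (k in seq_len(ncol(A)))
    fitv <- fitv + outer(A[, k], outer(B[, k], C[, k]))
  sum((X - fitv)^2, na.rm = TRUE)
}

#' Fit a non-negative PARAFAC model to a set of EEMs
#'
#' Alternating least squares on the sample x emission x excitation tensor
#' with non-negativity on all three factor matrices and masked cells
#' handled as missing. The fit is restarted from several random
#' initializations and the best (lowest residual) solution kept; with a
#' fixed `seed` the result is deterministic. The residual sum of squares is
#' checked to be non-increasing across iterations.
#'
#' @param eems list of fully corrected [eem()] objects on a common grid, or
#'   a numeric array `[sample, em, ex]` (NA = missing).
#' @param K number of components (>= 1). Fewer than K + 2 samples triggers
#'   a warning.
#' @param restarts random restarts (default 10).
#' @param tol convergence tolerance on the relative change of the residual
#'   sum of squares (default 1e-8).
#' @param max_iter maximum ALS iterations per restart (default 2500).
#' @param seed optional integer seed making the restarts reproducible.
#' @return object of class `parafac` with elements `K`, `scores`
#'   (samples x K, Fmax-scaled, i.e. `[Ck]`), `em_loadings`, `ex_loadings`
#'   (peak-normalized columns), `fit` (explained variance on observed
#'   cells), `sse`, `iterations`, `converged`, `objective` (per-iteration
#'   trace of the best restart).
#' @export
parafac_fit <- function(eems, K, restarts = 10, tol = 1e-8,
                        max_iter = 2500, seed = NULL) {
  if (is.list(eems)) {
    st <- eem_stack(eems); X <- st$X
  } else {
    X <- eems
    stop_if_not(is.array(X) && length(dim(X)) == 3,
                "eems must be a list of eem objects or a 3-way array")
  }
  stop_if_not(K >= 1 && K == round(K), "K must be a positive integer")
  n <- dim(X)[1]; nem <- dim(X)[2]; nex <- dim(X)[3]
  if (n < K + 2)
    warning(sprintf("only %d samples for K = %d components (< K + 2)", n, K))
  stop_if_not(any(is.finite(X)), "tensor has no observed cells")
  SST <- sum(X^2, na.rm = TRUE)
  scale0 <- sqrt(max(X, na.rm = TRUE) %||% 1)

  run_once <- function() {
    A <- matrix(stats::runif(n * K), n, K) * scale0
    B <- matrix(stats::runif(nem * K), nem, K)
    C <- matrix(stats::runif(nex * K), nex, K)
    sse_prev <- Inf
    trace <- numeric(0)
    converged <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      ZA <- .kr(C, B)                       # rows: (ex slow, em fast)
      for (i in seq_len(n))
        A[i, ] <- .nnls_row(ZA, as.vector(X[i, , ]), A[i, ])
      ZB <- .kr(C, A)                       # rows: (ex slow, sample fast)
      for (e in seq_len(nem))
        B[e, ] <- .nnls_row(ZB, as.vector(X[, e, ]), B[e, ])
      ZC <- .kr(B, A)                       # rows: (em slow, sample fast)
      for (f in seq_len(nex))
        C[f, ] <- .nnls_row(ZC, as.vector(X[, , f]), C[f, ])
      sse <- .parafac_sse(X, A, B, C)
      # ALS with exact block solves cannot increase the objective; tiny
      # relative and absolute slacks absorb floating-point noise near
      # perfect fits
      if (sse > sse_prev * (1 + 1e-9) + 1e-10 * SST)
        stop("internal error: ALS objective increased", call. = FALSE)
      trace <- c(trace, sse)
      if (is.finite(sse_prev) &&
          (sse_prev - sse) <= tol * max(sse_prev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
      sse_prev <- sse
    }
    list(A = A, B = B, C = C, sse = trace[length(trace)],
         iterations = it, converged = converged, trace = trace)
  }

  runner <- function() {
    best <- NULL
    for (r in seq_len(restarts)) {
      res <- run_once()
      if (is.null(best) || res$sse < best$sse) best <- res
    }
    best
  }
  best <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())

  A <- best$A; B <- best$B; C <- best$C
  # Fmax scaling: loadings peak at 1, magnitude absorbed into scores
  for (k in seq_len(K)) {
    bmax <- max(B[, k]); cmax <- max(C[, k])
    if (bmax > 0) B[, k] <- B[, k] / bmax
    if (cmax > 0) C[, k] <- C[, k] / cmax
    A[, k] <- A[, k] * bmax * cmax
  }
  ord <- order(colSums(A), decreasing = TRUE)   # deterministic ordering
  structure(list(K = K,
                 scores = A[, ord, drop = FALSE],
                 em_loadings = B[, ord, drop = FALSE],
                 ex_loadings = C[, ord, drop = FALSE],
                 fit = 1 - best$sse / SST,
                 sse = best$sse,
                 iterations = best$iterations,
                 converged = best$converged,
                 objective = best$trace),
            class = "parafac")
}

#' @export
print.parafac <- function(x, ...) {
  cat("parafac model: K =", x$K, "; explained variance =",
      format(x$fit, digits = 6), ";",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations\n")
  invisible(x)
}

#' Per-sample percentage contribution of each PARAFAC component
#'
#' For each sample, total fluorescence F_T is the sum of the component
#' maximum fluorescences `[Ck]` (the Fmax-scaled scores) and
#' %Ck = 100 * \[Ck\] / F_T. Samples with F_T = 0 are returned as NA with a
#' warning.
#'
#' @param model a [parafac_fit()] result, or a non-negative score matrix.
#' @return matrix samples x K of percentages; rows sum to 100.
#' @export
component_contributions <- function(model) {
  scores <- if (inherits(model, "parafac")) model$scores else as.matrix(model)
  stop_if_not(all(scores >= 0, na.rm = TRUE), "scores must be non-negative")
  FT <- rowSums(scores)
  if (any(FT == 0)) warning("samples with zero total fluorescence: NA")
  pct <- 100 * scores / ifelse(FT > 0, FT, NA_real_)
  colnames(pct) <- paste0("C", seq_len(ncol(scores)))
  pct
}

#' Additive log-ratio transform of compositional percentages
#'
#' alr_k = ln(p_k / p_d) for every component k other than the denominator
#' d, mapping a K-part composition to K - 1 unconstrained coordinates.
#' The transform is invariant to expressing the composition as percentages
#' or fractions. Zeros are replaced by half the smallest positive value in
#' the matrix (with a warning) before taking logs.
#'
#' @param pct matrix samples x K of positive percentages (or fractions).
#' @param denominator index (or column name) of the denominator component,
#'   default the first.
#' @return matrix samples x (K - 1) of log-ratios, columns named
#'   `alr_<comp>`.
#' @export
alr_transform <- function(pct, denominator = 1) {
  pct <- as.matrix(pct)
  if (is.character(denominator))
    denominator <- match(denominator, colnames(pct))
  stop_if_not(is.finite(denominator) && denominator >= 1 &&
                denominator <= ncol(pct), "bad denominator component")
  stop_if_not(all(pct >= 0, na.rm = TRUE), "negative composition entries")
  if (any(pct == 0, na.rm = TRUE)) {
    repl <- min(pct[pct > 0], na.rm = TRUE) / 2
    warning(sprintf("zero entries replaced by %g before alr", repl))
    pct[pct == 0] <- repl
  }
  if (any(!is.finite(pct[, denominator])) || any(pct[, denominator] <= 0))
    stop("denominator component has non-positive entries", call. = FALSE)
  out <- log(pct[, -denominator, drop = FALSE] / pct[, denominator])
  cn <- colnames(pct) %||% paste0("C", seq_len(ncol(pct)))
  colnames(out) <- paste0("alr_", cn[-denominator])
  out
}

#' Tucker congruence between two loading vectors
#'
#' phi(a, b) = sum(a b) / sqrt(sum(a^2) sum(b^2)); 1 means identical shape.
#'
#' @param a,b numeric vectors of equal length.
#' @return congruence coefficient in \[-1, 1\].
#' @export
tucker_congruence <- function(a, b) {
  stop_if_not(length(a) == length(b), "lengths differ")
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match fitted components to reference loadings by congruence
#'
#' Finds the component permutation maximizing the mean Tucker congruence of
#' emission and excitation loadings against a reference set, and reports
#' the per-component congruences. Used to score parameter recovery against
#' generator ground truth.
#'
#' @param model a [parafac_fit()] result.
#' @param em_ref,ex_ref reference loading matrices (em x K, ex x K).
#' @return list with `perm` (reference column for each model component),
#'   `em_congruence`, `ex_congruence` (per matched pair).
#' @export
match_components <- function(model, em_ref, ex_ref) {
  K <- model$K
  stop_if_not(ncol(em_ref) == K && ncol(ex_ref) == K,
              "reference must have K columns")
  perms <- pracma::perms(seq_len(K))
  best <- NULL; best_val <- -Inf
  for (p in seq_len(nrow(perms))) {
    pm <- perms[p, ]
    cem <- vapply(seq_len(K), function(k)
      tucker_congruence(model$em_loadings[, k], em_ref[, pm[k]]), 0)
    cex <- vapply(seq_len(K), function(k)
      tucker_congruence(model$ex_loadings[, k], ex_ref[, pm[k]]), 0)
    val <- mean(c(cem, cex))
    if (val > best_val) {
      best_val <- val
      best <- list(perm = pm, em_congruence = cem, ex_congruence = cex)
    }
  }
  best
}
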