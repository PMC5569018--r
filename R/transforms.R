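#' Fit the phenotype orthogonalization transforms
#'
#' Standardizes the discovery traits to z-scores and derives the two
#' uncorrelated phenotype sets used throughout the pipeline:
#'
#' * principal-component scores `u = T' g`, where `T` holds the
#'   eigenvectors of the correlation matrix of the standardized traits, so
#'   PC scores are uncorrelated with variances equal to the eigenvalues;
#' * Cholesky-transformed traits `c = L^{-1} g`, where `L L' = COV` is the
#'   lower Cholesky factor of the same correlation matrix, so CT scores are
#'   uncorrelated with unit variance and the j-th CT is the j-th trait
#'   corrected for the preceding j-1 traits. The first CT equals the first
#'   standardized trait.
#'
#' Eigenvector signs are fixed by forcing the largest-magnitude loading of
#' each component positive. All constants (means, SDs, `T`, `L`) come from
#' the discovery cohort and are reapplied verbatim to validation data.
#'
#' @param discovery Discovery trait panel (tibble; trait columns as in
#'   [panel_traits()]).
#' @param traits Optional subset/order of trait columns; defaults to panel
#'   column order.
#' @return An object of class `transform_set` with elements `means`, `sds`,
#'   `rotation` (eigenvector matrix `T`), `eigenvalues`, `L`, `cov`
#'   (correlation matrix of standardized traits), `traits`, `k`.
#' @export
fit_transforms <- function(discovery, traits = NULL) {
  if (is.null(traits)) traits <- panel_traits(discovery)
  if (length(traits) < 2) abort("at least 2 traits are required to fit transforms.")
  X <- panel_matrix(discovery, traits)
  if (anyNA(X)) abort("discovery panel has missing trait values.")
  means <- colMeans(X)
  sds <- apply(X, 2, sd)
  if (any(sds <= 0)) {
    abort(paste0("constant trait(s): ", paste(traits[sds <= 0], collapse = ", ")))
  }
  Z <- sweep(sweep(X, 2, means), 2, sds, "/")
  COV <- cov(Z)
  ev <- eigen(COV, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    cc <- COV; diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    abort(sprintf("trait covariance is singular; near-collinear pair: %s, %s",
                  traits[worst[1]], traits[worst[2]]))
  }
  if (any(diff(ev$values) > -1e-10 & abs(diff(ev$values)) < 1e-10)) {
    inform("repeated eigenvalues detected; component order follows trait-order-stable sorting.")
  }
  Tm <- ev$vectors
  for (j in seq_len(ncol(Tm))) {
    if (Tm[which.max(abs(Tm[, j])), j] < 0) Tm[, j] <- -Tm[, j]
  }
  dimnames(Tm) <- list(traits, sprintf("PC%02d", seq_along(traits)))
  L <- t(chol(COV))
  dimnames(L) <- list(traits, traits)
  structure(
    list(means = means, sds = sds, rotation = Tm, eigenvalues = ev$values,
         L = L, cov = COV, traits = traits, k = length(traits)),
    class = "transform_set"
  )
}

#' @export
print.transform_set <- function(x, ...) {
  cat(sprintf("<transform_set> k = %d traits; PC1 explains %.1f%% of total variance\n",
              x$k, 100 * x$eigenvalues[1] / x$k))
  invisible(x)
}

#' @describeIn fit_transforms One row per principal component: eigenvalue
#'   and share of total (standardized) variance explained.
#' @param x,object A `transform_set`.
#' @param ... Unused.
#' @export
tidy.transform_set <- function(x, ...) {
  tibble::tibble(
    component = colnames(x$rotation),
    eigenvalue = x$eigenvalues,
    variance_share = x$eigenvalues / x$k
  )
}

#' @describeIn fit_transforms One-row summary of the fitted transforms.
#' @export
glance.transform_set <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    eigenvalue_sum = sum(x$eigenvalues),
    condition_number = x$eigenvalues[1] / x$eigenvalues[x$k]
  )
}

#' Apply fitted transforms to a trait panel
#'
#' Standardizes the panel with the discovery means/SDs and maps it into the
#' three phenotype sets. Applied to the discovery panel itself this
#' reproduces the scores implied at fit time exactly; applied to a
#' validation panel it is a pure linear map (no refitting), so validation
#' PC scores need not have diagonal covariance.
#'
#' @param panel A trait panel whose trait columns match
#'   `transforms$traits` in the same order.
#' @param transforms A fitted [fit_transforms()] object.
#' @return Named list of tibbles `RT`, `PC`, `CT`; each keeps the panel's
#'   metadata columns. RT columns keep trait names; PC/CT columns are
#'   `PC01..` / `CT01..`.
#' @export
apply_transforms <- function(panel, transforms) {
  stopifnot(inherits(transforms, "transform_set"))
  traits <- transforms$traits
  have <- panel_traits(panel)
  if (!all(traits %in% have)) {
    abort(paste0("panel is missing trait(s): ",
                 paste(setdiff(traits, have), collapse = ", "),
                 "; refit transforms on the shared subset (see subset_refit)."))
  }
  if (!identical(intersect(have, traits), traits)) {
    abort("panel trait order does not match the fitted trait order.")
  }
  X <- panel_matrix(panel, traits)
  Z <- sweep(sweep(X, 2, transforms$means), 2, transforms$sds, "/")
  U <- Z %*% transforms$rotation
  C <- t(forwardsolve(transforms$L, t(Z)))
  colnames(Z) <- traits
  colnames(U) <- sprintf("PC%02d", seq_along(traits))
  colnames(C) <- sprintf("CT%02d", seq_along(traits))
  meta <- panel[, intersect(c("animal_id", "breed", "cohort"), names(panel)), drop = FALSE]
  list(
    RT = dplyr::bind_cols(meta, tibble::as_tibble(Z)),
    PC = dplyr::bind_cols(meta, tibble::as_tibble(U)),
    CT = dplyr::bind_cols(meta, tibble::as_tibble(C))
  )
}

#' Refit transforms on a subset of traits
#'
#' Used when a cohort lacks some traits (e.g. a validation population
#' recorded on 24 of 25 traits): transforms are refitted on the kept
#' traits, preserving their relative order, and every downstream stage
#' reruns with the reduced k.
#'
#' @param discovery Discovery trait panel.
#' @param keep_traits Traits to keep (subset of the panel's traits,
#'   relative order preserved).
#' @return A `transform_set` with `k = length(keep_traits)`.
#' @export
subset_refit <- function(discovery, keep_traits) {
  have <- panel_traits(discovery)
  if (!all(keep_traits %in% have)) {
    abort(paste0("unknown trait(s): ", paste(setdiff(keep_traits, have), collapse = ", ")))
  }
  if (length(keep_traits) < 2) abort("fewer than 2 traits kept.")
  keep <- have[have %in% keep_traits]
  fit_transforms(discovery, traits = keep)
}

#' Serialize or restore a transform set
#'
#' Writes the discovery means/SDs, eigenvector matrix, eigenvalues,
#' Cholesky factor and trait order to a JSON bundle so a validation run in
#' a separate invocation applies exactly the discovery-fitted transforms.
#'
#' @param transforms A `transform_set`.
#' @param path JSON file path.
#' @return `write_transforms()` returns `path` invisibly;
#'   `read_transforms()` the restored object.
#' @export
write_transforms <- function(transforms, path) {
  stopifnot(inherits(transforms, "transform_set"))
  x <- list(
    traits = transforms$traits, means = unname(transforms$means),
    sds = unname(transforms$sds), rotation = unname(transforms$rotation),
    eigenvalues = transforms$eigenvalues, L = unname(transforms$L),
    cov = unname(transforms$cov)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  traits <- x$traits
  Tm <- as.matrix(x$rotation)
  dimnames(Tm) <- list(traits, sprintf("PC%02d", seq_along(traits)))
  L <- as.matrix(x$L)
  dimnames(L) <- list(traits, traits)
  structure(
    list(means = setNames(x$means, traits), sds = setNames(x$sds, traits),
         rotation = Tm, eigenvalues = x$eigenvalues, L = L,
         cov = as.matrix(x$cov), traits = traits, k = length(traits)),
    class = "transform_set"
  )
}
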