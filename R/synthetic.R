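# Synthetic benchmark data: smooth multi-blob phantoms and graded, seeded
# perturbations (rigid misalignment + multiplicative bias field + additive
# noise) with known ground-truth severity. Stands in for external
# registration outputs so the whole evaluate -> store -> mine pipeline can
# be exercised against a planted quality ordering.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a smooth multi-blob phantom image
#'
#' A sum of `n_blobs` anisotropic Gaussian blobs with random centers, widths
#' and amplitudes on a dark (zero) background, quantized to `levels` gray
#' levels the way acquired images are: a scalar image with a non-trivial
#' intensity histogram whose distinct values align with equal-width bins
#' whenever `bins >= levels`, so a perfect candidate is an exact fixed point
#' of the binned statistical metrics. Deterministic given `seed`.
#'
#' @param shape per-axis voxel counts (2-D or 3-D), each axis >= 8.
#' @param n_blobs number of blobs (default 6).
#' @param seed RNG seed (the caller's RNG state is left untouched).
#' @param levels gray levels for intensity quantization (default 64;
#'   `Inf` keeps the continuous blob sum).
#' @return an `mm_image` with intensities in roughly [0, ~2].
#' @export
make_phantom <- function(shape, n_blobs = 6, seed = 1, levels = 64L) {
  shape <- as.integer(shape)
  if (length(shape) < 2L || length(shape) > 3L || any(shape < 8L))
    stop("phantom shape must be 2-D or 3-D with every axis >= 8")
  if (n_blobs < 1L) stop("n_blobs must be >= 1")
  with_seed(seed, {
    arr <- array(0, dim = shape)
    axes <- lapply(shape, function(n) seq_len(n))
    for (b in seq_len(n_blobs)) {
      center <- vapply(shape, function(n) stats::runif(1, 0.2 * n, 0.8 * n),
                       numeric(1))
      width <- vapply(shape, function(n) stats::runif(1, 0.08 * n, 0.2 * n),
                      numeric(1))
      amp <- stats::runif(1, 0.5, 1)
      terms <- lapply(seq_along(shape), function(a)
        exp(-(axes[[a]] - center[a])^2 / (2 * width[a]^2)))
      blob <- Reduce(function(x, y) outer(x, y), terms)
      arr <- arr + amp * blob
    }
    if (is.finite(levels)) {
      top <- max(arr)
      if (top > 0) arr <- round(arr / top * (levels - 1)) / (levels - 1) * top
    }
    mm_image(arr)
  })
}

#' Specify a ground-truth perturbation
#'
#' `severity` is the master knob: the applied translation, rotation, bias
#' amplitude and noise standard deviation are all the stated maxima scaled
#' by `severity`, so severity 0 reproduces the reference voxelwise and
#' severity 1 applies the full degradation.
#'
#' @param severity nonnegative real; 0 = perfect candidate.
#' @param translation per-axis translation at severity 1, in voxels
#'   (recycled to the image dimensionality).
#' @param rotation in-plane rotation at severity 1, degrees (about the
#'   center of the first two axes).
#' @param intensity_bias amplitude of the multiplicative low-frequency bias
#'   field at severity 1 (0.2 means +/-20 percent shading).
#' @param noise_sd additive Gaussian noise standard deviation at severity 1,
#'   in intensity units.
#' @param seed RNG seed for the noise and bias-field phase.
#' @return a list of class `mm_perturbation_spec`.
#' @export
perturbation_spec <- function(severity, translation = 1.5, rotation = 8,
                              intensity_bias = 0.2, noise_sd = 0.05,
                              seed = 1) {
  if (severity < 0) stop("severity must be >= 0")
  structure(list(severity = severity, translation = translation,
                 rotation = rotation, intensity_bias = intensity_bias,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "mm_perturbation_spec")
}

# linear (bi/tri) interpolation of arr at fractional voxel coordinates;
# coords outside the grid read as `background` (edge padding with background).
interp_linear <- function(arr, coords, background = 0) {
  d <- length(dim(arr))
  n <- nrow(coords)
  lo <- lapply(seq_len(d), function(a) floor(coords[, a]))
  fr <- lapply(seq_len(d), function(a) coords[, a] - lo[[a]])
  out <- numeric(n)
  corners <- as.matrix(expand.grid(rep(list(0:1), d)))
  for (k in seq_len(nrow(corners))) {
    idx <- matrix(0L, n, d)
    w <- rep(1, n)
    for (a in seq_len(d)) {
      idx[, a] <- as.integer(lo[[a]] + corners[k, a])
      w <- w * if (corners[k, a] == 1) fr[[a]] else 1 - fr[[a]]
    }
    inside <- rep(TRUE, n)
    for (a in seq_len(d))
      inside <- inside & idx[, a] >= 1L & idx[, a] <= dim(arr)[a]
    vals <- rep(background, n)
    if (any(inside)) vals[inside] <- arr[idx[inside, , drop = FALSE]]
    out <- out + w * vals
  }
  out
}

#' Apply a ground-truth perturbation to an image
#'
#' Rigid misalignment (in-plane rotation about the image center plus
#' translation, linear interpolation, background edge padding), then a
#' multiplicative low-frequency sinusoidal bias field, then additive
#' Gaussian noise — every component scaled by `spec$severity` and seeded, so
#' the result is deterministic and severity 0 is the identity.
#'
#' @param img an `mm_image`.
#' @param spec a [perturbation_spec()].
#' @return the perturbed `mm_image` (same shape).
#' @export
perturb <- function(img, spec) {
  stopifnot(inherits(spec, "mm_perturbation_spec"))
  img <- as_mm_image(img)
  sev <- spec$severity
  if (sev == 0) return(img)
  shape <- img$shape
  d <- length(shape)
  background <- min(img$voxels)
  trans <- rep_len(spec$translation, d) * sev
  theta <- spec$rotation * sev * pi / 180
  # inverse mapping: rotate output coords back about the center of axes 1-2,
  # then undo the translation
  grids <- do.call(expand.grid, lapply(shape, seq_len))
  coords <- as.matrix(grids)
  center <- (shape + 1) / 2
  x1 <- coords[, 1] - center[1] - trans[1]
  x2 <- coords[, 2] - center[2] - trans[2]
  src <- coords
  src[, 1] <- cos(theta) * x1 + sin(theta) * x2 + center[1]
  src[, 2] <- -sin(theta) * x1 + cos(theta) * x2 + center[2]
  if (d == 3) src[, 3] <- coords[, 3] - trans[3]
  vox <- interp_linear(img$voxels, src, background = background)
  arr <- array(vox, dim = shape)
  with_seed(spec$seed, {
    # low-frequency multiplicative shading: one sinusoidal period per axis
    # with a random phase
    phases <- stats::runif(d, 0, 2 * pi)
    bias <- array(1, dim = shape)
    for (a in seq_len(d)) {
      wave <- sin(2 * pi * seq_len(shape[a]) / shape[a] + phases[a])
      shape_a <- rep(1L, d); shape_a[a] <- shape[a]
      bias <- bias * (1 + sev * spec$intensity_bias *
                        array(rep(wave, each = prod(shape[seq_len(a - 1)])),
                              dim = shape) / d)
    }
    arr <- arr * bias
    if (spec$noise_sd > 0)
      arr <- arr + stats::rnorm(length(arr), sd = sev * spec$noise_sd)
    mm_image(arr)
  })
}

#' Generate a candidate set with planted quality ordering
#'
#' One reference phantom and `n` perturbed candidates whose ground-truth
#' severities follow `severity_grid` (recycled to length `n`). Severity 0
#' candidates are voxelwise copies of the reference. Deterministic given
#' `seed`.
#'
#' @param reference an `mm_image`, or `NULL` to generate a phantom of
#'   `shape`.
#' @param n number of candidates (default `length(severity_grid)`).
#' @param severity_grid ground-truth severities (default 50 levels, 0 to 1).
#' @param seed master seed; per-candidate noise seeds are derived from it.
#' @param shape phantom shape when `reference` is NULL
#'   (default `c(16, 16, 8)`).
#' @param ... further arguments to [perturbation_spec()] (translation,
#'   rotation, intensity_bias, noise_sd).
#' @return list of class `mm_candidate_set`: `reference`, `candidates`
#'   (named list of `mm_image`s), `specs`, `severity` (numeric),
#'   `run_ids`.
#' @export
make_candidate_set <- function(reference = NULL, n = NULL,
                               severity_grid = seq(0, 1, length.out = 50),
                               seed = 1, shape = c(16, 16, 8), ...) {
  if (length(severity_grid) == 0L) stop("severity_grid must be non-empty")
  if (is.null(n)) n <- length(severity_grid)
  sev <- rep_len(severity_grid, n)
  if (is.null(reference)) reference <- make_phantom(shape, seed = seed)
  reference <- as_mm_image(reference)
  run_ids <- sprintf("synthetic/%04d", seq_len(n))
  specs <- lapply(seq_len(n), function(k)
    perturbation_spec(severity = sev[k],
                      seed = (as.integer(seed) * 1009L + k * 7919L) %% 2147483647L,
                      ...))
  candidates <- lapply(specs, function(sp) perturb(reference, sp))
  names(candidates) <- run_ids
  structure(list(reference = reference, candidates = candidates,
                 specs = specs, severity = sev, run_ids = run_ids,
                 seed = as.integer(seed)),
            class = "mm_candidate_set")
}

#' Write a candidate set to disk as a campaign
#'
#' NIfTI images plus a JSON manifest recording each candidate's run id,
#' perturbation spec and ground-truth severity; readable back by the
#' campaign/store machinery.
#'
#' @param cs an `mm_candidate_set`.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_candidate_set <- function(cs, dir) {
  stopifnot(inherits(cs, "mm_candidate_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref_path <- file.path(dir, "reference.nii.gz")
  write_image(cs$reference, ref_path)
  entries <- lapply(seq_along(cs$candidates), function(k) {
    p <- file.path(dir, sprintf("candidate_%04d.nii.gz", k))
    write_image(cs$candidates[[k]], p)
    list(run_id = cs$run_ids[k], image_path = basename(p),
         ground_truth_severity = cs$severity[k],
         spec = unclass(cs$specs[[k]]))
  })
  manifest <- list(reference = basename(ref_path), seed = cs$seed,
                   candidates = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a candidate set written by [write_candidate_set()]
#'
#' @param dir directory holding `manifest.json` and the images.
#' @return an `mm_candidate_set` (specs restored as plain lists).
#' @export
read_candidate_set <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = FALSE)
  reference <- read_image(file.path(dir, manifest$reference))
  candidates <- lapply(manifest$candidates, function(e)
    read_image(file.path(dir, e$image_path)))
  names(candidates) <- vapply(manifest$candidates, `[[`, character(1), "run_id")
  structure(
    list(reference = reference, candidates = candidates,
         specs = lapply(manifest$candidates, `[[`, "spec"),
         severity = vapply(manifest$candidates, `[[`, numeric(1),
                           "ground_truth_severity"),
         run_ids = names(candidates), seed = manifest$seed),
    class = "mm_candidate_set")
}
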