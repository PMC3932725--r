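# Parameter-grid bookkeeping for evaluation campaigns: each registration (or
# other image-processing) algorithm is run over a discrete grid of parameter
# settings, and every run yields one candidate image / one row of the metric
# table.

#' Define a parameter grid
#'
#' @param algorithm_name short algorithm label, e.g. `"air_linear"`.
#' @param axes named list of discrete axis values, e.g.
#'   `list(blur = c(11, 15, 17, 19, 25), model = c(6, 7, 9), cost = c(1, 3))`.
#' @param multiplier integer replication factor for grids described as "k
#'   times some base grid" without their own extra axis (default 1).
#' @return an object of class `mm_parameter_grid`.
#' @export
parameter_grid <- function(algorithm_name, axes, multiplier = 1L) {
  if (!is.list(axes) || length(axes) == 0L || is.null(names(axes)) ||
      any(!nzchar(names(axes))))
    stop("axes must be a non-empty named list")
  for (nm in names(axes)) {
    if (length(axes[[nm]]) == 0L)
      stop("axis '", nm, "' of grid '", algorithm_name, "' is empty")
    if (anyDuplicated(axes[[nm]]))
      stop("axis '", nm, "' of grid '", algorithm_name, "' has duplicate values")
  }
  if (multiplier < 1L) stop("multiplier must be >= 1")
  structure(list(algorithm_name = algorithm_name, axes = axes,
                 multiplier = as.integer(multiplier)),
            class = "mm_parameter_grid")
}

#' Enumerate all parameter assignments of a grid
#'
#' Full Cartesian product in deterministic lexicographic order: the first
#' declared axis varies slowest, the last fastest.
#'
#' @param grid an [parameter_grid()].
#' @return data.frame with one column per axis plus `algorithm` and `run_id`
#'   (`algorithm/ordinal`); `multiplier` does not expand rows (see
#'   [campaign_size()]).
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "mm_parameter_grid"))
  ax <- grid$axes
  # expand.grid varies the first factor fastest; reverse to get the first
  # declared axis slowest, then restore column order.
  g <- expand.grid(rev(ax), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(ax)), drop = FALSE]
  names(g) <- names(ax)
  data.frame(run_id = paste0(grid$algorithm_name, "/",
                             sprintf("%04d", seq_len(nrow(g)))),
             algorithm = grid$algorithm_name, g,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Total size of a campaign
#'
#' @param grids list of [parameter_grid()]s.
#' @param multipliers optional integer vector overriding each grid's own
#'   multiplier.
#' @return total run count: sum over grids of multiplier * product of axis
#'   sizes.
#' @export
campaign_size <- function(grids, multipliers = NULL) {
  if (inherits(grids, "mm_parameter_grid")) grids <- list(grids)
  if (is.null(multipliers))
    multipliers <- vapply(grids, function(g) g$multiplier, integer(1))
  multipliers <- as.integer(rep_len(multipliers, length(grids)))
  if (any(multipliers < 1L)) stop("multipliers must be >= 1")
  sizes <- vapply(grids, function(g)
    prod(vapply(g$axes, length, integer(1))), numeric(1))
  as.integer(sum(multipliers * sizes))
}

#' Read / write a campaign specification (JSON)
#'
#' A campaign is a JSON list of `{algorithm, axes: {name: [values]},
#' multiplier}`. The package ships a fixture with the four standard
#' registration grids (two AIR variants, FSL FLIRT, MINC Tracc) totalling
#' 186 runs; see `system.file("extdata", "campaign_registration.json",
#' package = "metricmine")`.
#'
#' @param path JSON file path.
#' @return list of `mm_parameter_grid`s.
#' @export
read_campaign <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(spec, function(g)
    parameter_grid(g$algorithm,
                   lapply(g$axes, function(v) unlist(v)),
                   multiplier = if (is.null(g$multiplier)) 1L else g$multiplier))
}

#' @rdname read_campaign
#' @param grids list of `mm_parameter_grid`s to serialise.
#' @export
write_campaign <- function(grids, path) {
  spec <- lapply(grids, function(g)
    list(algorithm = g$algorithm_name, axes = g$axes,
         multiplier = g$multiplier))
  jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Enumerate a whole campaign
#'
#' @param grids list of `mm_parameter_grid`s.
#' @return data.frame stacking [enumerate_grid()] of each grid, with grids
#'   whose multiplier is k > 1 replicated k times (replicate index appended
#'   to the run id).
#' @export
enumerate_campaign <- function(grids) {
  if (inherits(grids, "mm_parameter_grid")) grids <- list(grids)
  out <- lapply(grids, function(g) {
    runs <- enumerate_grid(g)
    if (g$multiplier > 1L) {
      runs <- do.call(rbind, lapply(seq_len(g$multiplier), function(k) {
        rk <- runs
        rk$run_id <- paste0(rk$run_id, ".", k)
        rk
      }))
    }
    runs
  })
  all_cols <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(d) {
    for (nm in setdiff(all_cols, names(d))) d[[nm]] <- NA
    d[, all_cols, drop = FALSE]
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Build run records for logging
#'
#' @param assignments data.frame from [enumerate_grid()] or
#'   [enumerate_campaign()].
#' @param image_paths optional character vector of candidate image paths.
#' @param status initial status label (default `"pending"`).
#' @return list of run-record lists (`run_id`, `algorithm`, `parameters`,
#'   `image_path`, `status`) ready for [store_log_run()].
#' @export
run_records <- function(assignments, image_paths = NA_character_,
                        status = "pending") {
  image_paths <- rep_len(image_paths, nrow(assignments))
  par_cols <- setdiff(names(assignments), c("run_id", "algorithm"))
  lapply(seq_len(nrow(assignments)), function(i) {
    pars <- as.list(assignments[i, par_cols, drop = FALSE])
    pars <- pars[!vapply(pars, function(x) all(is.na(x)), logical(1))]
    list(run_id = assignments$run_id[i],
         algorithm = assignments$algorithm[i],
         parameters = pars,
         image_path = image_paths[i],
         status = status)
  })
}
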