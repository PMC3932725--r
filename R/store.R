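# Durable relational logging of runs and metric values. An embedded
# single-file SQLite database provides the ACID guarantees (atomic battery
# commits, independent parallel writers, ad hoc SQL extraction); the schema
# is plain SQL so a client-server backend is a drop-in.

utc_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

canonical_json <- function(x) {
  if (length(x)) x <- x[order(names(x))]
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}

#' Open (and initialise) a metric store
#'
#' @param path database file path; created with the package schema if absent.
#'   `":memory:"` gives a transient in-memory store.
#' @return a DBI connection of class `mm_store`.
#' @export
store_open <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON;")
  schema <- readLines(system.file("extdata", "schema.sql",
                                  package = "metricmine"))
  for (stmt in strsplit(paste(schema, collapse = "\n"), ";", fixed = TRUE)[[1]]) {
    if (grepl("[[:alpha:]]", stmt)) DBI::dbExecute(con, stmt)
  }
  class(con) <- c(class(con))
  con
}

#' @rdname store_open
#' @param store an open store connection.
#' @export
store_close <- function(store) DBI::dbDisconnect(store)

#' Log a run record
#'
#' One row per run (candidate image), carrying the algorithm, its parameter
#' assignment (canonical-ordered JSON) and execution metadata. Re-logging an
#' existing `run_id` is an error and leaves the store unchanged.
#'
#' @param store an open store connection.
#' @param record list with `run_id`, `algorithm`, `parameters` (named list),
#'   optional `image_path` and `status` (see [run_records()]).
#' @return the committed `run_id`, invisibly.
#' @export
store_log_run <- function(store, record) {
  stopifnot(is.list(record), !is.null(record$run_id))
  n <- DBI::dbGetQuery(store, "SELECT COUNT(*) AS k FROM runs WHERE run_id = ?",
                       params = list(record$run_id))$k
  if (n > 0) stop("duplicate run_id: ", record$run_id)
  DBI::dbExecute(store,
    "INSERT INTO runs (run_id, algorithm, parameters_json, image_path, created_at, status)
     VALUES (?, ?, ?, ?, ?, ?)",
    params = list(record$run_id,
                  record$algorithm %||% "unspecified",
                  canonical_json(record$parameters %||% list()),
                  record$image_path %||% NA_character_,
                  utc_now(),
                  record$status %||% "done"))
  invisible(record$run_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log the 11 metric results of one run atomically
#'
#' All rows for the run are committed in a single transaction: an
#' interrupted or failing write leaves no partial battery behind.
#'
#' @param store an open store connection.
#' @param run_id a run already logged with [store_log_run()].
#' @param results named list of `mm_metric_result`s as returned by
#'   [evaluate_pair()]; `NULL` entries (degenerate inputs) are stored as
#'   missing cells.
#' @return invisibly, the number of rows written.
#' @export
store_log_metrics <- function(store, run_id, results) {
  k <- DBI::dbGetQuery(store, "SELECT COUNT(*) AS k FROM runs WHERE run_id = ?",
                       params = list(run_id))$k
  if (k == 0) stop("unknown run_id: ", run_id)
  DBI::dbExecute(store, "BEGIN IMMEDIATE;")
  ok <- FALSE
  on.exit(if (!ok) DBI::dbExecute(store, "ROLLBACK;"))
  now <- utc_now()
  for (nm in names(results)) {
    res <- results[[nm]]
    if (!is.null(res) && !inherits(res, "mm_metric_result"))
      stop("result for metric '", nm, "' is not an mm_metric_result")
    DBI::dbExecute(store,
      "INSERT INTO metric_values (run_id, metric_name, raw_value, score, is_missing, computed_at)
       VALUES (?, ?, ?, ?, ?, ?)",
      params = list(run_id, nm,
                    if (is.null(res) || is.na(res$raw)) NA_real_ else res$raw,
                    if (is.null(res)) NA_real_ else res$score,
                    as.integer(is.null(res)), now))
  }
  DBI::dbExecute(store, "COMMIT;")
  ok <- TRUE
  invisible(length(results))
}

#' Log an evaluated battery (runs + metric values)
#'
#' Convenience wrapper: logs one run record per table row and its 11 metric
#' cells, each battery atomically.
#'
#' @param store an open store connection.
#' @param table an `mm_metric_table` from [evaluate_battery()].
#' @param records optional run records aligned with the table rows; defaults
#'   to bare records named by `candidate_id`.
#' @return invisibly, the vector of logged run ids.
#' @export
store_log_table <- function(store, table, records = NULL) {
  raw <- attr(table, "raw_values")
  miss <- attr(table, "missing")
  ids <- table$candidate_id
  for (i in seq_along(ids)) {
    rec <- if (is.null(records)) list(run_id = ids[i], algorithm = "unspecified",
                                      parameters = list(), status = "done")
           else records[[i]]
    store_log_run(store, rec)
    results <- stats::setNames(lapply(metric_names(), function(m) {
      if (!is.null(miss) && miss[i, m]) return(NULL)
      metric_result(m, if (is.null(raw)) NA_real_ else raw[i, m][[1]],
                    table[i, m][[1]], "similarity")
    }), metric_names())
    store_log_metrics(store, rec$run_id, results)
  }
  invisible(ids)
}

#' Fetch the metric table back out of the store
#'
#' @param store an open store connection.
#' @param algorithm optional algorithm name filter.
#' @param parameter optional named list of parameter values that must all
#'   match the run's assignment, e.g. `list(cost = 1)`.
#' @return an `mm_metric_table` (scores as stored; `raw_values` attribute
#'   attached; missing cells NA), rows in `run_id` order.
#' @export
store_fetch_table <- function(store, algorithm = NULL, parameter = NULL) {
  runs <- DBI::dbGetQuery(store,
    "SELECT run_id, algorithm, parameters_json FROM runs ORDER BY run_id")
  if (!is.null(algorithm)) runs <- runs[runs$algorithm %in% algorithm, ]
  if (!is.null(parameter) && nrow(runs)) {
    keep <- vapply(runs$parameters_json, function(js) {
      pars <- jsonlite::fromJSON(js)
      all(vapply(names(parameter), function(nm)
        !is.null(pars[[nm]]) && identical(as.character(pars[[nm]]),
                                          as.character(parameter[[nm]])),
        logical(1)))
    }, logical(1), USE.NAMES = FALSE)
    runs <- runs[keep, ]
  }
  if (nrow(runs) == 0L)
    stop(structure(class = c("mm_empty_result", "error", "condition"),
                   list(message = "no runs match the given filter", call = NULL)))
  vals <- DBI::dbGetQuery(store,
    "SELECT run_id, metric_name, raw_value, score, is_missing FROM metric_values")
  vals <- vals[vals$run_id %in% runs$run_id, ]
  p <- metric_names()
  scores <- raws <- matrix(NA_real_, nrow(runs), length(p),
                           dimnames = list(NULL, p))
  miss <- matrix(FALSE, nrow(runs), length(p), dimnames = list(NULL, p))
  ri <- match(vals$run_id, runs$run_id)
  ci <- match(vals$metric_name, p)
  ok <- !is.na(ri) & !is.na(ci)
  scores[cbind(ri[ok], ci[ok])] <- vals$score[ok]
  raws[cbind(ri[ok], ci[ok])] <- vals$raw_value[ok]
  miss[cbind(ri[ok], ci[ok])] <- vals$is_missing[ok] == 1
  scores[miss] <- NA_real_
  out <- data.frame(candidate_id = runs$run_id, scores,
                    stringsAsFactors = FALSE)
  attr(out, "raw_values") <- data.frame(candidate_id = runs$run_id, raws,
                                        stringsAsFactors = FALSE)
  attr(out, "missing") <- miss
  class(out) <- c("mm_metric_table", "data.frame")
  out
}

#' Export the store to CSV
#'
#' @param store an open store connection.
#' @param dir output directory; writes `runs.csv` and `metric_values.csv`.
#' @return the two file paths, invisibly.
#' @export
store_export_csv <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  runs <- DBI::dbGetQuery(store, "SELECT * FROM runs ORDER BY run_id")
  vals <- DBI::dbGetQuery(store,
    "SELECT * FROM metric_values ORDER BY run_id, metric_name")
  p1 <- file.path(dir, "runs.csv"); p2 <- file.path(dir, "metric_values.csv")
  utils::write.csv(runs, p1, row.names = FALSE)
  utils::write.csv(vals, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
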