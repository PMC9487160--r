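#' Construct a patient cohort
#'
#' A cohort bundles the feature table, optional binary labels, optional
#' survival follow-up records and row identifiers, and is the universe every
#' split (train pool, internal validation, seed) indexes into.
#'
#' @param features `data.frame`, one row per patient. Column types are
#'   declared through `schema`, not inferred.
#' @param schema Column-role declaration: a list with `id`, `categorical`,
#'   `continuous` and optionally `label`, `dfs_time`, `dfs_event`, `os_time`,
#'   `os_event` entries naming columns of the source table (see
#'   [read_schema()]). Here only `categorical`/`continuous` names are used.
#' @param labels Optional binary (0/1) vector, one per row.
#' @param followup Optional `data.frame` with columns `dfs_time`, `dfs_event`,
#'   `os_time`, `os_event` (times in months, events 0/1).
#' @param ids Row identifiers, unique; defaults to `1..N` as character.
#' @return An object of class `elas_cohort`.
#' @export
cohort <- function(features, schema, labels = NULL, followup = NULL, ids = NULL) {
  stopifnot(is.data.frame(features))
  feat_cols <- c(schema$categorical, schema$continuous)
  missing_cols <- setdiff(feat_cols, names(features))
  if (length(missing_cols) > 0) {
    stop("schema declares absent feature column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cc in schema$continuous) {
    v <- features[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      if (any(!is.na(v) & is.na(vn))) {
        stop("continuous column '", cc, "' contains non-numeric values")
      }
      features[[cc]] <- vn
    }
  }
  for (cc in schema$categorical) {
    features[[cc]] <- as.character(features[[cc]])
  }
  n <- nrow(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("cohort ids must be unique")
  if (length(ids) != n) stop("ids length must match the feature table")
  if (!is.null(labels)) {
    labels <- check_binary_labels(labels, n)
  }
  if (!is.null(followup)) {
    followup <- validate_followup(followup, n)
  }
  structure(
    list(
      features = features[, feat_cols, drop = FALSE],
      schema = list(categorical = schema$categorical %||% character(),
                    continuous = schema$continuous %||% character()),
      labels = labels, followup = followup, ids = ids
    ),
    class = "elas_cohort"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_followup <- function(followup, n) {
  req <- c("dfs_time", "dfs_event", "os_time", "os_event")
  if (!all(req %in% names(followup))) {
    stop("followup must contain columns: ", paste(req, collapse = ", "))
  }
  followup <- as.data.frame(followup)[, req]
  if (nrow(followup) != n) stop("followup must have one record per cohort row")
  for (tc in c("dfs_time", "os_time")) {
    if (any(followup[[tc]] < 0, na.rm = TRUE)) {
      stop("follow-up times must be non-negative (", tc, ")")
    }
  }
  for (ec in c("dfs_event", "os_event")) {
    if (!all(followup[[ec]] %in% c(0, 1))) {
      stop("follow-up event flags must be binary (", ec, ")")
    }
  }
  followup
}

#' @export
print.elas_cohort <- function(x, ...) {
  cat(sprintf(
    "<elas_cohort> %d patients, %d features (%d categorical, %d continuous)\n",
    nrow(x$features), ncol(x$features),
    length(x$schema$categorical), length(x$schema$continuous)
  ))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d positive (%.1f%%)\n", sum(x$labels),
                100 * mean(x$labels)))
  }
  if (!is.null(x$followup)) cat("  follow-up: DFS + OS recorded\n")
  invisible(x)
}

#' Read a cohort from delimited text
#'
#' @param path CSV/TSV file with a header row; the delimiter is taken from
#'   the file extension (`.tsv` = tab, otherwise comma).
#' @param schema A schema list or a path to a YAML/JSON schema file
#'   (see [read_schema()]).
#' @return An [cohort()] object with rows in file order.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.character(schema) && length(schema) == 1L) schema <- read_schema(schema)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  declared <- c(schema$id, schema$label, schema$dfs_time, schema$dfs_event,
                schema$os_time, schema$os_event)
  missing_cols <- setdiff(declared, names(tab))
  if (length(missing_cols) > 0) {
    stop("schema declares absent column(s): ", paste(missing_cols, collapse = ", "))
  }
  ids <- if (!is.null(schema$id)) as.character(tab[[schema$id]]) else NULL
  labels <- if (!is.null(schema$label)) tab[[schema$label]] else NULL
  followup <- NULL
  fu_roles <- c("dfs_time", "dfs_event", "os_time", "os_event")
  if (all(vapply(fu_roles, function(r) !is.null(schema[[r]]), logical(1)))) {
    followup <- data.frame(
      dfs_time = tab[[schema$dfs_time]], dfs_event = tab[[schema$dfs_event]],
      os_time = tab[[schema$os_time]], os_event = tab[[schema$os_event]]
    )
  }
  cohort(tab, schema, labels = labels, followup = followup, ids = ids)
}

#' Write a cohort (and its schema) as delimited text
#'
#' Inverse of [read_cohort()]: emits one CSV row per patient with id, feature,
#' label and follow-up columns, plus a schema file declaring the column roles.
#'
#' @param x An `elas_cohort`.
#' @param path Output CSV path.
#' @param schema_path Optional YAML schema output path.
#' @return Invisibly, the schema list that describes the written file.
#' @export
write_cohort <- function(x, path, schema_path = NULL) {
  stopifnot(inherits(x, "elas_cohort"))
  out <- cbind(data.frame(patient_id = x$ids, stringsAsFactors = FALSE),
               x$features)
  schema <- list(id = "patient_id",
                 categorical = x$schema$categorical,
                 continuous = x$schema$continuous)
  if (!is.null(x$labels)) {
    out$label <- x$labels
    schema$label <- "label"
  }
  if (!is.null(x$followup)) {
    out <- cbind(out, x$followup)
    schema[c("dfs_time", "dfs_event", "os_time", "os_event")] <-
      list("dfs_time", "dfs_event", "os_time", "os_event")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(schema_path)) write_schema(schema, schema_path)
  invisible(schema)
}

#' Read / write a column-role schema
#'
#' The schema declares which columns of a cohort file play which role:
#' `id`, `categorical` (vector), `continuous` (vector), and optionally
#' `label`, `dfs_time`, `dfs_event`, `os_time`, `os_event`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return The schema as a named list.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  schema <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (role in c("categorical", "continuous")) {
    schema[[role]] <- as.character(schema[[role]] %||% character())
  }
  schema
}

#' @rdname read_schema
#' @param schema Schema list to serialize.
#' @export
write_schema <- function(schema, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(schema, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(schema, path)
  }
  invisible(path)
}

#' Derive horizon-specific binary outcome labels from follow-up
#'
#' Implements the standard prognostic labeling at a fixed horizon: a patient
#' who experienced the event (recurrence under disease-free-survival
#' semantics, death under overall-survival semantics) at or before the
#' horizon is a positive; a patient observed event-free through the horizon
#' is a negative; a patient censored before the horizon without an event is
#' excluded (lost to follow-up within the period). The horizon boundary is
#' closed: an event at exactly the horizon counts as within the period, and a
#' censoring at exactly the horizon counts as followed through it.
#'
#' @param followup `data.frame` with `dfs_time`, `dfs_event`, `os_time`,
#'   `os_event` (times in months, events 0/1), or an `elas_cohort` carrying
#'   one.
#' @param horizon Horizon in years (the prognostic tasks use 1, 3 and 5).
#' @param outcome `"recurrence"` (DFS) or `"death"` (OS).
#' @return List with `labels` (0/1/NA, NA where excluded) and `included`
#'   (logical mask).
#' @export
derive_labels <- function(followup, horizon, outcome = c("recurrence", "death")) {
  outcome <- match.arg(outcome)
  if (inherits(followup, "elas_cohort")) {
    if (is.null(followup$followup)) stop("cohort carries no follow-up records")
    followup <- followup$followup
  }
  followup <- validate_followup(followup, nrow(followup))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    stop("horizon must be a single positive number of years")
  }
  h_months <- 12 * horizon
  time <- if (outcome == "recurrence") followup$dfs_time else followup$os_time
  event <- if (outcome == "recurrence") followup$dfs_event else followup$os_event

  labels <- rep(NA_integer_, length(time))
  labels[event == 1 & time <= h_months] <- 1L
  # observed (event-free) through the horizon: later event or late censoring
  labels[(event == 1 & time > h_months) | (event == 0 & time >= h_months)] <- 0L
  included <- !is.na(labels)
  list(labels = labels, included = included)
}
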