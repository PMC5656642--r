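# Delimited-text readers and writers for every pipeline table, with
# schema validation that names the first offending row and column.

table_schemas <- list(
  car_stops = list(
    required = c("stop_id", "site_type", "detected"),
    optional = c("municipality_id", "alert_prob", "day_of_year"),
    checks = list(
      site_type = function(v) v %in% c("road", "ITV"),
      detected = function(v) v %in% c(0, 1),
      alert_prob = function(v) is.na(v) | (v >= 0 & v <= 1),
      day_of_year = function(v) is.na(v) | (v >= 1 & v <= 366)
    )
  ),
  recapture = list(
    required = c("trial_id", "condition", "outcome"),
    optional = c("temp_c", "rh_pct"),
    checks = list(
      condition = function(v) v %in% recapture_conditions,
      outcome = function(v) v %in% recapture_outcomes
    )
  ),
  cell_posteriors = list(
    required = c("cell_id", "period", "draw_index", "value"),
    optional = character(),
    checks = list(
      period = function(v) v >= 1 & v <= 26,
      value = function(v) v >= 0 & v <= 1
    )
  ),
  overlaps = list(
    required = c("municipality_id", "cell_id", "weight"),
    optional = character(),
    checks = list(weight = function(v) v >= 0 & v <= 1)
  ),
  municipalities = list(
    required = c("municipality_id", "province_id", "population", "confirmed"),
    optional = character(),
    checks = list(
      population = function(v) v >= 0,
      confirmed = function(v) v %in% c(TRUE, FALSE, 0, 1)
    )
  ),
  od = list(
    required = c("origin", "destination", "flow"),
    optional = character(),
    checks = list(flow = function(v) v >= 0)
  )
)

#' Read and validate a pipeline table
#'
#' Reads a comma-separated table (header row, UTF-8, "." decimal) and
#' validates it against one of the pipeline schemas. Validation errors name
#' the offending column and the first offending data row.
#'
#' @param path File path.
#' @param schema One of \code{"car_stops"}, \code{"recapture"},
#'   \code{"cell_posteriors"}, \code{"overlaps"}, \code{"municipalities"},
#'   \code{"od"}.
#' @return A validated data.frame.
#' @export
read_table <- function(path, schema) {
  if (!schema %in% names(table_schemas)) {
    stop("unknown schema: ", schema, call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  validate_table(df, schema, label = path)
}

#' Validate a data frame against a pipeline schema
#'
#' @param df Data frame to check.
#' @param schema Schema id (see \code{\link{read_table}}).
#' @param label Name used in error messages.
#' @return The data frame, invisibly unchanged, on success.
#' @export
validate_table <- function(df, schema, label = deparse(substitute(df))) {
  sc <- table_schemas[[schema]]
  if (is.null(sc)) stop("unknown schema: ", schema, call. = FALSE)
  miss <- setdiff(sc$required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", label,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in names(sc$checks)) {
    if (!col %in% names(df)) next
    ok <- sc$checks[[col]](df[[col]])
    if (any(!ok)) {
      stop(sprintf("%s: invalid value in column '%s' at row %d (value: %s)",
                   label, col, which(!ok)[1],
                   format(df[[col]][which(!ok)[1]])), call. = FALSE)
    }
  }
  df
}

#' Write a pipeline table as CSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert long-format cell posterior draws to a cell_posteriors array
#'
#' @param df Data frame with cell_id, period, draw_index, value.
#' @return A \code{\link{cell_posteriors}} array.
#' @export
cells_from_long <- function(df) {
  validate_table(df, "cell_posteriors", label = "cell posterior table")
  cells <- sort(unique(df$cell_id))
  n_per <- max(df$period)
  n_draw <- max(df$draw_index)
  a <- array(NA_real_, c(length(cells), n_per, n_draw),
             dimnames = list(cells, NULL, NULL))
  a[cbind(match(df$cell_id, cells), df$period, df$draw_index)] <- df$value
  if (anyNA(a)) {
    stop("cell posterior table is ragged: identical draw counts required per cell-period",
         call. = FALSE)
  }
  cell_posteriors(a)
}

#' Flatten a cell_posteriors array to long format
#'
#' @param cells A \code{cell_posteriors} array.
#' @return Data frame with cell_id, period, draw_index, value.
#' @export
cells_to_long <- function(cells) {
  d <- dim(cells)
  data.frame(
    cell_id = rep(dimnames(cells)[[1]], times = d[2] * d[3]),
    period = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    draw_index = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(cells),
    stringsAsFactors = FALSE
  )
}

#' Assemble a geography from its component tables
#'
#' @param municipalities Data frame (municipalities schema).
#' @param overlaps Data frame (overlaps schema).
#' @return A \code{geography} object.
#' @export
geography_from_tables <- function(municipalities, overlaps) {
  validate_table(municipalities, "municipalities", label = "municipality table")
  validate_table(overlaps, "overlaps", label = "overlap table")
  municipalities$confirmed <- as.logical(municipalities$confirmed)
  geo <- list(
    provinces = sort(unique(municipalities$province_id)),
    municipalities = municipalities,
    cells = sort(unique(overlaps$cell_id)),
    overlaps = overlaps
  )
  class(geo) <- "geography"
  validate_geography(geo)
  geo
}

#' Convert a long OD table to a province_od matrix
#'
#' @param df Data frame with origin, destination, flow.
#' @param provinces Optional character vector fixing the province set and
#'   order.
#' @return A \code{\link{province_od}} matrix.
#' @export
od_from_long <- function(df, provinces = NULL) {
  validate_table(df, "od", label = "OD table")
  provs <- provinces %||% sort(unique(c(df$origin, df$destination)))
  m <- matrix(0, length(provs), length(provs),
              dimnames = list(provs, provs))
  m[cbind(match(df$origin, provs), match(df$destination, provs))] <- df$flow
  province_od(m)
}

#' Flatten an OD matrix to long format
#'
#' @param od A \code{province_od} or \code{municipal_od} matrix.
#' @param drop_zero Drop zero flows (default TRUE).
#' @return Data frame with origin, destination, flow.
#' @export
od_to_long <- function(od, drop_zero = TRUE) {
  idx <- which(if (drop_zero) od > 0 else row(od) != col(od), arr.ind = TRUE)
  data.frame(
    origin = rownames(od)[idx[, 1]],
    destination = colnames(od)[idx[, 2]],
    flow = od[idx],
    stringsAsFactors = FALSE
  )
}
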