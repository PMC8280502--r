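#' Wide-format dyadic panel data
#'
#' One row per dyad, one column per indicator x rater x occasion in the
#' package's frozen ordering (rater-major, occasion next, indicator last,
#' names `indicator<i>_rater<k>_t<l>`).  Missing cells are `NA`.  Rows with
#' no observed value at all are dropped with a message and counted in the
#' `n_dropped` attribute.
#'
#' @param values Numeric matrix or data frame, dyads x observed variables.
#'   Columns are matched by name when names are present, otherwise taken in
#'   order.
#' @param spec The [lst_spec()] the data belong to.
#' @param dyad_id Optional identifier per row; defaults to row numbers.
#' @return An object of class `lst_panel` with elements `values` (matrix
#'   with `NA` for missing), `dyad_id` and `spec_dims`.
#' @export
lst_panel <- function(values, spec, dyad_id = NULL) {
  stopifnot(inherits(spec, "lst_spec"))
  nm <- obs_names(spec)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != length(nm))
    stop("data have ", ncol(values), " columns; spec expects ", length(nm),
         call. = FALSE)
  if (!is.null(colnames(values))) {
    if (!all(nm %in% colnames(values)))
      stop("column names do not match the spec's observed-variable names ",
           "(indicator<i>_rater<k>_t<l>)", call. = FALSE)
    values <- values[, nm, drop = FALSE]
  } else {
    colnames(values) <- nm
  }
  if (is.null(dyad_id)) dyad_id <- seq_len(nrow(values))
  stopifnot(length(dyad_id) == nrow(values))
  all_missing <- rowSums(!is.na(values)) == 0L
  if (any(all_missing)) {
    message(sum(all_missing), " row(s) with no observed values dropped")
    values <- values[!all_missing, , drop = FALSE]
    dyad_id <- dyad_id[!all_missing]
  }
  structure(list(values = values, dyad_id = dyad_id,
                 spec_dims = c(I = spec$n_indicators, K = spec$n_raters,
                               L = spec$n_occasions)),
            class = "lst_panel", n_dropped = sum(all_missing))
}

#' @export
print.lst_panel <- function(x, ...) {
  cat(sprintf("LST panel: %d dyads x %d observed variables, %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.lst_panel <- function(x) dim(x$values)

#' Read / write panel data as wide CSV
#'
#' The CSV dialect has one `dyad_id` column followed by the observed
#' variables (`indicator<i>_rater<k>_t<l>`); missing cells are empty fields
#' or `NA`.
#'
#' @param file Path to a CSV file.
#' @param spec The [lst_spec()] the data belong to.
#' @return `read_panel_csv()`: an [lst_panel()]; `write_panel_csv()`: the
#'   path, invisibly.
#' @export
read_panel_csv <- function(file, spec) {
  df <- utils::read.csv(file, check.names = FALSE)
  id <- if ("dyad_id" %in% names(df)) df[["dyad_id"]] else NULL
  df <- df[, setdiff(names(df), "dyad_id"), drop = FALSE]
  lst_panel(df, spec, dyad_id = id)
}

#' @rdname read_panel_csv
#' @param panel An [lst_panel()].
#' @export
write_panel_csv <- function(panel, file) {
  df <- data.frame(dyad_id = panel$dyad_id, panel$values,
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, na = "")
  invisible(file)
}

# Group rows by missingness pattern and reduce to sufficient statistics:
# observed column indices (0-based for the compiled core), count, mean and
# within-pattern scatter sum((x - m)(x - m)').  FIML evaluation only needs
# these, so likelihood cost is independent of n.
pattern_stats <- function(values) {
  obs <- !is.na(values)
  key <- apply(obs, 1L, function(r) rawToChar(as.raw(as.integer(r) + 48L)))
  groups <- split(seq_len(nrow(values)), key)
  lapply(groups, function(rows) {
    idx <- which(obs[rows[1L], ])
    X <- values[rows, idx, drop = FALSE]
    m <- colMeans(X)
    Xc <- sweep(X, 2L, m)
    list(idx = idx - 1L, n = length(rows), m = unname(m),
         W = unname(crossprod(Xc)), rows = rows)
  })
}
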