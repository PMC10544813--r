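# Flat-file interfaces: CSV for datasets, coordinates and predictions
# (presence-absence data ship as flat tables), JSON for fitted parameters,
# YAML/flags for run configuration. Every artifact embeds enough metadata
# (seed, m, R, grid, package version) to re-run the producing command.

# locale-independent numeric formatting (full precision, '.' decimal)
.fmt_num <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), "")
  out
}

.write_meta <- function(con, meta) {
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = ","),
                              "")), con)
}

#' Read a point-referenced binary dataset from CSV
#'
#' Expects a header with coordinate columns `x` and `y_coord` (or `lon` and
#' `lat`), a 0/1 `response` column, and optionally further numeric columns,
#' which are taken as covariates. Lines starting with `#` are metadata and
#' are skipped. Row order is preserved; validation errors name the
#' offending data rows.
#'
#' @param path CSV file path.
#' @return A [spatial_dataset()].
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  nm <- names(df)
  if (all(c("x", "y_coord") %in% nm)) {
    cx <- "x"; cy <- "y_coord"
  } else if (all(c("lon", "lat") %in% nm)) {
    cx <- "lon"; cy <- "lat"
  } else {
    stop("missing coordinate columns: expected `x`/`y_coord` or `lon`/`lat`")
  }
  if (!("response" %in% nm))
    stop("missing required column `response`")
  bad <- which(!(df$response %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("`response` must be 0 or 1; invalid at row(s) %s",
                 paste(head(bad, 5L), collapse = ", ")))
  covs <- setdiff(nm, c(cx, cy, "response"))
  X <- if (length(covs)) as.matrix(df[covs]) else NULL
  coords <- cbind(df[[cx]], df[[cy]])
  if (anyDuplicated(coords)) {
    dup <- which(duplicated(coords))
    stop(sprintf("duplicate coordinates at row(s) %s",
                 paste(head(dup, 5L), collapse = ", ")))
  }
  spatial_dataset(coords, df$response, X)
}

#' Write a dataset to CSV
#'
#' Columns `x`, `y_coord`, `response`, then any covariates as `x1`, `x2`,
#' ...; metadata is embedded as leading `#` comment lines.
#'
#' @param dataset a [spatial_dataset()].
#' @param path output path.
#' @param meta named list of metadata to embed.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path, meta = list()) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  .write_meta(con, c(list(package = paste0("probitNNGP ",
                                           .pkg_version())), meta))
  p <- ncol(dataset$X)
  header <- c("x", "y_coord", "response",
              if (p) paste0("x", seq_len(p)))
  writeLines(paste(header, collapse = ","), con)
  n <- nrow(dataset$coords)
  for (i in seq_len(n)) {
    row <- c(.fmt_num(dataset$coords[i, ]), format(dataset$y[i]),
             if (p) .fmt_num(dataset$X[i, ]))
    writeLines(paste(row, collapse = ","), con)
  }
  invisible(path)
}

#' Write predictions to CSV
#'
#' Columns `index`, `x`, `y_coord`, `prob`, `mc_se` in deterministic
#' (input) order, full precision, locale-independent decimal formatting;
#' run metadata (seed, m, R, version) is embedded as `#` comment lines.
#'
#' @param result a `prediction_result` from [predict_at_locations()].
#' @param path output path.
#' @param meta extra metadata to embed.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(result, path, meta = list()) {
  stopifnot(inherits(result, "prediction_result"))
  con <- file(path, "w")
  on.exit(close(con))
  base_meta <- list(package = paste0("probitNNGP ", .pkg_version()))
  for (key in c("m", "R", "seed")) {
    v <- attr(result, key)
    if (!is.null(v)) base_meta[[key]] <- v
  }
  .write_meta(con, c(base_meta, meta))
  writeLines("index,x,y_coord,prob,mc_se", con)
  for (i in seq_len(nrow(result))) {
    writeLines(paste(c(format(result$index[i]),
                       .fmt_num(c(result$x[i], result$y_coord[i],
                                  result$prob[i], result$mc_se[i]))),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Read predictions written by [write_predictions_csv()]
#'
#' @param path CSV file path.
#' @return A data frame with columns `index`, `x`, `y_coord`, `prob`,
#'   `mc_se`.
#' @export
read_predictions_csv <- function(path) {
  read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Write fitted parameters to JSON
#'
#' @param fit a `probit_nngp_fit` or [probit_params()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(fit, path) {
  obj <- if (inherits(fit, "probit_nngp_fit")) {
    list(beta = fit$best_params$beta, sigma2 = fit$best_params$sigma2,
         phi = fit$best_params$phi, m = fit$m, R = fit$R,
         seed = fit$draws_seed,
         grid_sigma2 = fit$grid$sigma2_values,
         grid_phi = fit$grid$phi_values,
         package = paste0("probitNNGP ", .pkg_version()))
  } else if (inherits(fit, "probit_params")) {
    list(beta = fit$beta, sigma2 = fit$sigma2, phi = fit$phi,
         package = paste0("probitNNGP ", .pkg_version()))
  } else {
    stop("`fit` must be a probit_nngp_fit or probit_params")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read parameters from JSON
#'
#' @param path JSON file written by [write_params_json()].
#' @return A [probit_params()].
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  probit_params(beta = if (is.null(obj$beta)) numeric(0)
                       else as.numeric(obj$beta),
                sigma2 = obj$sigma2, phi = obj$phi)
}

.pkg_version <- function() {
  as.character(utils::packageVersion("probitNNGP"))
}

.config_defaults <- function() {
  list(m = 15L, R = 10000L, seed = 1L,
       grid_sigma2 = c(0.5, 1.5, 10), grid_phi = c(15, 45, 10),
       workers = 1L, clamp_eps = 1e-10, beta = numeric(0),
       test_design = "random")
}

#' Resolve a run configuration
#'
#' Precedence: explicit flags > configuration file (YAML) > documented
#' defaults (`m = 15`, `R = 10000`, 10-point grid axes on
#' `[0.5, 1.5] x [15, 45]`, `clamp_eps = 1e-10`). Unknown keys are
#' rejected; basic validity (positive `m`, `R`, sane clamp) is enforced.
#'
#' @param flags named list of overrides (highest precedence).
#' @param file optional YAML configuration file.
#' @return The fully resolved configuration, class `run_config`.
#' @export
run_config <- function(flags = list(), file = NULL) {
  cfg <- .config_defaults()
  if (!is.null(file)) {
    if (!file.exists(file)) stop(sprintf("config file not found: %s", file))
    fromfile <- yaml::read_yaml(file)
    unknown <- setdiff(names(fromfile), names(cfg))
    if (length(unknown))
      stop(sprintf("unknown configuration key(s): %s",
                   paste(unknown, collapse = ", ")))
    cfg <- modifyList(cfg, fromfile)
  }
  unknown <- setdiff(names(flags), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg <- modifyList(cfg, flags)
  if (!is.numeric(cfg$m) || cfg$m < 1)
    stop("`m` must be a positive integer")
  if (!is.numeric(cfg$R) || cfg$R < 1)
    stop("`R` must be a positive integer")
  if (!is.numeric(cfg$clamp_eps) || cfg$clamp_eps <= 0 || cfg$clamp_eps >= 0.5)
    stop("`clamp_eps` must be in (0, 0.5)")
  for (key in c("grid_sigma2", "grid_phi")) {
    v <- cfg[[key]]
    if (length(v) != 3L || v[1L] <= 0 || v[2L] < v[1L] || v[3L] < 1)
      stop(sprintf("`%s` must be c(lo, hi, k) with 0 < lo <= hi, k >= 1", key))
  }
  cfg$m <- as.integer(cfg$m)
  cfg$R <- as.integer(cfg$R)
  cfg$workers <- as.integer(cfg$workers)
  structure(cfg, class = "run_config")
}

# grid axis from a c(lo, hi, k) spec; k = 1 collapses to lo
.grid_axis <- function(spec) {
  if (spec[3L] == 1) spec[1L] else seq(spec[1L], spec[2L],
                                       length.out = spec[3L])
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %s: %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}
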