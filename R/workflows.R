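# User-facing drivers: one-shot entropy dispatch, sliding-window complexity
# profiles, 1D bifurcation sweeps, 2D parameter-plane grids, and file I/O.

#' Compute one entropy of a signal
#'
#' Thin dispatcher over [pe()], [wpe()], [ipe()], and [npe()]; the common
#' entry point of the sliding-window and sweep drivers.
#'
#' @param x numeric signal.
#' @param method one of `"pe"`, `"wpe"`, `"ipe"`, `"npe"`.
#' @param d embedding dimension (3..9).
#' @param error NPE weight tolerance (ignored by the other methods).
#' @param L IPE quantization levels (ignored by the other methods).
#' @return entropy value in `[0, 1]`.
#' @export
entropy_of <- function(x, method = c("npe", "pe", "wpe", "ipe"),
                       d = 5L, error = 0.005, L = 4L) {
  method <- match.arg(method)
  switch(method,
    pe = pe(x, d),
    wpe = wpe(x, d),
    ipe = ipe(x, d, L),
    npe = npe(x, d, error)$value
  )
}

#' Sliding-window complexity profile
#'
#' Computes the chosen entropy independently on consecutive windows of
#' fixed length; for NPE each window gets its own connection network (no
#' cross-window connections). The number of windows is
#' `floor((N - window_length)/step) + 1`; every window lies fully inside
#' the signal, trailing samples that do not fill a window are unused.
#'
#' @inheritParams entropy_of
#' @param window_length window size in samples (`>= d + 1`).
#' @param step slide in samples (`>= 1`).
#' @return object of class `window_profile`: list with `values`, `offsets`
#'   (1-based window starts), `window_length`, `step`, `method`, `config`.
#' @export
sliding_profile <- function(x, method = c("npe", "pe", "wpe", "ipe"),
                            window_length = 1000L, step = 30L,
                            d = 5L, error = 0.005, L = 4L) {
  method <- match.arg(method)
  check_signal(x, n_min = window_length)
  if (window_length < d + 1L) stop("window_length must be >= d + 1", call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  k <- (length(x) - window_length) %/% step + 1L
  offsets <- 1L + (seq_len(k) - 1L) * step
  values <- vapply(offsets, function(o) {
    entropy_of(x[o:(o + window_length - 1L)], method, d, error, L)
  }, numeric(1))
  structure(
    list(values = values, offsets = offsets, window_length = window_length,
         step = step, method = method,
         config = list(d = d, error = error, L = L)),
    class = "window_profile"
  )
}

# inclusive grid with endpoint tolerance against fp drift
axis_values <- function(start, stop, step = NULL, n_points = NULL) {
  if (!is.null(n_points)) {
    if (n_points < 1L) stop("n_points must be >= 1", call. = FALSE)
    if (n_points == 1L) return(start)
    return(start + (stop - start) * (seq_len(n_points) - 1L) / (n_points - 1L))
  }
  if (is.null(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  if (stop < start) stop("stop must be >= start", call. = FALSE)
  m <- floor((stop - start) / step + 1e-9)
  start + step * (0:m)
}

sweep_generators <- list(
  logistic = list(fn = function(pars, n) do.call(logistic_series, c(pars, list(n = n))),
                  params = c("mu", "x0", "transient")),
  simplified_lorenz = list(fn = function(pars, n) do.call(simplified_lorenz_series, c(pars, list(n = n))),
                           params = c("c_par", "h", "transient")),
  fractional_henon = list(fn = function(pars, n) do.call(fractional_henon_series, c(pars, list(n = n))),
                          params = c("a", "b", "nu", "x0", "y0", "allow_long"))
)

check_sweep_args <- function(generator, params) {
  if (!generator %in% names(sweep_generators))
    stop("unknown generator: ", generator, call. = FALSE)
  bad <- setdiff(params, sweep_generators[[generator]]$params)
  if (length(bad))
    stop("unknown parameter(s) for ", generator, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
}

sweep_cell <- function(generator, pars, n, method, d, error, L) {
  tryCatch(
    entropy_of(sweep_generators[[generator]]$fn(pars, n), method, d, error, L),
    error = function(e) NA_real_
  )
}

#' 1D bifurcation sweep of an entropy
#'
#' For each grid value of one generator parameter, generates a fresh series
#' and computes the chosen entropy. Endpoints are inclusive. Cells whose
#' trajectory diverges are returned as `NA`, not errors.
#'
#' @inheritParams entropy_of
#' @param generator `"logistic"`, `"simplified_lorenz"`, or
#'   `"fractional_henon"`.
#' @param param name of the swept generator argument (e.g. `"mu"`, `"c_par"`,
#'   `"a"`, `"nu"`).
#' @param start,stop inclusive parameter range.
#' @param step grid spacing (`> 0`); alternatively give `n_points`.
#' @param n_points number of grid points (overrides `step`).
#' @param n series length per cell.
#' @param ... fixed generator arguments (e.g. `b = 0.2`).
#' @return object of class `sweep_result`: list with `param`, `grid`,
#'   `values`, `method`, `generator`, `config`.
#' @export
sweep_1d <- function(generator, param, start, stop, step = NULL,
                     n_points = NULL, method = "npe", d = 5L,
                     error = 0.005, L = 4L, n = 1000L, ...) {
  fixed <- list(...)
  check_sweep_args(generator, c(param, names(fixed)))
  grid <- axis_values(start, stop, step, n_points)
  values <- vapply(grid, function(v) {
    sweep_cell(generator, c(stats::setNames(list(v), param), fixed),
               n, method, d, error, L)
  }, numeric(1))
  structure(
    list(param = param, grid = grid, values = values, method = method,
         generator = generator,
         config = list(d = d, error = error, L = L, n = n, fixed = fixed)),
    class = "sweep_result"
  )
}

#' 2D parameter-plane sweep of an entropy
#'
#' Entropy over a grid in two generator parameters; `values[i, j]`
#' corresponds to `grid_y[i]` and `grid_x[j]`. Diverged cells are `NA`.
#'
#' @inheritParams sweep_1d
#' @param param_x,param_y names of the two swept generator arguments.
#' @param x_start,x_stop,x_step,x_n grid for `param_x` (step or count).
#' @param y_start,y_stop,y_step,y_n grid for `param_y`.
#' @return object of class `sweep_result` with `values` a matrix.
#' @export
sweep_2d <- function(generator, param_x, x_start, x_stop,
                     param_y, y_start, y_stop,
                     x_step = NULL, y_step = NULL,
                     x_n = NULL, y_n = NULL, method = "npe", d = 5L,
                     error = 0.005, L = 4L, n = 1000L, ...) {
  fixed <- list(...)
  check_sweep_args(generator, c(param_x, param_y, names(fixed)))
  gx <- axis_values(x_start, x_stop, x_step, x_n)
  gy <- axis_values(y_start, y_stop, y_step, y_n)
  values <- matrix(NA_real_, length(gy), length(gx),
                   dimnames = list(format(gy, trim = TRUE),
                                   format(gx, trim = TRUE)))
  for (i in seq_along(gy)) {
    for (j in seq_along(gx)) {
      pars <- c(stats::setNames(list(gy[i], gx[j]), c(param_y, param_x)), fixed)
      values[i, j] <- sweep_cell(generator, pars, n, method, d, error, L)
    }
  }
  structure(
    list(param = c(x = param_x, y = param_y), grid_x = gx, grid_y = gy,
         values = values, method = method, generator = generator,
         config = list(d = d, error = error, L = L, n = n, fixed = fixed)),
    class = "sweep_result"
  )
}

#' Read a univariate signal from text
#'
#' Accepts single-column ASCII (one sample per line, the dialect of the
#' Bonn EEG archive segments) or CSV with a selectable column. Lines
#' starting with `#` are skipped.
#'
#' @param path file path.
#' @param format `"ascii"` (whitespace-separated single column) or `"csv"`.
#' @param column column index for CSV input.
#' @return numeric vector (finite values).
#' @export
read_signal <- function(path, format = c("ascii", "csv"), column = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "ascii") {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
    if (anyNA(vals)) {
      bad <- which(keep)[which(is.na(vals))[1L]]
      stop("non-numeric value at line ", bad, " of ", path, call. = FALSE)
    }
  } else {
    df <- utils::read.csv(path, comment.char = "#", header = FALSE,
                          stringsAsFactors = FALSE)
    if (column > ncol(df)) stop("column ", column, " not present", call. = FALSE)
    col <- df[[column]]
    if (is.character(col) && suppressWarnings(anyNA(as.numeric(col[-1L]))) == FALSE &&
        is.na(suppressWarnings(as.numeric(col[1L])))) {
      col <- col[-1L] # tolerate a single header row
    }
    vals <- suppressWarnings(as.numeric(col))
    if (anyNA(vals)) {
      stop("non-numeric value at row ", which(is.na(vals))[1L],
           ", column ", column, " of ", path, call. = FALSE)
    }
  }
  if (length(vals) == 0L) stop("empty file: ", path, call. = FALSE)
  check_signal(vals)
  vals
}

#' Write a signal as single-column ASCII
#'
#' `#`-prefixed header lines record the generator name and parameters so a
#' written fixture is self-describing.
#'
#' @param x numeric signal.
#' @param path output path.
#' @param header named list echoed as `# name: value` comment lines.
#' @export
write_signal <- function(x, path, header = list()) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(header))
    writeLines(sprintf("# %s: %s", nm, format(header[[nm]])), con)
  writeLines(format(x, trim = TRUE, digits = 15), con)
  invisible(path)
}

#' Write an analysis result to TSV or JSON
#'
#' TSV output carries the full configuration echo in `#`-comment header
#' lines; JSON output round-trips losslessly via [read_results()].
#'
#' @param result a `window_profile`, `sweep_result`, or `npe_result`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- result_payload(result)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  con <- file(path, "w"); on.exit(close(con))
  if (inherits(result, "npe_result")) {
    net <- result$network
    writeLines(sprintf("# npe value=%.10g d=%d error=%g nodes=%d edges=%d",
                       result$value, net$d, net$error, net$n_nodes,
                       nrow(net$edges)), con)
    writeLines("node\traw_score\tprobability", con)
    writeLines(sprintf("%d\t%.10g\t%.10g", seq_len(net$n_nodes),
                       net$raw_scores, result$probabilities), con)
  } else if (inherits(result, "window_profile")) {
    writeLines(sprintf("# sliding profile method=%s window=%d step=%d d=%d error=%g L=%d",
                       result$method, result$window_length, result$step,
                       result$config$d, result$config$error, result$config$L), con)
    writeLines("offset\tvalue", con)
    writeLines(sprintf("%d\t%.10g", result$offsets, result$values), con)
  } else if (inherits(result, "sweep_result")) {
    cfg <- result$config
    writeLines(sprintf("# sweep generator=%s method=%s d=%d error=%g L=%d n=%d",
                       result$generator, result$method, cfg$d, cfg$error,
                       cfg$L, cfg$n), con)
    if (is.matrix(result$values)) {
      writeLines(sprintf("# rows: %s, columns: %s",
                         result$param[["y"]], result$param[["x"]]), con)
      writeLines(paste(c(result$param[["y"]], format(result$grid_x, trim = TRUE)),
                       collapse = "\t"), con)
      for (i in seq_along(result$grid_y))
        writeLines(paste(c(format(result$grid_y[i], trim = TRUE),
                           sprintf("%.10g", result$values[i, ])),
                         collapse = "\t"), con)
    } else {
      writeLines(sprintf("%s\tvalue", result$param), con)
      writeLines(sprintf("%.10g\t%.10g", result$grid, result$values), con)
    }
  } else {
    stop("unsupported result class: ", paste(class(result), collapse = "/"),
         call. = FALSE)
  }
  invisible(path)
}

result_payload <- function(result) {
  if (inherits(result, "npe_result")) {
    net <- result$network
    list(kind = "npe_result", value = result$value, d = net$d,
         error = net$error, n_nodes = net$n_nodes,
         probabilities = result$probabilities,
         edges = if (nrow(net$edges)) unname(apply(net$edges, 1L, as.list))
                 else list())
  } else if (inherits(result, "window_profile")) {
    list(kind = "window_profile", method = result$method,
         window_length = result$window_length, step = result$step,
         config = result$config, offsets = result$offsets,
         values = result$values)
  } else if (inherits(result, "sweep_result")) {
    out <- list(kind = "sweep_result", generator = result$generator,
                method = result$method, param = as.list(result$param),
                config = result$config)
    if (is.matrix(result$values)) {
      out$grid_x <- result$grid_x
      out$grid_y <- result$grid_y
      out$values <- apply(unname(result$values), 1L, identity, simplify = FALSE)
    } else {
      out$grid <- result$grid
      out$values <- result$values
    }
    out
  } else {
    stop("unsupported result class", call. = FALSE)
  }
}

#' Read back a JSON result written by [write_results()]
#'
#' @param path JSON file path.
#' @return the parsed payload (a list mirroring the written structure).
#' @export
read_results <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
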