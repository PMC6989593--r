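## Plain-text serialization: CSV for profiles and scans, flat JSON for
## model configuration, catalogs and spectra. No binary formats.

#' Write / read an activity profile as CSV
#'
#' Columns `index` (0-based cell), `theta_rad` (radians, full double
#' precision) and `u`, with a mandatory header row.
#'
#' @param state A [state_profile()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_state_profile <- function(state, path) {
  stopifnot(inherits(state, "state_profile"))
  df <- data.frame(index = 0:(state$grid$n - 1L),
                   theta_rad = format(state$grid$theta, digits = 17),
                   u = format(state$u, digits = 17))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_state_profile
#' @param t Time stamp to attach on read (default 0).
#' @export
read_state_profile <- function(path, t = 0) {
  df <- read.csv(path)
  stopifnot(all(c("index", "theta_rad", "u") %in% names(df)))
  df <- df[order(df$index), ]
  state_profile(ring_grid(nrow(df)), as.numeric(df$u), t = t)
}

#' Write / read the model (kernel + gain) as flat JSON
#'
#' Schema: `{a, b, c, alpha, gain_kind, k, u0}` (`k` is `null` for the
#' step gain).
#'
#' @param w A [weight_profile()].
#' @param gain A [gain_function()].
#' @param path JSON file path.
#' @return `path`, invisibly (writer); a list with `w` and `gain`
#'   (reader).
#' @export
write_model_json <- function(w, gain, path) {
  stopifnot(inherits(w, "weight_profile"), inherits(gain, "gain_function"))
  obj <- list(a = w$a, b = w$b, c = w$c, alpha = w$alpha,
              gain_kind = gain$kind,
              k = if (gain$kind == "logistic") gain$k else NULL,
              u0 = gain$u0)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("a", "b", "c", "alpha", "gain_kind", "u0")
  if (!all(need %in% names(obj)))
    stop("model JSON is missing fields: ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  list(w = weight_profile(a = obj$a, b = obj$b, c = obj$c,
                          alpha = obj$alpha),
       gain = if (obj$gain_kind == "step")
         gain_function("step", u0 = obj$u0)
       else gain_function("logistic", k = obj$k, u0 = obj$u0))
}

#' Export an equilibrium catalog as JSON
#'
#' Array of objects `{family, b, c, a0, b1, b2, c1, c2, residual, n_grid}`.
#'
#' @param catalog Data frame from [equilibrium_catalog()].
#' @param path JSON file path.
#' @export
write_catalog_json <- function(catalog, path) {
  jsonlite::write_json(catalog, path, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Export a spectrum as JSON
#'
#' Object `{family, b, c, bulk, special_re, special_im, lambda_max,
#' stable}`; infinite sentinels (step-gain flat state) are serialized as
#' the strings `"Inf"` / `"-Inf"`.
#'
#' @param spectrum A `"ring_spectrum"`.
#' @param path JSON file path.
#' @export
write_spectrum_json <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ring_spectrum"))
  ser <- function(x) ifelse(is.finite(x), x, as.character(x))
  obj <- list(family = spectrum$family, b = spectrum$b, c = spectrum$c,
              bulk = spectrum$bulk,
              special_re = ser(Re(spectrum$special)),
              special_im = Im(spectrum$special),
              lambda_max = ser(spectrum$lambda_max),
              stable = spectrum$stable,
              method = spectrum$method)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a phase diagram as CSV plus JSON metadata
#'
#' @param pd A `"phase_diagram"` data frame.
#' @param csv_path Long-form CSV output path.
#' @param meta_path Optional JSON path for the run metadata (gain slope,
#'   grid, time step, seeds, tolerances).
#' @export
write_phase_diagram <- function(pd, csv_path, meta_path = NULL) {
  write.csv(as.data.frame(pd), csv_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- attr(pd, "meta")
    if (is.null(meta)) meta <- list(kind = attr(pd, "kind"))
    meta$kind <- attr(pd, "kind")
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(csv_path)
}
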