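# Tabular export of the analytic functions: two-column CSVs with JSON
# sidecars carrying the parameters, written at full double precision so
# that read-back round-trips bit-exactly.

fmt17 <- function(x) sprintf("%.17g", x)

sidecar_payload <- function(params, ctrl, extra = list()) {
  c(list(params = lapply(unclass(params)[1:5], fmt17),
         ctrl = lapply(unclass(ctrl), fmt17)),
    extra)
}

#' Export a tabulated step density or distribution function
#'
#' Writes a two-column CSV `(s, value)` plus a JSON sidecar
#' (`<path>.json`) carrying the mixture parameters and series policy.
#'
#' @param tbl A tibble from [ssf_table()] (attributes `params`, `ctrl`).
#' @param path Destination CSV path.
#' @param what Which column to export: `"pdf"` or `"cdf"`.
#' @param note Optional free-text tag stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_ssf_table <- function(tbl, path, what = c("pdf", "cdf"), note = NULL) {
  what <- match.arg(what)
  params <- attr(tbl, "params")
  ctrl <- attr(tbl, "ctrl")
  if (is.null(params) || is.null(ctrl)) {
    stop("`tbl` must carry `params` and `ctrl` attributes (see ssf_table())",
         call. = FALSE)
  }
  df <- data.frame(s = fmt17(tbl$s), value = fmt17(tbl[[what]]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  extra <- list(what = what)
  if (!is.null(note)) extra$note <- note
  jsonlite::write_json(sidecar_payload(params, ctrl, extra),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read back a tabulated step function
#'
#' @param path CSV path written by [write_ssf_table()].
#' @return A tibble `(s, value)` with attributes `params`, `ctrl`, `what`.
#' @export
read_ssf_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  p <- lapply(side$params, as.numeric)
  ct <- lapply(side$ctrl, as.numeric)
  out <- tibble::tibble(s = df$s, value = df$value)
  attr(out, "params") <- mixture_params(p$mu_ta, p$mu_tb, p$sigma_a, p$sigma_b, p$P)
  attr(out, "ctrl") <- series_control(ct$epsilon_tail, ct$n_max_cap, ct$quad_rel_tol)
  attr(out, "what") <- side$what
  out
}

#' Serialise a quantile look-up table
#'
#' Writes the `(cdf, s)` grid as CSV at full precision with a JSON sidecar
#' (parameters, series policy, coverage, parameter hash). Reading back with
#' [read_quantile_table()] reproduces the table bit-exactly.
#'
#' @param table An `ssf_quantile_table`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_quantile_table <- function(table, path) {
  stopifnot(inherits(table, "ssf_quantile_table"))
  df <- data.frame(cdf = fmt17(table$cdf), s = fmt17(table$s))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    sidecar_payload(attr(table, "params"), attr(table, "ctrl"),
                    list(coverage = fmt17(attr(table, "coverage")),
                         params_hash = attr(table, "params_hash"))),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read back a quantile look-up table
#'
#' @param path CSV path written by [write_quantile_table()].
#' @return An `ssf_quantile_table` identical (bit-exactly on its grids) to
#'   the one written.
#' @export
read_quantile_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  p <- lapply(side$params, as.numeric)
  ct <- lapply(side$ctrl, as.numeric)
  tbl <- tibble::tibble(s = df$s, cdf = df$cdf)
  attr(tbl, "params") <- mixture_params(p$mu_ta, p$mu_tb, p$sigma_a, p$sigma_b, p$P)
  attr(tbl, "ctrl") <- series_control(ct$epsilon_tail, ct$n_max_cap, ct$quad_rel_tol)
  attr(tbl, "coverage") <- as.numeric(side$coverage)
  attr(tbl, "params_hash") <- side$params_hash
  class(tbl) <- c("ssf_quantile_table", class(tbl))
  tbl
}
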