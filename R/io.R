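#' Write a stimulus ensemble as flat binary plus JSON sidecar
#'
#' Frames are stored as little-endian float32 in C (row-major) order over
#' `(T, H, W)`, alongside a JSON header `<path>.json` recording dtype, shape,
#' order and the ensemble metadata.
#'
#' @param ensemble a [stimulus_ensemble()].
#' @param path output `.bin` path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stimuli <- function(ensemble, path) {
  d <- dim(ensemble)
  # C order over (T,H,W): last index fastest
  x <- aperm(unclass(ensemble), c(3, 2, 1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(x), con, size = 4, endian = "little")
  header <- list(dtype = "float32", shape = d, order = "C",
                 frame_rate = attr(ensemble, "frame_rate"),
                 kind = attr(ensemble, "kind"),
                 seed = attr(ensemble, "seed"))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a stimulus ensemble written by [write_stimuli()]
#' @param path the `.bin` path (sidecar `<path>.json` must exist).
#' @return A [stimulus_ensemble()].
#' @export
read_stimuli <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(header$dtype, "float32") || !identical(header$order, "C"))
    stop("unsupported stimulus container (need float32, C order)")
  d <- as.integer(header$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = prod(d), size = 4, endian = "little")
  frames <- aperm(array(x, dim = rev(d)), c(3, 2, 1))
  stimulus_ensemble(frames, frame_rate = header$frame_rate %||% 33,
                    kind = header$kind %||% "external",
                    seed = header$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write spike counts as plain text, one integer per line
#' @param spikes a [spike_response()] or integer vector.
#' @param path output path.
#' @export
write_spikes <- function(spikes, path) {
  writeLines(format(as.integer(spikes), scientific = FALSE), path)
  invisible(path)
}

#' Read spike counts written by [write_spikes()]
#' @param path input path.
#' @return A [spike_response()].
#' @export
read_spikes <- function(path) {
  spike_response(as.integer(readLines(path)))
}

#' Serialize a jackknife partition as JSON
#' @param partition a [jackknife_partitions()] object.
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  jsonlite::write_json(list(n = partition$n, folds = partition$folds,
                            blocks = partition$blocks),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a jackknife partition from JSON
#' @param path input path.
#' @export
read_partition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- jackknife_partitions(x$n, x$folds)
  p$blocks <- lapply(x$blocks, as.integer)
  p
}

#' Serialize an LN cell specification as JSON
#'
#' The gain family and parameters go into the JSON body; the dimension
#' matrix is stored column-wise in the same file.
#'
#' @param cell an [ln_cell()].
#' @param path output path.
#' @export
write_cell <- function(cell, path) {
  jsonlite::write_json(list(gain_family = cell$gain_family,
                            theta = cell$theta, sigma = cell$sigma,
                            gamma = cell$gamma, omega = cell$omega,
                            D = nrow(cell$dimensions),
                            K = ncol(cell$dimensions),
                            dimensions = as.vector(cell$dimensions)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an LN cell written by [write_cell()]
#' @param path input path.
#' @export
read_cell <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ln_cell(matrix(x$dimensions, x$D, x$K), x$gain_family,
          theta = x$theta, sigma = x$sigma, gamma = x$gamma, omega = x$omega)
}
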