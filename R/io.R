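# Serialization: matrices as headed CSV with a YAML metadata sidecar,
# phase maps as 32-bit float TIFF plus a mask TIFF, mode vectors as CSV.

#' Save a matrix as CSV with a metadata sidecar
#'
#' Values are written with 12 significant digits; a `<path>.meta.yaml`
#' sidecar records the dimensions and any extra metadata, and is validated
#' on load.
#'
#' @param m matrix, or an `influence_matrix` / `control_matrix` object.
#' @param path output CSV path.
#' @param meta named list of extra metadata.
#' @return `path`, invisibly.
#' @export
save_matrix <- function(m, path, meta = list()) {
  if (inherits(m, "influence_matrix")) {
    meta <- c(meta, list(kind = "influence_matrix",
                         mode_indices = m$mode_indices))
    mat <- m$B
    dimnames(mat) <- list(paste0("noll", m$mode_indices),
                          paste0("act", seq_len(ncol(mat))))
  } else if (inherits(m, "control_matrix")) {
    meta <- c(meta, list(kind = "control_matrix",
                         mode_indices = m$mode_indices,
                         entry_threshold = m$entry_threshold,
                         sv_cutoff = m$sv_cutoff, source = m$source))
    mat <- m$C
    dimnames(mat) <- list(paste0("act", seq_len(nrow(mat))),
                          paste0("noll", m$mode_indices))
  } else {
    mat <- as.matrix(m)
    if (is.null(rownames(mat))) rownames(mat) <- paste0("r", seq_len(nrow(mat)))
    if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  }
  df <- as.data.frame(signif(mat, 12))
  utils::write.csv(cbind(id = rownames(mat), df), path, row.names = FALSE,
                   quote = FALSE)
  meta$nrow <- nrow(mat)
  meta$ncol <- ncol(mat)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Load a matrix saved by [save_matrix()]
#'
#' @param path CSV path.
#' @return The matrix; `influence_matrix` / `control_matrix` objects are
#'   restored with their class and metadata.
#' @export
load_matrix <- function(path) {
  metapath <- paste0(path, ".meta.yaml")
  if (!file.exists(metapath)) stop("missing metadata sidecar: ", metapath)
  meta <- yaml::read_yaml(metapath)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "id") stop("tampered or invalid header: expected 'id' column")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$id
  if (!identical(dim(mat), c(as.integer(meta$nrow), as.integer(meta$ncol))))
    stop(sprintf("matrix shape %dx%d does not match metadata %sx%s",
                 nrow(mat), ncol(mat), meta$nrow, meta$ncol))
  storage.mode(mat) <- "double"
  kind <- meta$kind %||% "matrix"
  if (kind == "influence_matrix") {
    structure(list(B = unname(mat), mode_indices = as.integer(meta$mode_indices),
                   fit_residuals = NULL, positions = NULL),
              class = "influence_matrix")
  } else if (kind == "control_matrix") {
    structure(list(C = unname(mat), mode_indices = as.integer(meta$mode_indices),
                   entry_threshold = meta$entry_threshold,
                   sv_cutoff = meta$sv_cutoff, source = meta$source),
              class = "control_matrix")
  } else mat
}

#' Write a phase map as 32-bit TIFF plus mask and scaling sidecars
#'
#' TIFF samples live in [0, 1], so the phase is affinely rescaled and the
#' (offset, scale) pair recorded in a `<path>.meta.yaml` sidecar; the pupil
#' mask goes to `<path>.mask.tiff`.
#'
#' @param phase a [phase_map()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_phase_tiff <- function(phase, path) {
  rng <- range(phase$values)
  span <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((phase$values - rng[1]) / span, path, bits.per.sample = 32)
  tiff::writeTIFF(phase$mask * 1, paste0(path, ".mask.tiff"),
                  bits.per.sample = 8)
  yaml::write_yaml(list(offset = rng[1], scale = span,
                        pixel_scale = phase$pixel_scale),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a phase map written by [write_phase_tiff()]
#' @param path TIFF path.
#' @return A [phase_map()].
#' @export
read_phase_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  vals <- tiff::readTIFF(path) * meta$scale + meta$offset
  mask <- tiff::readTIFF(paste0(path, ".mask.tiff")) > 0.5
  phase_map(vals, mask, meta$pixel_scale)
}

#' Save / load a mode vector as two-column CSV
#' @param a a [mode_vector()].
#' @param path CSV path.
#' @return `path` (save) or a [mode_vector()] (load).
#' @export
save_mode_vector <- function(a, path) {
  utils::write.csv(data.frame(noll_index = mode_indices(a),
                              amplitude_rad = signif(a$amplitudes, 12)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_mode_vector
#' @export
load_mode_vector <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("noll_index", "amplitude_rad") %in% names(df)))
    stop("expected columns noll_index, amplitude_rad")
  if (any(diff(df$noll_index) != 1)) stop("noll_index must be contiguous")
  mode_vector(df$amplitude_rad, first_index = df$noll_index[1])
}
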