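# Serialization: NIfTI volumes with JSON sidecars for image sets, maps,
# labels and bias fields; CSV/JSON for evaluation reports; PNG previews.

sidecar_path <- function(prefix) paste0(prefix, ".json")

#' Write a complex image set to NIfTI
#'
#' Writes `<prefix>_real.nii.gz` and `<prefix>_imag.nii.gz` (images stacked
#' on the third dimension) plus a JSON sidecar `<prefix>.json` listing the
#' (TE, TR) pairs in ms, the noise sigma and the storage dialect.
#'
#' @param images A [complex_image_set].
#' @param prefix Output path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_image_set <- function(images, prefix) {
  stopifnot(inherits(images, "complex_image_set"))
  RNifti::writeNifti(Re(images$images), paste0(prefix, "_real.nii.gz"))
  RNifti::writeNifti(Im(images$images), paste0(prefix, "_imag.nii.gz"))
  side <- list(te_ms = images$protocol$te, tr_ms = images$protocol$tr,
               noise_sigma = images$noise_sigma, dialect = "complex")
  jsonlite::write_json(side, sidecar_path(prefix),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a complex image set written by [write_image_set()]
#'
#' Also accepts a magnitude-only export (`<prefix>_mag.nii.gz`, dialect
#' `"magnitude"`), in which case the imaginary part is taken as zero and
#' the dialect is recorded on the returned object.
#'
#' @param prefix Path prefix used when writing.
#' @return A [complex_image_set].
#' @export
read_image_set <- function(prefix) {
  side <- jsonlite::read_json(sidecar_path(prefix), simplifyVector = TRUE)
  if (is.null(side$te_ms) || is.null(side$tr_ms))
    stop("malformed sidecar: missing te_ms/tr_ms")
  proto <- acquisition_protocol(side$te_ms, side$tr_ms)
  dialect <- if (is.null(side$dialect)) "complex" else side$dialect
  if (identical(dialect, "magnitude")) {
    mag <- as.array(RNifti::readNifti(paste0(prefix, "_mag.nii.gz")))
    cube <- array(complex(real = mag), dim = dim(mag))
  } else {
    re <- as.array(RNifti::readNifti(paste0(prefix, "_real.nii.gz")))
    im <- as.array(RNifti::readNifti(paste0(prefix, "_imag.nii.gz")))
    cube <- array(complex(real = re, imaginary = im), dim = dim(re))
  }
  if (length(dim(cube)) == 2L) cube <- array(cube, dim = c(dim(cube), 1L))
  sig <- if (is.null(side$noise_sigma)) NA_real_ else side$noise_sigma
  out <- complex_image_set(cube, proto, noise_sigma = sig)
  attr(out, "dialect") <- dialect
  out
}

#' Write estimate maps to NIfTI
#'
#' One volume per parameter (`_rho`, `_t1`, `_t2`, `_phi`, `_residual`)
#' plus a `_mask` volume; units (a.u., ms, radians) are recorded in the
#' sidecar.
#'
#' @param maps An [estimate_maps].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_estimate_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "estimate_maps"))
  nz <- function(m) { m[is.na(m)] <- 0; m }
  RNifti::writeNifti(nz(maps$rho_hat), paste0(prefix, "_rho.nii.gz"))
  RNifti::writeNifti(nz(maps$t1_hat), paste0(prefix, "_t1.nii.gz"))
  RNifti::writeNifti(nz(maps$t2_hat), paste0(prefix, "_t2.nii.gz"))
  RNifti::writeNifti(nz(maps$phi_hat), paste0(prefix, "_phi.nii.gz"))
  RNifti::writeNifti(nz(maps$residual), paste0(prefix, "_residual.nii.gz"))
  RNifti::writeNifti(maps$mask * 1, paste0(prefix, "_mask.nii.gz"))
  jsonlite::write_json(list(units = list(rho = "a.u.", t1 = "ms", t2 = "ms",
                                         phi = "rad")),
                       sidecar_path(prefix), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read estimate maps written by [write_estimate_maps()]
#' @param prefix Path prefix used when writing.
#' @return An [estimate_maps].
#' @export
read_estimate_maps <- function(prefix) {
  rd <- function(s) {
    m <- as.array(RNifti::readNifti(paste0(prefix, "_", s, ".nii.gz")))
    matrix(m, dim(m)[1], dim(m)[2])
  }
  mask <- rd("mask") > 0.5
  blank <- function(m) { m[!mask] <- NA_real_; m }
  estimate_maps(blank(rd("rho")), blank(rd("t1")), blank(rd("t2")),
                blank(rd("phi")), blank(rd("residual")), mask)
}

#' Write a label map (or segmentation labels) to NIfTI + JSON
#' @param x A [label_map] or [segmentation].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_labels <- function(x, prefix) {
  if (inherits(x, "label_map")) {
    RNifti::writeNifti(x$labels, paste0(prefix, "_labels.nii.gz"),
                       datatype = "int16")
    side <- list(kind = "label_map", class_names = x$class_names,
                 class_params = lapply(x$class_params, function(t)
                   list(rho = t$rho, t1_ms = t$t1, t2_ms = t$t2)))
  } else if (inherits(x, "segmentation")) {
    RNifti::writeNifti(x$labels, paste0(prefix, "_labels.nii.gz"),
                       datatype = "int16")
    side <- list(kind = "segmentation", criterion = x$criterion)
  } else stop("x must be a label_map or segmentation")
  jsonlite::write_json(side, sidecar_path(prefix), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a label map written by [write_labels()]
#' @param prefix Path prefix used when writing.
#' @return A [label_map].
#' @export
read_label_map <- function(prefix) {
  side <- jsonlite::read_json(sidecar_path(prefix), simplifyVector = FALSE)
  lab <- as.array(RNifti::readNifti(paste0(prefix, "_labels.nii.gz")))
  lab <- matrix(as.integer(round(lab)), dim(lab)[1], dim(lab)[2])
  params <- lapply(side$class_params, function(p)
    tissue_params(p$rho, p$t1_ms, p$t2_ms))
  label_map(lab, unlist(side$class_names), params)
}

#' Write an evaluation report as CSV (one row per class) and JSON
#' @param report An `evaluation_report` from [evaluate_segmentation()].
#' @param prefix Output path prefix.
#' @param extra Named list of run descriptors (seed, SNR, criterion, ...)
#'   prepended as columns to every CSV row.
#' @return `prefix`, invisibly.
#' @export
write_report <- function(report, prefix, extra = list()) {
  stopifnot(inherits(report, "evaluation_report"))
  df <- report$per_class
  df$overall_accuracy <- report$overall_accuracy
  if (length(extra))
    df <- cbind(as.data.frame(extra, stringsAsFactors = FALSE), df)
  write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(confusion = report$confusion, per_class = report$per_class,
         overall_accuracy = report$overall_accuracy,
         n_voxels = report$n_voxels, run = extra),
    sidecar_path(prefix), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(prefix)
}

# fixed class -> color table for previews (background, then classes)
segmentation_palette <- function(n) {
  base <- c("#2166ac", "#e08214", "#1b7837", "#b2182b",
            "#762a83", "#35978f", "#c51b7d", "#8c510a")
  c("#000000", rep(base, length.out = n))
}

#' Color-coded PNG preview of a label map or segmentation
#'
#' Requires the optional `png` package.
#'
#' @param x A [label_map] or [segmentation].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_preview_png <- function(x, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for previews")
  lab <- x$labels
  pal <- segmentation_palette(max(lab))
  rgb <- grDevices::col2rgb(pal[lab + 1L]) / 255
  img <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[ch, ], nrow(lab), ncol(lab))
  png::writePNG(img, path)
  invisible(path)
}
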