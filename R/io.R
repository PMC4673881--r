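#' Write / read traced contours as TSV
#'
#' One row per point: genotype, replicate, x_um, y_um.
#'
#' @param contours List of \code{sam_contour} objects.
#' @param path Output file.
#' @export
write_contours_tsv <- function(contours, path) {
  tab <- do.call(rbind, lapply(contours, function(ct)
    data.frame(genotype = ct$genotype, replicate = ct$replicate,
               x_um = ct$x, y_um = ct$y, stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_tsv
#' @export
read_contours_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  sp <- split(tab, list(tab$genotype, tab$replicate), drop = TRUE)
  unname(lapply(sp, function(d)
    sam_contour(d$x_um, d$y_um, genotype = d$genotype[1],
                replicate = d$replicate[1])))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a 16-bit grayscale TIFF image
#'
#' @param image Numeric matrix in [0, 1], rows = image rows.
#' @param path Output .tif path.
#' @export
write_image_tiff <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(image)), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_gray <- function(path) {
  img <- EBImage::readImage(path)
  img_matrix(img)
}
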