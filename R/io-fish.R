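#' Write a nucleus image as multi-page TIFF with a JSON sidecar
#'
#' Pages are z-planes interleaved by channel (z1/ch1, z1/ch2, z2/ch1, ...),
#' stored as 32-bit float after division by a global scale factor recorded in
#' the sidecar. The sidecar (\code{<path>.json}) carries voxel size, channel
#' order, shape, intensity scale and - for simulated nuclei - the ground
#' truth.
#'
#' @param img a [NucleusImage-class].
#' @param path output path; \code{.tif} is appended when absent.
#' @return the TIFF path, invisibly.
#' @export
writeNucleusImage <- function(img, path) {
    if (!grepl("\\.tif{1,2}$", path)) path <- paste0(path, ".tif")
    d <- dim(channelArray(img, 1L))
    scale <- max(max(channelArray(img, 1L)), max(channelArray(img, 2L)), 1)
    pages <- vector("list", 2L * d[1L])
    for (z in seq_len(d[1L])) for (ch in 1:2)
        pages[[(z - 1L) * 2L + ch]] <-
            channelArray(img, ch)[z, , ] / scale
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    gt <- imageTruth(img)
    if (length(gt) && !is.null(gt$centers))
        gt$centers <- lapply(gt$centers, function(m)
            if (nrow(m)) unclass(as.data.frame(m)) else list())
    jsonlite::write_json(list(
        voxel_size_um = voxelSize(img), shape = d,
        channel_order = "interleaved", n_channels = 2L,
        intensity_scale = scale, ground_truth = gt),
        paste0(tools::file_path_sans_ext(path), ".json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Read a nucleus image written by [writeNucleusImage()]
#'
#' @param path the TIFF path (the sidecar is found next to it).
#' @return a [NucleusImage-class] (float32 precision).
#' @export
readNucleusImage <- function(path) {
    meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                                simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    d <- as.integer(meta$shape)
    chans <- lapply(1:2, function(ch) {
        a <- array(0, dim = d)
        for (z in seq_len(d[1L]))
            a[z, , ] <- pages[[(z - 1L) * 2L + ch]]
        a * meta$intensity_scale
    })
    gt <- meta$ground_truth
    if (!is.null(gt$centers))
        gt$centers <- lapply(gt$centers, function(l)
            if (length(l)) as.matrix(as.data.frame(l)) else
                matrix(numeric(), 0L, 3L))
    NucleusImage(chans, meta$voxel_size_um,
                 groundTruth = if (is.null(gt)) list() else gt)
}
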