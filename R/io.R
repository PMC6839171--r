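# Format adapters: BED / bedGraph / TSV readers and writers, model
# serialization, and the JSON run manifest. All files written are 0-based
# half-open.

MODEL_FORMAT_VERSION <- 1L

#' Read a BED file as GRanges
#'
#' @param path BED file (0-based half-open)
#' @return GRanges
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED requires the rtracklayer package")
  rtracklayer::import(path, format = "BED")
}

#' Write a BinnedTrack to disk
#'
#' @param track a \linkS4class{BinnedTrack}
#' @param path output file
#' @param format \code{"bedGraph"} (4 columns) or \code{"tsv"} (with header)
#' @export
writeBinnedTrack <- function(track, path, format = c("bedGraph", "tsv")) {
  format <- match.arg(format)
  gb <- track@bins
  s0 <- binStart0(gb)
  chrom <- binChrom(gb)
  df <- data.frame(chrom = chrom, start = s0,
                   end = pmin(s0 + gb@binSize, gb@seqlengths[chrom]),
                   value = track@values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = (format == "tsv"))
  invisible(path)
}

#' Read a binned track from a bedGraph-style table
#'
#' Accepts a 4-column (chrom, start, end, value) table, headered or not;
#' intervals must align to the bin grid. Unlisted bins default to 0.
#'
#' @param path input file
#' @param bins the target \linkS4class{GenomeBins}
#' @param mark track label
#' @return a \linkS4class{BinnedTrack}
#' @export
readBinnedTrack <- function(path, bins, mark) {
  if (!file.exists(path)) stop("missing file: ", path)
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("start", first, ignore.case = TRUE)
  df <- read.table(path, sep = "\t", header = hasHeader,
                   col.names = c("chrom", "start", "end", "value"),
                   stringsAsFactors = FALSE)
  bad <- !(df$chrom %in% names(bins@seqlengths))
  if (all(bad)) stop("no overlap between file chromosomes and the bin grid")
  if (any(bad)) {
    warning(sum(bad), " interval(s) on chromosomes absent from the grid dropped")
    df <- df[!bad, , drop = FALSE]
  }
  if (any(df$start %% bins@binSize != 0L))
    stop("intervals in ", path, " do not align to the ", bins@binSize,
         "-bp bin grid")
  v <- numeric(nBins(bins))
  v[globalBin(bins, df$chrom, df$start)] <- df$value
  binnedTrack(bins, mark, v)
}

#' Write enhancer peaks as BED6+
#'
#' Columns: chrom, start, end, name, summit probability, strand (.),
#' summit position (0-based).
#'
#' @param peaks GRanges from \code{\link{callPeaks}}
#' @param path output file
#' @export
writePeaksBed <- function(peaks, path) {
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = sprintf("peak_%d", seq_along(peaks)),
                   score = mcols(peaks)$summit_prob, strand = ".",
                   summit = mcols(peaks)$summit0)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write differential regions as BED with pattern, peak and p-value columns
#'
#' @param regions GRanges from \code{\link{buildRegions}}
#' @param path output file
#' @export
writeRegionsBed <- function(regions, path) {
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L, end = end(regions),
                   pattern = mcols(regions)$pattern,
                   peak = mcols(regions)$peak0,
                   peak_p = mcols(regions)$peak_p)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Serialize / restore a trained EnhancerModel
#'
#' The archive embeds a format version; \code{loadEnhancerModel} refuses to
#' load archives written under an incompatible format.
#'
#' @param model an \linkS4class{EnhancerModel}
#' @param path archive path
#' @export
saveEnhancerModel <- function(model, path) {
  saveRDS(list(format_version = MODEL_FORMAT_VERSION, model = model), path)
  invisible(path)
}

#' @rdname saveEnhancerModel
#' @export
loadEnhancerModel <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format_version, MODEL_FORMAT_VERSION))
    stop("incompatible model archive (format version ",
         if (is.list(obj)) obj$format_version else "unknown",
         ", expected ", MODEL_FORMAT_VERSION, ")")
  validObject(obj$model)
  obj$model
}

#' Write a JSON run manifest
#'
#' Records the stage, its parameters, the seed, input file checksums and the
#' package version, so any stage can be re-run reproducibly.
#'
#' @param path output JSON path
#' @param stage stage name
#' @param params named list of parameters
#' @param inputs character vector of input paths (checksummed when they exist)
#' @param seed integer seed
#' @export
writeRunManifest <- function(path, stage, params, inputs = character(0),
                             seed = NA_integer_) {
  checksums <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1))
  manifest <- list(stage = stage, params = params, seed = seed,
                   inputs = as.list(checksums),
                   version = as.character(packageVersion("enhanceRF")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
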