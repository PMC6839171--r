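# Track normalization: input normalization, the me1/me3 ratio track, and
# target quantile normalization against a stored training reference.

#' Log2 input normalization of raw counts
#'
#' Per bin, \code{log2(treatment + 1) - log2(control + 1)}, i.e. the log2
#' ratio of treatment to input with a pseudo-count of 1 on both.
#'
#' @param treatment,control \linkS4class{BinnedTrack}s of raw counts on the
#'   same grid
#' @return a \linkS4class{BinnedTrack} with the treatment's mark
#' @export
inputNormalize <- function(treatment, control) {
  stopifDifferentBins(treatment, control)
  binnedTrack(treatment@bins, treatment@mark,
              log2(treatment@values + 1) - log2(control@values + 1))
}

# genome-wide minima used to shift input-normalized me1/me3 tracks to >= 0;
# captured at training time and reapplied verbatim at prediction time
trackShifts <- function(me1, me3) {
  c(H3K4me1 = min(me1@values), H3K4me3 = min(me3@values))
}

#' H3K4me1 / H3K4me3 log-ratio track
#'
#' Both input-normalized tracks are shifted to be >= 0 by subtracting their
#' genome-wide minima (or the supplied training-time \code{shifts}); the
#' ratio is then \code{log2(me1' + 1) - log2(me3' + 1)}.
#'
#' @param me1,me3 input-normalized \linkS4class{BinnedTrack}s
#' @param shifts optional named numeric (\code{H3K4me1}, \code{H3K4me3})
#'   overriding the tracks' own minima; shifted values are clipped at 0
#' @return a \linkS4class{BinnedTrack} with mark \code{"ratio"}
#' @export
ratioTrack <- function(me1, me3, shifts = NULL) {
  stopifDifferentBins(me1, me3)
  if (is.null(shifts)) shifts <- trackShifts(me1, me3)
  v1 <- pmax(me1@values - shifts[["H3K4me1"]], 0)
  v3 <- pmax(me3@values - shifts[["H3K4me3"]], 0)
  binnedTrack(me1@bins, "ratio", log2(v1 + 1) - log2(v3 + 1))
}

#' Build a quantile reference from a training track
#'
#' Stores a sorted snapshot of the track's value distribution, subsampled to
#' at most \code{maxPoints} evenly spaced quantiles to bound model size.
#'
#' @param track a \linkS4class{BinnedTrack} (input-normalized, at training)
#' @param maxPoints maximum stored quantiles (default 10000)
#' @return a \linkS4class{QuantileReference}
#' @export
quantileReference <- function(track, maxPoints = 10000L) {
  v <- sort(track@values)
  if (length(v) > maxPoints) {
    q <- (seq_len(maxPoints) - 1) / (maxPoints - 1)
    v <- unname(quantile(v, probs = q, names = FALSE, type = 7))
  }
  new("QuantileReference", mark = track@mark, sortedValues = v)
}

#' Quantile normalization against a stored reference distribution
#'
#' Maps each input value to the reference quantile at the same relative rank,
#' so the output follows the reference's distribution while preserving the
#' input's ordering. Ties get the average rank (tied inputs map to one common
#' output value); relative ranks are interpolated linearly when input and
#' reference lengths differ.
#'
#' @param values numeric vector
#' @param reference a \linkS4class{QuantileReference} or sorted numeric vector
#' @return numeric vector, same length and order as \code{values}
#' @examples
#' ref <- new("QuantileReference", mark = "H3K27ac",
#'            sortedValues = c(10, 20, 30))
#' quantileNormalize(c(5, 1, 3), ref)  # 30 10 20
#' @export
quantileNormalize <- function(values, reference) {
  ref <- if (is(reference, "QuantileReference")) reference@sortedValues
         else as.numeric(reference)
  if (length(ref) == 0L) stop("empty quantile reference")
  n <- length(values)
  if (n == 0L) return(numeric(0))
  m <- length(ref)
  if (m == 1L) return(rep(ref, n))
  r <- rank(values, ties.method = "average")
  q <- if (n == 1L) 0.5 else (r - 1) / (n - 1)
  refq <- (seq_len(m) - 1) / (m - 1)
  approx(refq, ref, xout = q, rule = 2, ties = "ordered")$y
}

#' @rdname quantileNormalize
#' @param track a \linkS4class{BinnedTrack} to normalize
#' @export
quantileNormalizeTrack <- function(track, reference) {
  binnedTrack(track@bins, track@mark,
              quantileNormalize(track@values, reference))
}
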